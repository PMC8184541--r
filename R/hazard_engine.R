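# Competing-risk probability engine on piecewise-constant hazards.
#
# The 10-year probability of a first fracture before death is
#   P = int_0^H phi(a+t) exp(-int_0^t [phi + mu] du) dt
# with phi the fracture hazard and mu the death hazard. Both hazards are
# piecewise constant on one-year intervals, so the integral has an exact
# per-interval closed form and no quadrature tolerance is involved.

#' Piecewise-constant hazard function
#'
#' Hazard per person-year on one-year intervals `[start_age + i - 1,
#' start_age + i)`. Usually produced by [to_hazard()]; the constructor is
#' exported for direct use in tests and simulations.
#'
#' @param start_age,end_age range covered, in years; `end_age - start_age`
#'   must equal `length(values)`.
#' @param values non-negative finite hazards per year, one per interval.
#' @return An object of class `hazard_function`.
#' @export
hazard_function <- function(start_age, end_age, values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("hazard needs at least one interval")
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("hazard values must be finite and non-negative")
  if (abs((end_age - start_age) - length(values)) > 1e-9)
    stop("end_age - start_age must equal the number of one-year intervals")
  structure(list(start_age = start_age, end_age = end_age, values = values),
            class = "hazard_function")
}

#' Constant hazard over an age range
#'
#' @param value hazard per year.
#' @param start_age,end_age covered range in whole years.
#' @return A [hazard_function()].
#' @export
constant_hazard <- function(value, start_age = 40, end_age = 110) {
  hazard_function(start_age, end_age, rep(value, end_age - start_age))
}

#' @export
print.hazard_function <- function(x, ...) {
  cat(sprintf("<hazard_function> ages [%g, %g), %d one-year intervals\n",
              x$start_age, x$end_age, length(x$values)))
  cat(sprintf("  hazard/yr range: %.3g - %.3g\n",
              min(x$values), max(x$values)))
  invisible(x)
}

# Log-linear interpolation of rates with clamped extrapolation. Zero rates
# are floored at 1e-12 before logs; exact zeros are restored wherever the
# interpolated zero-indicator says both bracketing rates were zero.
.interp_rate_loglinear <- function(ages, rates, at) {
  if (length(ages) == 1L)
    return(rep(rates[1L], length(at)))
  lr <- log(pmax(rates, 1e-12))
  out <- exp(stats::approx(ages, lr, xout = at, rule = 2)$y)
  zf <- stats::approx(ages, as.numeric(rates <= 0), xout = at, rule = 2)$y
  out[zf >= 1 - 1e-12] <- 0
  out
}

#' Convert a rate schedule to a piecewise-constant hazard
#'
#' Identifies the event rate with the hazard (rare-event approximation:
#' `hazard(a) = rate(a) / 100000` per year). Between supplied age points
#' the rate is interpolated linearly on the log scale, reflecting the
#' near-exponential growth of fracture and death rates with age; below the
#' first and above the last age point the rate is clamped. The hazard is
#' discretised to one-year intervals using the interval-midpoint age.
#'
#' @param schedule an [age_rate_schedule()].
#' @param start_age,end_age whole-year range to cover; must intersect
#'   \[40, 110\].
#' @return A [hazard_function()] covering `[start_age, end_age)`.
#' @examples
#' s <- age_rate_schedule(c(50, 60), c(10, 40), "female", "hip_incidence")
#' to_hazard(s, 50, 60)
#' @export
to_hazard <- function(schedule, start_age, end_age) {
  stopifnot(inherits(schedule, "age_rate_schedule"))
  if (end_age <= start_age) stop("end_age must exceed start_age")
  if (end_age <= .AGE_MIN || start_age >= .AGE_MAX)
    stop(sprintf("requested range [%g, %g] lies entirely outside [%d, %d]",
                 start_age, end_age, .AGE_MIN, .AGE_MAX))
  n <- as.integer(round(end_age - start_age))
  if (abs(end_age - start_age - n) > 1e-9)
    stop("start_age and end_age must span a whole number of years")
  mids <- start_age + seq_len(n) - 0.5
  rates <- .interp_rate_loglinear(schedule$ages, schedule$rates, mids)
  hazard_function(start_age, end_age, rates / 1e5)
}

#' Evaluate a piecewise-constant hazard at given ages
#'
#' @param h a [hazard_function()].
#' @param age ages in years within the covered range (the right endpoint
#'   maps to the final interval).
#' @return Hazard per year at each age.
#' @export
hazard_at <- function(h, age) {
  stopifnot(inherits(h, "hazard_function"))
  if (any(age < h$start_age - 1e-9) || any(age > h$end_age + 1e-9))
    stop("age outside hazard coverage")
  idx <- pmax(1L, pmin(length(h$values), floor(age - h$start_age) + 1L))
  h$values[idx]
}

.check_coverage <- function(h, age, horizon, what) {
  if (h$start_age > age + 1e-9 || h$end_age < age + horizon - 1e-9)
    stop("hazard coverage gap: ", what, " does not cover [",
         age, ", ", age + horizon, "]")
}

#' 10-year fracture probability under competing mortality
#'
#' Probability of a first fracture before death within `horizon` years of
#' age `age`, for fracture hazard `phi` and death hazard `mu`:
#' `P = int_0^H phi(a+t) exp(-int_0^t (phi+mu) du) dt`. On each interval
#' where both hazards are constant the contribution is
#' `phi/(phi+mu) * S * (1 - exp(-(phi+mu)*d))`, with `S` the survival
#' carried in from earlier intervals, so the result is exact for
#' piecewise-constant hazards.
#'
#' @param phi fracture [hazard_function()].
#' @param mu death [hazard_function()].
#' @param age starting age in years.
#' @param horizon horizon in years, > 0 (default 10).
#' @return Probability in \[0, 1\].
#' @examples
#' phi <- constant_hazard(0.01); mu <- constant_hazard(0.05)
#' ten_year_probability(phi, mu, 60)  # (0.01/0.06) * (1 - exp(-0.6))
#' @export
ten_year_probability <- function(phi, mu, age, horizon = 10) {
  stopifnot(inherits(phi, "hazard_function"), inherits(mu, "hazard_function"))
  if (horizon <= 0) stop("horizon must be positive")
  .check_coverage(phi, age, horizon, "fracture hazard")
  .check_coverage(mu, age, horizon, "death hazard")
  # split at every knot of either hazard so each segment has constant rates
  knots <- c(seq(phi$start_age, phi$end_age),
             seq(mu$start_age, mu$end_age))
  knots <- knots[knots > age & knots < age + horizon]
  brk <- sort(unique(round(c(age, knots, age + horizon), 9)))
  surv <- 1
  p <- 0
  for (i in seq_len(length(brk) - 1L)) {
    d <- brk[i + 1L] - brk[i]
    m <- (brk[i] + brk[i + 1L]) / 2
    f <- hazard_at(phi, m)
    g <- hazard_at(mu, m)
    h <- f + g
    if (h > 0) {
      e <- exp(-h * d)
      p <- p + (f / h) * surv * (1 - e)
      surv <- surv * e
    }
  }
  p
}

#' Probability curve over a set of ages
#'
#' Evaluates [ten_year_probability()] at each age and reports the results
#' in percent, the unit used for published 10-year probabilities.
#'
#' @inheritParams ten_year_probability
#' @param ages numeric vector of starting ages.
#' @return A `data.frame` with columns `age` and `probability_pct`.
#' @export
probability_curve <- function(phi, mu, ages, horizon = 10) {
  p <- vapply(ages, function(a) ten_year_probability(phi, mu, a, horizon),
              numeric(1))
  data.frame(age = as.numeric(ages), probability_pct = 100 * p)
}
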