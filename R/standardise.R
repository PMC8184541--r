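# Age-standardisation and cross-population comparison statistics.

# Half-up decimal rounding (round() rounds half to even; published ratios
# like 17.7 come from half-up rounding).
.round_half_up <- function(x, dp) {
  f <- 10^dp
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Age-standardise a probability curve to a standard population
#'
#' Computes the weighted sum `sum_i w_i * p(mid_i)` over the standard
#' population's age bands, with `p` looked up at each band midpoint
#' (linear interpolation within the curve's age range). Weights are
#' normalised first, so the result is invariant to their scale and always
#' lies within `[min p, max p]`.
#'
#' @param curve a `data.frame` with columns `age` and `probability_pct`
#'   (as returned by [probability_curve()]).
#' @param pop a [standard_population()].
#' @return The standardised probability in percent.
#' @export
age_standardise <- function(curve, pop) {
  stopifnot(inherits(pop, "standard_population"))
  if (!all(c("age", "probability_pct") %in% names(curve)))
    stop("curve needs columns 'age' and 'probability_pct'")
  pop <- normalise(pop)
  mids <- (pop$age_lower + pop$age_upper) / 2
  p <- if (nrow(curve) == 1L) {
    if (any(abs(mids - curve$age) > 1e-9))
      stop("curve does not cover band midpoint(s)")
    rep(curve$probability_pct, length(mids))
  } else {
    stats::approx(curve$age, curve$probability_pct, xout = mids,
                  rule = 1)$y
  }
  if (anyNA(p))
    stop("curve does not cover band midpoint(s)")
  sum(pop$weights * p)
}

#' Ratio of probabilities at two ages within one population
#'
#' E.g. the 80:50 ratio measures how steeply probability rises with age in
#' a population. Rounded half-up to `round_dp` decimals to reproduce
#' published figures deterministically.
#'
#' @param grid a [probability_grid()].
#' @param population population label.
#' @param age_num,age_den numerator and denominator ages.
#' @param round_dp decimals to round to (default 1).
#' @return The rounded ratio.
#' @examples
#' tab <- load_table1_fixture()
#' age_ratio(tab$hip, "Botswana", 80, 50)  # 7.5
#' @export
age_ratio <- function(grid, population, age_num, age_den, round_dp = 1) {
  num <- grid_value(grid, population, age_num)
  den <- grid_value(grid, population, age_den)
  if (den == 0) stop("zero denominator cell")
  .round_half_up(num / den, round_dp)
}

#' Cross-population spread of probabilities at each age
#'
#' For each age, the ratio of the highest to the lowest probability across
#' populations, plus the minimum of these ratios over all ages (a spread
#' floor: "at least an x-fold difference at every age"). Invariant under
#' multiplying every cell by the same positive constant.
#'
#' @param grid a [probability_grid()] with no zero cells.
#' @return A list with `by_age` (named numeric of max/min ratios) and
#'   `min_over_ages`.
#' @export
cross_population_spread <- function(grid) {
  stopifnot(inherits(grid, "probability_grid"))
  if (any(grid$values == 0)) stop("zero cell in grid")
  hi <- apply(grid$values, 2, max)
  lo <- apply(grid$values, 2, min)
  by_age <- hi / lo
  list(by_age = by_age, min_over_ages = min(by_age))
}

#' Per-population range of probabilities over ages
#'
#' @param grid a [probability_grid()].
#' @param population population label.
#' @return Numeric `c(min, max)` over the grid's ages, in percent.
#' @export
column_range <- function(grid, population) {
  stopifnot(inherits(grid, "probability_grid"))
  if (!population %in% grid$populations)
    stop("population not in grid: ", population)
  v <- grid$values[population, ]
  c(min = min(v), max = max(v))
}

#' Comparison statistics for a probability grid
#'
#' Bundles the statistics used to compare populations: the per-population
#' 80:50 age ratio, the per-age cross-population spread, and each
#' population's (min, max) probability over ages.
#'
#' @param grid a [probability_grid()].
#' @param age_num,age_den ages for the per-population ratio (default 80
#'   and 50).
#' @param round_dp decimals for the ratios.
#' @return An object of class `comparison_stats`.
#' @export
comparison_stats <- function(grid, age_num = 80, age_den = 50,
                             round_dp = 1) {
  ratios <- vapply(grid$populations, function(p)
    age_ratio(grid, p, age_num, age_den, round_dp), numeric(1))
  spread <- cross_population_spread(grid)
  rng <- vapply(grid$populations, function(p) column_range(grid, p),
                numeric(2))
  structure(list(outcome = grid$outcome,
                 ratio_ages = c(age_num, age_den),
                 ratio_by_population = ratios,
                 spread_by_age = spread$by_age,
                 min_spread = spread$min_over_ages,
                 column_range = t(rng)),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("<comparison_stats> outcome = %s\n", x$outcome))
  cat(sprintf("  %g:%g probability ratio by population:\n",
              x$ratio_ages[1], x$ratio_ages[2]))
  for (p in names(x$ratio_by_population))
    cat(sprintf("    %-24s %.1f\n", p, x$ratio_by_population[[p]]))
  cat(sprintf("  cross-population spread (max/min), minimum over ages: %.2f\n",
              x$min_spread))
  invisible(x)
}

#' Age-specific intervention thresholds
#'
#' Under the fracture-threshold rule, a person qualifies for treatment
#' when their 10-year MOF probability reaches that of a woman of the same
#' age with a prior fracture and no other risk factors. This returns those
#' threshold probabilities (percent) at each requested age, plus their
#' range over ages.
#'
#' @param model a [country_model()] with female schedules.
#' @param config a [risk_factor_config()]; its `rr_prior_fracture` drives
#'   the thresholds (set to 1 to recover population-average
#'   probabilities).
#' @param ages ages in years.
#' @param horizon horizon in years (default 10).
#' @return A list with `thresholds` (`data.frame(age, threshold_pct)`) and
#'   `range` (`c(min, max)` in percent).
#' @export
intervention_thresholds <- function(model, config = risk_factor_config(),
                                    ages = seq(50, 90, 5), horizon = 10) {
  th <- vapply(ages, function(a) {
    pr <- risk_profile(age = a, sex = "female", prior_fracture = TRUE)
    100 * profile_probability(model, pr, config, horizon)$p_mof
  }, numeric(1))
  list(thresholds = data.frame(age = as.numeric(ages), threshold_pct = th),
       range = c(min = min(th), max = max(th)))
}
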