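# Synthetic-data generator: Gompertz-Makeham schedules, Poisson event
# counts, exact rate estimation, and fully synthetic country models whose
# true hazards are known in closed form. Everything here is clearly
# synthetic and never presented as an estimate for any real population.

#' Gompertz-Makeham rate parameters
#'
#' Fracture incidence and adult mortality both rise near-exponentially
#' with age; the generator uses
#' `rate(a) = base_rate * exp(slope * (a - anchor_age)) + makeham * 100000`
#' per 100,000 person-years, the Makeham term being an age-constant
#' additive hazard (useful for mortality).
#'
#' @param base_rate events per 100,000 person-years at `anchor_age` (> 0).
#' @param anchor_age anchor age in years.
#' @param slope per-year log-rate increase (>= 0).
#' @param makeham age-constant additive hazard per year (>= 0).
#' @return An object of class `gompertz_params`.
#' @export
gompertz_params <- function(base_rate, anchor_age = 50, slope = 0,
                            makeham = 0) {
  if (base_rate <= 0) stop("base_rate must be positive")
  if (slope < 0) stop("slope must be non-negative")
  if (makeham < 0) stop("makeham must be non-negative")
  structure(list(base_rate = base_rate, anchor_age = anchor_age,
                 slope = slope, makeham = makeham),
            class = "gompertz_params")
}

#' Deterministic Gompertz-Makeham rate schedule
#'
#' @param params a [gompertz_params()].
#' @param ages ages in years.
#' @param kind rate kind (see [age_rate_schedule()]).
#' @param sex `"female"` or `"male"`.
#' @param population label; defaults to `"synthetic"`.
#' @return An [age_rate_schedule()].
#' @examples
#' # doubling every 5 years: rate 10 at 50, 20 at 55, 40 at 60
#' gompertz_schedule(gompertz_params(10, 50, log(2) / 5), c(50, 55, 60),
#'                   "hip_incidence", "female")
#' @export
gompertz_schedule <- function(params, ages, kind, sex,
                              population = "synthetic") {
  stopifnot(inherits(params, "gompertz_params"))
  rates <- params$base_rate *
    exp(params$slope * (ages - params$anchor_age)) +
    params$makeham * 1e5
  age_rate_schedule(ages, rates, sex = sex, kind = kind,
                    population = population)
}

#' Sample Poisson event counts from a rate schedule
#'
#' Stands in for register-based case counts: at each age, events are drawn
#' independently from a Poisson law with mean `rate / 100000 *
#' person_years`. A single seed governs all draws, so results are
#' reproducible.
#'
#' @param schedule an [age_rate_schedule()].
#' @param person_years exposure per age: a single value recycled to all
#'   ages, or one value per age; all > 0.
#' @param seed integer seed.
#' @return A `data.frame` with columns `age`, `count`, `person_years`.
#' @export
sample_counts <- function(schedule, person_years, seed) {
  stopifnot(inherits(schedule, "age_rate_schedule"))
  n <- length(schedule$ages)
  person_years <- rep_len(as.numeric(person_years), n)
  if (any(person_years <= 0)) stop("person_years must be positive")
  set.seed(as.integer(seed))
  counts <- stats::rpois(n, schedule$rates / 1e5 * person_years)
  data.frame(age = schedule$ages, count = counts,
             person_years = person_years)
}

#' Estimate rates with exact Poisson confidence intervals
#'
#' `rate = count / person_years * 100000` per age, with the exact
#' (Garwood) 95% interval from chi-square quantiles:
#' lower `qchisq(alpha/2, 2k) / (2 PY)`, upper
#' `qchisq(1 - alpha/2, 2k + 2) / (2 PY)` (lower bound 0 when `k = 0`).
#'
#' @param counts a `data.frame` as returned by [sample_counts()] (columns
#'   `age`, `count`, `person_years`).
#' @param sex,kind,population metadata for the resulting schedule.
#' @param conf_level confidence level (default 0.95).
#' @return An [age_rate_schedule()] with an extra element `ci`, a
#'   `data.frame(age, rate, lower, upper)` per 100,000 person-years.
#' @export
estimate_rates <- function(counts, sex, kind = "hip_incidence",
                           population = "synthetic", conf_level = 0.95) {
  if (!all(c("age", "count", "person_years") %in% names(counts)))
    stop("counts needs columns 'age', 'count', 'person_years'")
  if (any(counts$person_years <= 0)) stop("person_years must be positive")
  k <- counts$count
  py <- counts$person_years
  alpha <- 1 - conf_level
  rate <- k / py * 1e5
  lower <- ifelse(k == 0, 0, stats::qchisq(alpha / 2, 2 * k) / (2 * py) * 1e5)
  upper <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / (2 * py) * 1e5
  out <- age_rate_schedule(counts$age, rate, sex = sex, kind = kind,
                           population = population)
  out$ci <- data.frame(age = counts$age, rate = rate,
                       lower = lower, upper = upper)
  out
}

#' Default synthetic generator parameters
#'
#' A stated synthetic world producing low, age-increasing fracture
#' probabilities (female 10-year hip probability of order 0.2-1.5% across
#' ages 50-90) together with high, steeply rising adult mortality, i.e.
#' the regime in which competing mortality visibly bends the old-age
#' probability curve. These are synthetic defaults, not estimates for any
#' country.
#'
#' @return A list with elements `incidence` and `mortality`, each a list
#'   of [gompertz_params()] by sex.
#' @export
synthetic_default_params <- function() {
  list(
    incidence = list(
      female = gompertz_params(base_rate = 13, anchor_age = 50,
                               slope = 0.080),
      male = gompertz_params(base_rate = 9, anchor_age = 50,
                             slope = 0.075)
    ),
    mortality = list(
      female = gompertz_params(base_rate = 900, anchor_age = 50,
                               slope = 0.080, makeham = 0.003),
      male = gompertz_params(base_rate = 1300, anchor_age = 50,
                             slope = 0.080, makeham = 0.004)
    )
  )
}

#' Build a fully synthetic country model
#'
#' Generates hip incidence and mortality from Gompertz-Makeham parameters,
#' derives MOF incidence with a constant MOF:hip ratio, and bundles the
#' result into a [country_model()] whose true hazards are known in closed
#' form. With `person_years` supplied, hip incidence is first sampled as
#' Poisson counts and re-estimated (emulating a register survey feeding
#' the pipeline); mortality always uses the exact schedule, as national
#' mortality statistics are treated as known.
#'
#' @param incidence_params,mortality_params a [gompertz_params()]
#'   (female only) or a list of them by sex; defaults from
#'   [synthetic_default_params()].
#' @param ratio_constant MOF:hip ratio applied at all ages (>= 1).
#' @param ages age grid for the schedules.
#' @param person_years optional exposure per age; `NULL` (default) keeps
#'   the exact rates.
#' @param seed integer seed used when sampling.
#' @param label model label.
#' @return A [country_model()]; the generating parameters are attached as
#'   attribute `"params"`.
#' @export
make_synthetic_country <- function(incidence_params = NULL,
                                   mortality_params = NULL,
                                   ratio_constant = 3,
                                   ages = seq(50, 100, 5),
                                   person_years = NULL,
                                   seed = 1L,
                                   label = "synthetic") {
  defaults <- synthetic_default_params()
  as_by_sex <- function(x, fallback) {
    if (is.null(x)) return(fallback)
    if (inherits(x, "gompertz_params")) return(list(female = x))
    x
  }
  inc <- as_by_sex(incidence_params, defaults$incidence)
  mor <- as_by_sex(mortality_params, defaults$mortality)
  sexes <- intersect(names(inc), names(mor))
  if (length(sexes) == 0L)
    stop("incidence and mortality parameters share no sex")
  hip <- list(); mof <- list(); mortality <- list()
  for (i in seq_along(sexes)) {
    sx <- sexes[i]
    h <- gompertz_schedule(inc[[sx]], ages, "hip_incidence", sx,
                           population = label)
    if (!is.null(person_years)) {
      cts <- sample_counts(h, person_years, seed = as.integer(seed) + i - 1L)
      h <- estimate_rates(cts, sex = sx, kind = "hip_incidence",
                          population = label)
    }
    rat <- ratio_schedule(range(ages), rep(ratio_constant, 2), sx)
    hip[[i]] <- h
    mof[[i]] <- derive_mof_schedule(h, rat)
    mortality[[i]] <- gompertz_schedule(mor[[sx]], ages, "mortality", sx,
                                        population = label)
  }
  model <- country_model(label, hip = hip, mof = mof,
                         mortality = mortality)
  attr(model, "params") <- list(incidence = inc, mortality = mor,
                                ratio_constant = ratio_constant,
                                ages = ages, person_years = person_years,
                                seed = seed)
  model
}

#' Write a complete set of synthetic input CSVs
#'
#' Emits hip-incidence, mortality and MOF:hip ratio CSVs per sex plus a
#' JSON manifest of the generating parameters, so the file-based pipeline
#' ([read_rate_schedule()], [build_country_model()]) can be exercised
#' end to end.
#'
#' @param dir output directory (created if needed).
#' @inheritParams make_synthetic_country
#' @return Invisibly, the manifest path.
#' @export
write_synthetic_inputs <- function(dir, incidence_params = NULL,
                                   mortality_params = NULL,
                                   ratio_constant = 3,
                                   ages = seq(50, 100, 5),
                                   person_years = NULL, seed = 1L) {
  model <- make_synthetic_country(incidence_params, mortality_params,
                                  ratio_constant, ages, person_years,
                                  seed, label = "synthetic")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sx in names(model$schedules)) {
    sl <- model$schedules[[sx]]
    write_rate_schedule(sl$hip, file.path(dir, paste0("hip_", sx, ".csv")))
    write_rate_schedule(sl$mortality,
                        file.path(dir, paste0("mortality_", sx, ".csv")))
    utils::write.csv(data.frame(age = range(ages),
                                ratio = rep(ratio_constant, 2)),
                     file.path(dir, paste0("ratios_", sx, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- file.path(dir, "manifest.json")
  strip <- function(x) {
    if (inherits(x, "gompertz_params")) unclass(x)
    else if (is.list(x)) lapply(x, strip)
    else x
  }
  jsonlite::write_json(strip(attr(model, "params")), manifest,
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
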