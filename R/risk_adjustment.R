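# Individual risk adjustment: clinical risk factors and femoral-neck BMD
# act as multiplicative relative risks on the fracture hazard only; the
# death hazard is left untouched (no mortality coefficients are modelled).

#' Individual risk profile
#'
#' Covariates of one individual for whom a fracture probability is wanted.
#' BMI has no built-in effect on the hazard (published comparison grids fix
#' it at 25 kg/m2); a BMI effect, like any other clinical risk factor, can
#' be supplied through `extra_rr`.
#'
#' @param age age in years.
#' @param sex `"female"` or `"male"`.
#' @param bmi body-mass index in kg/m2, within \[10, 60\] when supplied.
#' @param prior_fracture has the individual already had a fragility
#'   fracture?
#' @param t_score optional femoral-neck BMD T-score in SD units.
#' @param extra_rr optional named numeric vector of additional relative
#'   risks (> 0), multiplied into the fracture hazard.
#' @return An object of class `risk_profile`.
#' @export
risk_profile <- function(age, sex, bmi = 25, prior_fracture = FALSE,
                         t_score = NULL, extra_rr = NULL) {
  sex <- match.arg(sex, .SEXES)
  if (!is.null(bmi) && (bmi < 10 || bmi > 60))
    stop("bmi must lie within [10, 60] kg/m2")
  if (!is.null(extra_rr)) {
    extra_rr <- unlist(extra_rr)
    if (any(extra_rr <= 0) || anyNA(extra_rr))
      stop("relative risks must be strictly positive")
  }
  structure(list(age = age, sex = sex, bmi = bmi,
                 prior_fracture = isTRUE(prior_fracture),
                 t_score = t_score, extra_rr = extra_rr),
            class = "risk_profile")
}

#' Risk-factor configuration
#'
#' Holds the user-supplied relative risks and gradients of risk used by
#' [profile_probability()]. The shipped defaults are literature-typical
#' placeholders (prior fracture roughly doubles risk; BMD gradients of
#' risk near 3.7 per SD for hip and 1.6 per SD for MOF are commonly
#' reported); they are configuration values, not calibrated coefficients,
#' and should be replaced with values appropriate to the application.
#'
#' @param rr_prior_fracture named numeric `c(hip = , mof = )` relative
#'   risks (> 0) conferred by a prior fracture.
#' @param gradient_hip,gradient_mof gradient of risk (> 1): multiplicative
#'   increase in fracture risk per SD decrease in femoral-neck BMD.
#' @param t_ref reference mean T-score: either a single number or a
#'   `data.frame(age, t_ref)` interpolated linearly in age (clamped at the
#'   ends).
#' @return An object of class `risk_factor_config`.
#' @export
risk_factor_config <- function(rr_prior_fracture = c(hip = 1.8, mof = 1.8),
                               gradient_hip = 3.7, gradient_mof = 1.6,
                               t_ref = 0) {
  if (length(rr_prior_fracture) == 1L)
    rr_prior_fracture <- c(hip = unname(rr_prior_fracture),
                           mof = unname(rr_prior_fracture))
  if (!all(c("hip", "mof") %in% names(rr_prior_fracture)))
    stop("rr_prior_fracture must name 'hip' and 'mof' entries")
  if (any(rr_prior_fracture <= 0))
    stop("relative risks must be strictly positive")
  if (gradient_hip <= 1 || gradient_mof <= 1)
    stop("gradients of risk must exceed 1")
  if (is.data.frame(t_ref) &&
      !all(c("age", "t_ref") %in% names(t_ref)))
    stop("age-indexed t_ref needs columns 'age' and 't_ref'")
  structure(list(rr_prior_fracture = rr_prior_fracture,
                 gradient_hip = gradient_hip, gradient_mof = gradient_mof,
                 t_ref = t_ref),
            class = "risk_factor_config")
}

.t_ref_at <- function(config, age) {
  tr <- config$t_ref
  if (is.data.frame(tr)) {
    if (nrow(tr) == 1L) return(tr$t_ref[1L])
    stats::approx(tr$age, tr$t_ref, xout = age, rule = 2)$y
  } else {
    tr
  }
}

#' Relative risk implied by a femoral-neck T-score
#'
#' Each SD of BMD below the reference multiplies fracture risk by the
#' gradient of risk: `rr = gradient^(t_ref - t)`.
#'
#' @param t observed T-score (SD units).
#' @param t_ref reference T-score.
#' @param gradient gradient of risk per SD, must exceed 1 (a gradient at
#'   or below 1 is a non-informative or inverted configuration).
#' @return A positive relative risk.
#' @examples
#' rr_from_tscore(-2, t_ref = -1, gradient = 2)   # 2
#' rr_from_tscore(-2.5, t_ref = 0, gradient = 1.5) # 1.5^2.5
#' @export
rr_from_tscore <- function(t, t_ref, gradient) {
  if (gradient <= 1)
    stop("gradient of risk must exceed 1")
  gradient^(t_ref - t)
}

#' Scale a fracture hazard by a relative risk
#'
#' Pointwise multiplication `phi'(a) = rr * phi(a)`; applying `rr1` then
#' `rr2` is exactly applying `rr1 * rr2`.
#'
#' @param phi a [hazard_function()].
#' @param rr strictly positive relative risk.
#' @return The scaled [hazard_function()].
#' @export
apply_relative_risk <- function(phi, rr) {
  stopifnot(inherits(phi, "hazard_function"))
  if (length(rr) != 1L || is.na(rr) || rr <= 0)
    stop("relative risk must be a single strictly positive number")
  phi$values <- phi$values * rr
  phi
}

# Total fracture-hazard multiplier for a profile and outcome.
.profile_rr <- function(profile, config, outcome) {
  rr <- 1
  if (profile$prior_fracture)
    rr <- rr * unname(config$rr_prior_fracture[[outcome]])
  if (!is.null(profile$t_score)) {
    g <- if (outcome == "hip") config$gradient_hip else config$gradient_mof
    rr <- rr * rr_from_tscore(profile$t_score,
                              .t_ref_at(config, profile$age), g)
  }
  if (length(profile$extra_rr))
    rr <- rr * prod(profile$extra_rr)
  rr
}

#' 10-year hip and MOF probabilities for an individual profile
#'
#' Composes the pipeline for one individual: converts the model's
#' schedules to hazards over the needed age range, multiplies the fracture
#' hazards by the profile's total relative risk (prior fracture, T-score
#' and any extra factors compose multiplicatively), and integrates against
#' the unmodified death hazard. With no risk factors the result equals the
#' population-average probability. The probability saturates below 1 for
#' arbitrarily large relative risks through the competing-risk integral
#' itself, never by clipping.
#'
#' @param model a [country_model()] covering `profile$age + horizon`.
#' @param profile a [risk_profile()].
#' @param config a [risk_factor_config()].
#' @param horizon horizon in years (default 10).
#' @return An object of class `probability_result`: a list with `age`,
#'   `sex`, `horizon`, `p_hip`, `p_mof` (probabilities in \[0, 1\]).
#' @export
profile_probability <- function(model, profile,
                                config = risk_factor_config(),
                                horizon = 10) {
  stopifnot(inherits(model, "country_model"),
            inherits(profile, "risk_profile"),
            inherits(config, "risk_factor_config"))
  sched <- model$schedules[[profile$sex]]
  if (is.null(sched))
    stop("model '", model$label, "' has no schedules for sex ", profile$sex)
  start <- floor(profile$age)
  end <- ceiling(profile$age + horizon)
  mu <- to_hazard(sched$mortality, start, end)
  one <- function(outcome) {
    slot <- if (outcome == "hip") "hip" else "mof"
    if (is.null(sched[[slot]]))
      stop("missing ", outcome, " schedule for sex ", profile$sex)
    phi <- to_hazard(sched[[slot]], start, end)
    phi <- apply_relative_risk(phi, .profile_rr(profile, config, outcome))
    ten_year_probability(phi, mu, profile$age, horizon)
  }
  structure(list(age = profile$age, sex = profile$sex, horizon = horizon,
                 p_hip = one("hip"), p_mof = one("mof")),
            class = "probability_result")
}

#' @export
print.probability_result <- function(x, ...) {
  cat(sprintf("%d-year fracture probability, %s age %g:\n",
              round(x$horizon), x$sex, x$age))
  cat(sprintf("  major osteoporotic: %.1f%%\n", 100 * x$p_mof))
  cat(sprintf("  hip:                %.1f%%\n", 100 * x$p_hip))
  invisible(x)
}
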