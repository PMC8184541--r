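# Surrogate MOF incidence: where only hip-fracture incidence is measured,
# the full major-osteoporotic-fracture aggregate is estimated by applying
# age- and sex-specific MOF:hip ratios taken from a population with
# complete site-specific data (classically Malmo, Sweden). Ratios are
# applied to incidence rates, not to probabilities.

#' Derive a MOF incidence schedule from hip incidence
#'
#' Multiplies the hip-fracture rate at each age by the MOF:hip ratio,
#' linearly interpolated in age (ratios vary slowly, so no log scale) and
#' clamped beyond the ratio schedule's range. Output ages equal the hip
#' schedule's ages.
#'
#' @param hip an [age_rate_schedule()] with `kind = "hip_incidence"`.
#' @param ratios a [ratio_schedule()] for the same sex.
#' @return An [age_rate_schedule()] with `kind = "mof_incidence"`.
#' @examples
#' hip <- age_rate_schedule(c(50, 60), c(10, 40), "female", "hip_incidence")
#' rat <- ratio_schedule(c(50, 60), c(4, 2), "female")
#' derive_mof_schedule(hip, rat)
#' @export
derive_mof_schedule <- function(hip, ratios) {
  stopifnot(inherits(hip, "age_rate_schedule"),
            inherits(ratios, "ratio_schedule"))
  if (hip$kind != "hip_incidence")
    stop("input schedule must have kind 'hip_incidence'")
  if (hip$sex != ratios$sex)
    stop("sex mismatch: hip schedule is ", hip$sex,
         ", ratio schedule is ", ratios$sex)
  r <- if (length(ratios$ages) == 1L) {
    rep(ratios$ratios, length(hip$ages))
  } else {
    stats::approx(ratios$ages, ratios$ratios, xout = hip$ages, rule = 2)$y
  }
  age_rate_schedule(hip$ages, hip$rates * r, sex = hip$sex,
                    kind = "mof_incidence", population = hip$population)
}

#' Check that MOF incidence dominates hip incidence pointwise
#'
#' MOF includes hip fracture, so a valid MOF schedule can never fall below
#' the hip schedule at any age. Violations are reported, not raised.
#'
#' @param hip,mof [age_rate_schedule()]s on the same ages, same sex.
#' @return A list with `ok` (logical) and `violating_ages` (numeric,
#'   empty on success).
#' @export
validate_mof_dominance <- function(hip, mof) {
  stopifnot(inherits(hip, "age_rate_schedule"),
            inherits(mof, "age_rate_schedule"))
  if (hip$sex != mof$sex) stop("sex mismatch")
  if (length(hip$ages) != length(mof$ages) ||
      any(abs(hip$ages - mof$ages) > 1e-9))
    stop("schedules must share the same age grid")
  bad <- hip$ages[mof$rates < hip$rates]
  list(ok = length(bad) == 0L, violating_ages = bad)
}
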