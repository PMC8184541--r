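# The buildable, serialisable artifact of the pipeline: hip, MOF and
# mortality schedules per sex plus metadata.

.collect_by_sex <- function(x, slot, kind) {
  if (inherits(x, "age_rate_schedule")) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, logical(1), "age_rate_schedule")))
    stop(slot, " must be an age_rate_schedule or a list of them")
  out <- list()
  for (s in x) {
    if (s$kind != kind)
      stop(slot, " schedule has kind '", s$kind, "', expected '", kind, "'")
    if (!is.null(out[[s$sex]]))
      stop("duplicate ", slot, " schedule for sex ", s$sex)
    out[[s$sex]] <- s
  }
  out
}

#' Bundle fracture and mortality schedules into a country model
#'
#' A `country_model` carries, per sex, the hip-incidence, MOF-incidence and
#' mortality schedules from which 10-year probabilities are computed. Each
#' of `hip`, `mof`, `mortality` may be a single [age_rate_schedule()] or a
#' list of one per sex.
#'
#' @param label country/population label.
#' @param hip hip-incidence schedule(s) (`kind = "hip_incidence"`).
#' @param mof MOF-incidence schedule(s) (`kind = "mof_incidence"`).
#' @param mortality mortality schedule(s) (`kind = "mortality"`).
#' @return An object of class `country_model`.
#' @seealso [build_country_model()] to derive the MOF schedule from hip
#'   incidence and a ratio schedule.
#' @export
country_model <- function(label, hip, mof, mortality) {
  hip <- .collect_by_sex(hip, "hip", "hip_incidence")
  mof <- .collect_by_sex(mof, "mof", "mof_incidence")
  mortality <- .collect_by_sex(mortality, "mortality", "mortality")
  sexes <- union(union(names(hip), names(mof)), names(mortality))
  schedules <- list()
  for (sx in sexes) {
    if (is.null(hip[[sx]]) || is.null(mof[[sx]]) || is.null(mortality[[sx]]))
      stop("incomplete schedule set for sex ", sx,
           ": need hip, mof and mortality")
    schedules[[sx]] <- list(hip = hip[[sx]], mof = mof[[sx]],
                            mortality = mortality[[sx]])
  }
  structure(list(label = label, schedules = schedules),
            class = "country_model")
}

#' @export
print.country_model <- function(x, ...) {
  cat(sprintf("<country_model> %s (sexes: %s)\n",
              x$label, paste(names(x$schedules), collapse = ", ")))
  invisible(x)
}

#' Build a country model from hip incidence, ratio and mortality schedules
#'
#' Derives the MOF incidence schedule from hip incidence via
#' [derive_mof_schedule()] and bundles everything into a [country_model()].
#'
#' @inheritParams country_model
#' @param ratios a [ratio_schedule()] or list of one per sex.
#' @export
build_country_model <- function(label, hip, ratios, mortality) {
  hip_l <- .collect_by_sex(hip, "hip", "hip_incidence")
  if (inherits(ratios, "ratio_schedule")) ratios <- list(ratios)
  rat <- list()
  for (r in ratios) rat[[r$sex]] <- r
  mof <- lapply(names(hip_l), function(sx) {
    if (is.null(rat[[sx]])) stop("no ratio schedule for sex ", sx)
    derive_mof_schedule(hip_l[[sx]], rat[[sx]])
  })
  country_model(label, hip = hip, mof = mof, mortality = mortality)
}

#' Serialise a country model to JSON
#'
#' Writes all schedules and metadata as structured text; the file
#' round-trips through [read_country_model()].
#'
#' @param model a [country_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_country_model <- function(model, path) {
  stopifnot(inherits(model, "country_model"))
  ser <- list(
    format = "fracrisk-country-model",
    version = 1L,
    label = model$label,
    schedules = lapply(model$schedules, function(sl)
      lapply(sl, function(s) s[c("population", "sex", "kind", "ages", "rates")]))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a country model written by [write_country_model()]
#'
#' @param path path to the JSON file.
#' @return A [country_model()].
#' @export
read_country_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$format) || js$format != "fracrisk-country-model")
    stop("not a fracrisk country-model file: ", path)
  rebuild <- function(s)
    age_rate_schedule(s$ages, s$rates, sex = s$sex, kind = s$kind,
                      population = s$population)
  by_sex <- function(slot)
    lapply(js$schedules, function(sl) rebuild(sl[[slot]]))
  country_model(js$label,
                hip = unname(by_sex("hip")),
                mof = unname(by_sex("mof")),
                mortality = unname(by_sex("mortality")))
}
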