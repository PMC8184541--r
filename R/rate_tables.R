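# Age-structured rate tables: typed ingestion, validation and serialisation.

.RATE_KINDS <- c("hip_incidence", "mof_incidence", "mortality")
.SEXES <- c("female", "male")
.AGE_MIN <- 40
.AGE_MAX <- 110

#' Age- and sex-specific event rate schedule
#'
#' An `age_rate_schedule` holds event rates per 100,000 person-years on an
#' age grid for one sex and one population. The same container is used for
#' hip-fracture incidence, surrogate MOF incidence and all-cause mortality;
#' `kind` records which.
#'
#' @param ages numeric vector of ages in years, strictly increasing, within
#'   \[40, 110\].
#' @param rates numeric vector of non-negative, finite event rates per
#'   100,000 person-years, same length as `ages`.
#' @param sex `"female"` or `"male"`.
#' @param kind one of `"hip_incidence"`, `"mof_incidence"`, `"mortality"`.
#' @param population free-text population label.
#' @return An object of class `age_rate_schedule`.
#' @examples
#' age_rate_schedule(c(50, 60, 70), c(10, 40, 160),
#'                   sex = "female", kind = "hip_incidence",
#'                   population = "example")
#' @export
age_rate_schedule <- function(ages, rates, sex, kind, population = "unspecified") {
  sex <- match.arg(sex, .SEXES)
  kind <- match.arg(kind, .RATE_KINDS)
  ages <- as.numeric(ages)
  rates <- as.numeric(rates)
  if (length(ages) == 0L)
    stop("schedule must contain at least one age point")
  if (length(rates) != length(ages))
    stop("ages and rates must have equal length")
  if (anyNA(ages) || any(!is.finite(ages)))
    stop("ages must be finite")
  if (anyNA(rates) || any(!is.finite(rates)))
    stop("rates must be finite")
  if (length(ages) > 1L && any(diff(ages) <= 0))
    stop("ages not increasing")
  if (ages[1L] < .AGE_MIN || ages[length(ages)] > .AGE_MAX)
    stop(sprintf("ages must lie within [%d, %d]", .AGE_MIN, .AGE_MAX))
  if (any(rates < 0))
    stop("negative rate")
  structure(
    list(population = population, sex = sex, kind = kind,
         ages = ages, rates = rates),
    class = "age_rate_schedule"
  )
}

#' @export
print.age_rate_schedule <- function(x, ...) {
  cat(sprintf("<age_rate_schedule> %s, %s, %s\n", x$population, x$sex, x$kind))
  cat(sprintf("  %d age points %g-%g, rates per 100,000 person-years\n",
              length(x$ages), x$ages[1L], x$ages[length(x$ages)]))
  invisible(x)
}

.read_numeric_csv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("CSV ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("malformed row ", bad[1L], ": non-numeric '", cl, "'")
    df[[cl]] <- v
  }
  df
}

#' Read a rate schedule from CSV
#'
#' The file must have a header row and columns `age,rate` (comma-delimited,
#' dot decimal separator). Population, sex and rate kind are metadata and
#' are supplied as arguments, not stored in the file.
#'
#' @param path path to the CSV file.
#' @inheritParams age_rate_schedule
#' @return A validated [age_rate_schedule()].
#' @export
read_rate_schedule <- function(path, kind, sex, population = "unspecified") {
  df <- .read_numeric_csv(path, c("age", "rate"))
  neg <- which(df$rate < 0)
  if (length(neg)) stop("negative rate at row ", neg[1L])
  dup <- which(duplicated(df$age))
  if (length(dup)) stop("duplicate age at row ", dup[1L])
  if (length(df$age) > 1L && any(diff(df$age) <= 0))
    stop("ages not increasing")
  age_rate_schedule(df$age, df$rate, sex = sex, kind = kind,
                    population = population)
}

#' Write a rate schedule to CSV
#'
#' Inverse of [read_rate_schedule()]: writes the `age,rate` columns only
#' (metadata travels out of band).
#'
#' @param schedule an [age_rate_schedule()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rate_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "age_rate_schedule"))
  utils::write.csv(data.frame(age = schedule$ages, rate = schedule$rates),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' MOF:hip incidence ratio schedule
#'
#' Age-specific multipliers that convert hip-fracture incidence into
#' estimated incidence of the major-osteoporotic-fracture aggregate.
#' Because MOF includes hip fracture, every ratio must be at least 1.
#'
#' @param ages strictly increasing ages in years.
#' @param ratios multipliers >= 1, same length as `ages`.
#' @param sex `"female"` or `"male"`.
#' @return An object of class `ratio_schedule`.
#' @export
ratio_schedule <- function(ages, ratios, sex) {
  sex <- match.arg(sex, .SEXES)
  ages <- as.numeric(ages)
  ratios <- as.numeric(ratios)
  if (length(ages) == 0L) stop("ratio schedule must contain at least one age")
  if (length(ratios) != length(ages))
    stop("ages and ratios must have equal length")
  if (anyNA(ages) || anyNA(ratios) || any(!is.finite(ratios)))
    stop("ages and ratios must be finite")
  if (length(ages) > 1L && any(diff(ages) <= 0))
    stop("ages not increasing")
  if (any(ratios < 1))
    stop("ratio < 1: MOF incidence cannot fall below hip incidence")
  structure(list(sex = sex, ages = ages, ratios = ratios),
            class = "ratio_schedule")
}

#' Read a MOF:hip ratio schedule from CSV (columns `age,ratio`)
#'
#' @inheritParams read_rate_schedule
#' @inheritParams ratio_schedule
#' @return A validated [ratio_schedule()].
#' @export
read_ratio_schedule <- function(path, sex) {
  df <- .read_numeric_csv(path, c("age", "ratio"))
  ratio_schedule(df$age, df$ratio, sex = sex)
}

#' Standard population age weights
#'
#' Contiguous, non-overlapping `[lower, upper)` age bands with non-negative
#' weights, used by [age_standardise()]. Weights need not sum to 1 until
#' [normalise()] is applied.
#'
#' @param age_lower,age_upper numeric vectors of band bounds in years.
#' @param weights non-negative weights, one per band.
#' @return An object of class `standard_population`.
#' @export
standard_population <- function(age_lower, age_upper, weights) {
  age_lower <- as.numeric(age_lower)
  age_upper <- as.numeric(age_upper)
  weights <- as.numeric(weights)
  n <- length(age_lower)
  if (n == 0L) stop("at least one age band required")
  if (length(age_upper) != n || length(weights) != n)
    stop("age_lower, age_upper and weights must have equal length")
  if (any(age_upper <= age_lower))
    stop("each band must satisfy upper > lower")
  if (n > 1L && any(abs(age_lower[-1L] - age_upper[-n]) > 1e-9))
    stop("bands must be contiguous and non-overlapping")
  if (any(weights < 0) || anyNA(weights))
    stop("weights must be non-negative")
  structure(list(age_lower = age_lower, age_upper = age_upper,
                 weights = weights),
            class = "standard_population")
}

#' Read a standard population from CSV (columns `age_lower,age_upper,weight`)
#'
#' @inheritParams read_rate_schedule
#' @return A [standard_population()].
#' @export
read_standard_population <- function(path) {
  df <- .read_numeric_csv(path, c("age_lower", "age_upper", "weight"))
  standard_population(df$age_lower, df$age_upper, df$weight)
}

#' Normalise weights to sum to one
#'
#' @param x object whose weights should be rescaled.
#' @param ... passed to methods.
#' @return The object with weights summing to 1.
#' @export
normalise <- function(x, ...) UseMethod("normalise")

#' @rdname normalise
#' @export
normalise.standard_population <- function(x, ...) {
  s <- sum(x$weights)
  if (s <= 0) stop("cannot normalise: all weights are zero")
  x$weights <- x$weights / s
  x
}

#' Populations-by-ages grid of 10-year fracture probabilities
#'
#' @param outcome `"hip"` or `"mof"`.
#' @param populations character vector of population labels (rows).
#' @param ages numeric vector of ages (columns).
#' @param values numeric matrix, `length(populations)` x `length(ages)`,
#'   of 10-year probabilities in percent (0-100).
#' @return An object of class `probability_grid`.
#' @export
probability_grid <- function(outcome, populations, ages, values) {
  outcome <- match.arg(outcome, c("hip", "mof"))
  values <- as.matrix(values)
  if (nrow(values) != length(populations) || ncol(values) != length(ages))
    stop("values must be a populations x ages matrix")
  if (anyNA(values) || any(values < 0) || any(values > 100))
    stop("probabilities must lie in [0, 100] percent")
  dimnames(values) <- list(populations, as.character(ages))
  structure(list(outcome = outcome, populations = populations,
                 ages = as.numeric(ages), values = values),
            class = "probability_grid")
}

#' @export
print.probability_grid <- function(x, ...) {
  cat(sprintf("<probability_grid> outcome = %s, %d populations x %d ages (%%)\n",
              x$outcome, length(x$populations), length(x$ages)))
  print(x$values)
  invisible(x)
}

#' Look up one cell of a probability grid
#'
#' @param grid a [probability_grid()].
#' @param population population label.
#' @param age age in years.
#' @return The probability in percent.
#' @export
grid_value <- function(grid, population, age) {
  stopifnot(inherits(grid, "probability_grid"))
  if (!population %in% grid$populations)
    stop("population not in grid: ", population)
  j <- match(age, grid$ages)
  if (is.na(j)) stop("age not in grid: ", age)
  grid$values[population, j]
}

#' Load the packaged six-population probability grid
#'
#' Returns the packaged reference grid of published 10-year probabilities
#' (percent) of major osteoporotic fracture and of hip fracture for women
#' with a prior fracture (BMI 25 kg/m2), for Botswana, South Africa (Black
#' and Coloured), Morocco, Tunisia and US Blacks at ages 50 to 90 in 5-year
#' steps, exactly as printed in the source model comparison (including
#' integer-rounded cells and the non-monotone old-age hip values).
#'
#' @return A list with elements `mof` and `hip`, each a [probability_grid()].
#' @examples
#' tab <- load_table1_fixture()
#' grid_value(tab$mof, "Botswana", 50)
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_10yr_probabilities.csv",
                      package = "fracrisk", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  make_grid <- function(outc) {
    sub <- df[df$outcome == outc, , drop = FALSE]
    pops <- unique(sub$population)
    ages <- sort(unique(sub$age))
    m <- matrix(NA_real_, length(pops), length(ages),
                dimnames = list(pops, as.character(ages)))
    m[cbind(match(sub$population, pops), match(sub$age, ages))] <-
      sub$probability_pct
    probability_grid(outc, pops, ages, m)
  }
  list(mof = make_grid("mof"), hip = make_grid("hip"))
}
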