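test_that("age_rate_schedule enforces its invariants", {
  s <- age_rate_schedule(c(50, 60, 70), c(10, 40, 160),
                         sex = "female", kind = "hip_incidence")
  expect_s3_class(s, "age_rate_schedule")
  expect_length(s$ages, 3)

  expect_error(age_rate_schedule(c(60, 50), c(1, 2), "female",
                                 "hip_incidence"), "not increasing")
  expect_error(age_rate_schedule(50, -1, "female", "hip_incidence"),
               "negative rate")
  expect_error(age_rate_schedule(c(50, 60), 1, "female", "hip_incidence"),
               "equal length")
  expect_error(age_rate_schedule(c(30, 50), c(1, 2), "female",
                                 "hip_incidence"), "within")
  expect_error(age_rate_schedule(50, Inf, "female", "hip_incidence"),
               "finite")
  expect_error(age_rate_schedule(numeric(0), numeric(0), "female",
                                 "hip_incidence"), "at least one")
})

test_that("read_rate_schedule parses valid files and names bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,rate", "50,10", "60,40", "70,160"), path)
  s <- read_rate_schedule(path, kind = "hip_incidence", sex = "female")
  expect_equal(s$ages, c(50, 60, 70))
  expect_equal(s$rates, c(10, 40, 160))

  writeLines(c("age,rate", "60,10", "50,40"), path)
  expect_error(read_rate_schedule(path, "hip_incidence", "female"),
               "not increasing")
  writeLines(c("age,rate", "50,10", "60,-1"), path)
  expect_error(read_rate_schedule(path, "hip_incidence", "female"),
               "negative rate at row 2")
  writeLines(c("age,rate", "50,10", "50,11"), path)
  expect_error(read_rate_schedule(path, "hip_incidence", "female"),
               "duplicate age at row 2")
  writeLines(c("age,rate", "50,ten"), path)
  expect_error(read_rate_schedule(path, "hip_incidence", "female"),
               "malformed row 1")
  writeLines(c("age,wrong", "50,10"), path)
  expect_error(read_rate_schedule(path, "hip_incidence", "female"),
               "required column")
})

test_that("write/read rate schedule round-trips valid schedules", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(7)
  for (i in 1:5) {
    ages <- sort(sample(40:110, sample(3:12, 1)))
    rates <- round(stats::runif(length(ages), 0, 5000), 3)
    s <- age_rate_schedule(ages, rates, sex = "male", kind = "mortality",
                           population = "roundtrip")
    write_rate_schedule(s, path)
    back <- read_rate_schedule(path, kind = "mortality", sex = "male",
                               population = "roundtrip")
    expect_equal(back, s)
  }
})

test_that("ratio schedules reject ratios below one", {
  r <- ratio_schedule(c(50, 60), c(4, 2), "female")
  expect_s3_class(r, "ratio_schedule")
  expect_error(ratio_schedule(c(50, 60), c(0.9, 2), "female"), "ratio < 1")
  expect_error(ratio_schedule(c(60, 50), c(2, 2), "female"),
               "not increasing")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,ratio", "50,4", "60,2"), path)
  expect_equal(read_ratio_schedule(path, "female"), r)
})

test_that("standard populations validate bands and normalise weights", {
  p <- standard_population(c(50, 60, 70), c(60, 70, 80), c(2, 2, 4))
  expect_equal(normalise(p)$weights, c(0.25, 0.25, 0.5))
  expect_equal(normalise(standard_population(50, 60, 3))$weights, 1)
  expect_error(normalise(standard_population(c(50, 60), c(60, 70),
                                             c(0, 0))), "all weights")
  expect_error(standard_population(c(50, 70), c(60, 80), c(1, 1)),
               "contiguous")
  expect_error(standard_population(50, 50, 1), "upper > lower")
  expect_error(standard_population(c(50, 55), c(60, 65), c(1, 1)),
               "contiguous")
})

test_that("the packaged probability grid matches the printed table", {
  tab <- load_table1_fixture()
  expect_named(tab, c("mof", "hip"))
  for (g in tab) {
    expect_s3_class(g, "probability_grid")
    expect_length(g$populations, 6)
    expect_equal(g$ages, seq(50, 90, 5))
    expect_false(anyNA(g$values))
  }
  expect_equal(grid_value(tab$mof, "Botswana", 50), 1.6)
  expect_equal(grid_value(tab$hip, "US Black", 80), 5.3)
  # non-monotone old-age tail preserved exactly as printed
  expect_equal(grid_value(tab$hip, "Botswana", 85), 1.7)
  expect_equal(grid_value(tab$hip, "Botswana", 90), 1.5)
  expect_equal(grid_value(tab$mof, "South Africa, Coloured", 75), 11)
  expect_equal(grid_value(tab$mof, "Tunisia", 90), 3.4)
  expect_equal(grid_value(tab$hip, "Morocco", 65), 1.6)

  # MOF dominates hip at every (population, age) cell
  expect_true(all(tab$mof$values >= tab$hip$values))
})

test_that("probability_grid validates and indexes cells", {
  g <- probability_grid("hip", c("A", "B"), c(50, 60),
                        matrix(c(1, 2, 3, 4), 2))
  expect_equal(grid_value(g, "B", 60), 4)
  expect_error(grid_value(g, "C", 60), "population not in grid")
  expect_error(grid_value(g, "A", 70), "age not in grid")
  expect_error(probability_grid("hip", "A", 50, matrix(101)), "0, 100")
  expect_error(probability_grid("hip", "A", c(50, 60), matrix(1)),
               "populations x ages")
})
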