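test_that("gompertz_schedule evaluates the closed form", {
  flat <- gompertz_schedule(gompertz_params(10, 50, 0), seq(50, 90, 10),
                            "hip_incidence", "female")
  expect_equal(flat$rates, rep(10, 5))

  # doubling every 5 years
  dbl <- gompertz_schedule(gompertz_params(10, 50, log(2) / 5),
                           c(50, 55, 60, 90), "hip_incidence", "female")
  expect_equal(dbl$rates, c(10, 20, 40, 10 * 2^8), tolerance = 1e-12)

  # Makeham term adds a constant hazard (x 100,000 on the rate scale)
  mk <- gompertz_schedule(gompertz_params(10, 50, 0, makeham = 0.002),
                          c(50, 70), "mortality", "female")
  expect_equal(mk$rates, c(210, 210))

  expect_error(gompertz_params(0, 50, 0.1), "positive")
  expect_error(gompertz_params(10, 50, -0.1), "non-negative")
})

test_that("sample_counts is Poisson with the stated mean and reproducible", {
  ages <- seq(50, 90, 1)  # 41 iid draws per call at a flat rate
  sched <- gompertz_schedule(gompertz_params(100, 50, 0), ages,
                             "hip_incidence", "female")
  draws <- unlist(lapply(1:30, function(s)
    sample_counts(sched, 1e5, seed = s)$count))
  # mean 100, variance 100 within Monte-Carlo error (n = 1230)
  expect_equal(mean(draws), 100, tolerance = 0.015)
  expect_equal(stats::var(draws), 100, tolerance = 0.2)

  # zero rate gives zero counts
  z <- sample_counts(gompertz_schedule(gompertz_params(1e-12, 50, 0),
                                       ages, "hip_incidence", "female"),
                     1e5, seed = 1)
  expect_true(all(z$count == 0))

  # determinism under a fixed seed
  expect_identical(sample_counts(sched, 1e5, seed = 7),
                   sample_counts(sched, 1e5, seed = 7))
  expect_error(sample_counts(sched, 0, seed = 1), "positive")
})

test_that("estimate_rates returns exact Garwood intervals", {
  cts <- data.frame(age = c(50, 60, 70), count = c(5, 0, 10),
                    person_years = c(5e4, 1e5, 1e5))
  est <- estimate_rates(cts, sex = "female")
  expect_equal(est$rates, c(10, 0, 10))
  expect_equal(est$ci$lower[2], 0)
  # 10 events in 100,000 PY: 95% CI (4.80, 18.39) per 100,000
  expect_equal(est$ci$lower[3], 4.80, tolerance = 0.005)
  expect_equal(est$ci$upper[3], 18.39, tolerance = 0.005)
  # interval brackets the point estimate
  expect_true(all(est$ci$lower <= est$ci$rate))
  expect_true(all(est$ci$upper >= est$ci$rate))
})

test_that("log-linear fit on estimated rates recovers the Gompertz slope", {
  ages <- seq(50, 90, 5)
  true_slope <- 0.08
  sched <- gompertz_schedule(gompertz_params(13, 50, true_slope), ages,
                             "hip_incidence", "female")
  cts <- sample_counts(sched, 1e6, seed = 123)
  est <- estimate_rates(cts, sex = "female")
  fit <- stats::lm(log(rate) ~ age, data = est$ci)
  se <- summary(fit)$coefficients["age", "Std. Error"]
  expect_lt(abs(stats::coef(fit)[["age"]] - true_slope), 3 * se)
})

test_that("make_synthetic_country builds a coherent, reproducible model", {
  m <- make_synthetic_country()
  expect_s3_class(m, "country_model")
  expect_setequal(names(m$schedules), c("female", "male"))
  for (sx in names(m$schedules)) {
    sl <- m$schedules[[sx]]
    expect_true(validate_mof_dominance(sl$hip, sl$mof)$ok)
  }

  # negligible mortality: probabilities reduce to 1 - exp(-cum phi)
  tiny_mu <- list(female = gompertz_params(1e-9, 50, 0))
  m0 <- make_synthetic_country(mortality_params = tiny_mu)
  sl <- m0$schedules$female
  phi <- to_hazard(sl$hip, 50, 100)
  mu <- to_hazard(sl$mortality, 50, 100)
  p <- ten_year_probability(phi, mu, 55)
  expect_equal(p, 1 - exp(-sum(hazard_at(phi, 55:64 + 0.5))),
               tolerance = 1e-8)

  # small-hazard linearisation: scaling incidence by c scales probability
  # by ~c as rates -> 0
  lo <- make_synthetic_country(list(female = gompertz_params(0.1, 50, 0)),
                               tiny_mu)
  hi <- make_synthetic_country(list(female = gompertz_params(0.3, 50, 0)),
                               tiny_mu)
  p_lo <- ten_year_probability(to_hazard(lo$schedules$female$hip, 50, 100),
                               mu, 60)
  p_hi <- ten_year_probability(to_hazard(hi$schedules$female$hip, 50, 100),
                               mu, 60)
  expect_equal(p_hi / p_lo, 3, tolerance = 1e-4)

  # seeded sampling path serialises identically across runs
  path1 <- withr::local_tempfile(fileext = ".json")
  path2 <- withr::local_tempfile(fileext = ".json")
  write_country_model(make_synthetic_country(person_years = 1e6,
                                             seed = 42), path1)
  write_country_model(make_synthetic_country(person_years = 1e6,
                                             seed = 42), path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("pipeline probabilities converge to truth as exposure grows", {
  curve_of <- function(m) {
    sl <- m$schedules$female
    probability_curve(to_hazard(sl$mof, 50, 100),
                      to_hazard(sl$mortality, 50, 100),
                      c(55, 70, 85))$probability_pct
  }
  pt <- curve_of(make_synthetic_country())  # exact rates
  pe <- curve_of(make_synthetic_country(person_years = 1e7, seed = 202))
  expect_equal(pe, pt, tolerance = 0.02)
})

test_that("write_synthetic_inputs feeds the file-based pipeline", {
  dir <- withr::local_tempdir()
  manifest <- write_synthetic_inputs(dir, seed = 9)
  expect_true(file.exists(file.path(dir, "hip_female.csv")))
  expect_true(file.exists(file.path(dir, "mortality_male.csv")))
  expect_true(file.exists(manifest))

  hip <- read_rate_schedule(file.path(dir, "hip_female.csv"),
                            "hip_incidence", "female")
  rat <- read_ratio_schedule(file.path(dir, "ratios_female.csv"), "female")
  mort <- read_rate_schedule(file.path(dir, "mortality_female.csv"),
                             "mortality", "female")
  model <- build_country_model("rebuilt", hip, rat, mort)
  expect_s3_class(model, "country_model")
  expect_true(validate_mof_dominance(model$schedules$female$hip,
                                     model$schedules$female$mof)$ok)
})
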