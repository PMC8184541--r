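# Independent discrete-time oracle for the competing-risk integral:
# midpoint quadrature of phi(t) * exp(-H(t)) with daily steps, where the
# cumulative hazard H is accumulated step by step. Shares no code with
# ten_year_probability()'s per-interval closed form.
oracle_probability <- function(phi, mu, age, horizon, steps_per_year = 365) {
  h <- 1 / steps_per_year
  n <- round(horizon * steps_per_year)
  t_mid <- age + (seq_len(n) - 0.5) * h
  f <- hazard_at(phi, t_mid)
  g <- hazard_at(mu, t_mid)
  lam <- f + g
  H_mid <- cumsum(lam * h) - lam * h / 2
  sum(f * exp(-H_mid) * h)
}

# Random piecewise-constant hazard pair over [start, end), fracture
# hazards up to 0.05/yr and death hazards up to 0.2/yr (beyond the
# magnitudes seen in fracture epidemiology, to stress the engine).
random_hazard_pair <- function(start = 50, end = 70) {
  n <- end - start
  list(phi = hazard_function(start, end, stats::runif(n, 0, 0.05)),
       mu = hazard_function(start, end, stats::runif(n, 0, 0.2)))
}

# Small valid schedules for reuse across tests.
flat_schedule <- function(rate, kind = "hip_incidence", sex = "female",
                          ages = c(40, 110)) {
  age_rate_schedule(ages, rep(rate, length(ages)), sex = sex, kind = kind)
}

# Constant-rate country model: hip rate, mof rate and mortality rate per
# 100,000 person-years at all ages.
flat_model <- function(hip = 1000, mof = 2000, mortality = 5000,
                       sex = "female", label = "flat") {
  country_model(
    label,
    hip = flat_schedule(hip, "hip_incidence", sex),
    mof = flat_schedule(mof, "mof_incidence", sex),
    mortality = flat_schedule(mortality, "mortality", sex)
  )
}
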