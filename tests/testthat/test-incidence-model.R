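test_that("threshold map uses the natural log and hits the death parameters", {
  hp <- hazard_params_from_threshold(17, ct_default)
  expect_lt(abs(hp$a - 0.132) / 0.132, 0.01)
  expect_lt(abs(hp$A - 2.22e-6) / 2.22e-6, 0.02)
  expect_lt(abs(hp$b - 9.774e-6) / 9.774e-6, 0.02)
  expect_error(hazard_params_from_threshold(0), "xc > 0")
  expect_error(hazard_params_from_threshold(-3), "xc > 0")
})

test_that("hazard evaluates the logistic form stably at all ages", {
  hp <- death_hazard_params(ct_default)
  expect_equal(hazard(0, hp), hp$A / (1 + hp$b))
  # direct double-precision evaluation is exact (no overflow) at t = 80
  direct <- hp$A * exp(hp$a * 80) / (1 + hp$b * exp(hp$a * 80))
  expect_equal(hazard(80, hp), direct, tolerance = 1e-12)
  # saturated regime where the direct form overflows
  expect_equal(hazard(1e4, hp), hp$A / hp$b, tolerance = 1e-12)
  # rising limb: h ~ A e^{at} while b e^{at} << 1
  expect_equal(hazard(10, hp), hp$A * exp(hp$a * 10), tolerance = 1e-4)
})

test_that("survival is the exact integral of the hazard", {
  expect_equal(survival(0, death_hazard_params(ct_default)), 1)
  set.seed(42)
  for (i in 1:20) {
    hp <- hazard_params(A = 10^stats::runif(1, -7, -1),
                        b = 10^stats::runif(1, -6, 1),
                        a = stats::runif(1, 0.01, 0.2))
    ts <- stats::runif(3, 0, 110)
    expect_equal(survival(ts, hp), quad_survival(ts, hp),
                 tolerance = 1e-8)
  }
  # a -> 0 limit form
  hp0 <- hazard_params(1e-3, 0.5, 0)
  expect_equal(survival(c(10, 50), hp0), quad_survival(c(10, 50), hp0),
               tolerance = 1e-10)
  # vanishing amplitude: no events, survival sticks at 1
  expect_equal(survival(200, hazard_params(1e-300, 0.5, 0.1)), 1)
})

test_that("survival_inverse round-trips through survival", {
  hp <- hazard_params_from_threshold(14, ct_default)
  p <- c(1, 0.9, 0.5, 0.1, 1e-4)
  expect_equal(survival(survival_inverse(p, hp), hp), p, tolerance = 1e-9)
})

test_that("two-parameter incidence obeys its closed-form identities", {
  hp <- hazard_params_from_threshold(14, ct_default)
  t <- seq(0, 109, by = 1)
  # s = 1: denominator collapses, incidence is the pure hazard
  expect_equal(incidence_2p(t, disease_model(14, 1), ct_default),
               hazard(t, hp))
  # t = 0: both survivals are 1
  for (s in c(1e-3, 0.1, 0.7)) {
    expect_equal(incidence_2p(0, disease_model(14, s), ct_default),
                 s * hp$A / (1 + hp$b))
  }
  # rare-disease limit: I/s independent of s within 1%
  t2 <- seq(0, 90, by = 1)
  i1 <- incidence_2p(t2, disease_model(14, 1e-3), ct_default) / 1e-3
  i2 <- incidence_2p(t2, disease_model(14, 1e-5), ct_default) / 1e-5
  expect_lt(max(abs(i1 / i2 - 1)), 0.01)
})

test_that("incidence declines at old ages only for partial susceptibility", {
  t <- seq(0, 109, by = 0.5)
  inc <- incidence_2p(t, disease_model(14, 0.1), ct_default)
  expect_lt(inc[length(inc)], max(inc))          # late decline
  expect_lt(t[which.max(inc)], 100)              # interior peak
  inc1 <- incidence_2p(t, disease_model(14, 1), ct_default)
  expect_true(all(diff(inc1) >= 0))              # pure hazard never declines
  # incidence never exceeds the hazard at the lowest threshold in support
  hp <- hazard_params_from_threshold(14, ct_default)
  expect_true(all(inc <= hazard(t, hp) + 1e-15))
  expect_true(all(inc >= 0))
})

test_that("threshold-distribution incidence matches a fine-grid oracle", {
  m <- disease_model(14, 0.1, sigma = 2)
  t <- c(10, 40, 60, 80, 100)
  expect_equal(incidence_3p(t, m, ct_default),
               riemann_incidence_3p(t, m, ct_default),
               tolerance = 1e-6)
})

test_that("sigma = 0 reduces the three-parameter model to two parameters", {
  t <- seq(0, 109, by = 1)
  m0 <- disease_model(14, 0.1, sigma = 0)
  expect_identical(incidence_3p(t, m0, ct_default),
                   incidence_2p(t, m0, ct_default))
  m_eps <- disease_model(14, 0.1, sigma = 1e-6)
  expect_equal(incidence_3p(t, m_eps, ct_default),
               incidence_2p(t, m0, ct_default), tolerance = 1e-8)
})

test_that("widening the threshold distribution flattens the log-slope", {
  t <- seq(30, 80, by = 1)
  slopes <- vapply(c(0, 1.5, 3), function(sg) {
    inc <- incidence_3p(t, disease_model(14, 0.05, sg), ct_default)
    stats::coef(stats::lm(log(inc) ~ t))[[2]]
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("the age of maximal incidence rises linearly with the threshold", {
  xcs <- 12:16
  peaks <- vapply(xcs, function(xc) {
    peak_age(disease_model(xc, 0.01), ct_default)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  fit <- stats::lm(peaks ~ xcs)
  expect_gt(summary(fit)$r.squared, 0.95)
  # monotone (pure-hazard) curve exercises the endpoint warning
  expect_warning(pa <- peak_age(disease_model(14, 1), ct_default),
                 "monotone")
  expect_equal(pa, 110)
})

test_that("thresholds beyond the death threshold are allowed but flagged", {
  expect_warning(m <- disease_model(20, 0.3), "death threshold")
  expect_silent(inc <- incidence_2p(c(60, 80), m, ct_default))
  expect_true(all(is.finite(inc)))
})
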