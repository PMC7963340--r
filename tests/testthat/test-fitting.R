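test_that("mean log-slope is exact on exponential and flat curves", {
  ages <- 30:80
  cv <- incidence_curve(ages, 2e-4 * exp(0.07 * ages))
  expect_equal(mean_log_slope(cv), 0.07, tolerance = 1e-12)
  flat <- incidence_curve(ages, rep(1e-3, length(ages)))
  expect_equal(mean_log_slope(flat), 0, tolerance = 1e-12)
  sparse <- incidence_curve(c(40, 50, 60), c(0, 0, 1e-3))
  expect_error(mean_log_slope(sparse), "at least 3")
})

test_that("synthetic two-parameter curves land in the age-related regime", {
  cv <- model_curve(disease_model(14, 0.05), ages = seq(0.5, 99.5, 1),
                    constants = ct_default)
  slope <- mean_log_slope(cv)
  expect_gt(slope, 0.03)
  expect_lt(slope, 0.15)
  # finite-difference oracle over the same window
  sel <- cv$age >= 30 & cv$age <= 80
  fd <- mean(diff(log(cv$incidence[sel])) / diff(cv$age[sel]))
  expect_equal(slope, fd, tolerance = 0.1)  # OLS vs mean finite difference
})

test_that("age-relatedness classification uses left-closed slope bands", {
  expect_equal(classify_age_related(0.08), "strong")
  expect_equal(classify_age_related(0.07), "strong")
  expect_equal(classify_age_related(0.0699), "mild")
  expect_equal(classify_age_related(0.03), "mild")
  expect_equal(classify_age_related(0.0299), "not")
  expect_equal(classify_age_related(0.01), "not")
  expect_equal(classify_age_related(-0.5), "not")
  expect_error(classify_age_related(Inf), "finite")
})

test_that("r_squared matches hand-computed sums of squares", {
  obs <- c(1, 2, 3, 5)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  # SS_res = 0.5, SS_tot = 8.75 -> R^2 = 1 - 0.5/8.75
  pred <- c(1.5, 2, 2.5, 5)
  expect_equal(r_squared(obs, pred), 1 - 0.5 / 8.75)
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero variance")
})

test_that("noiseless two-parameter round trip recovers the generator", {
  cv <- model_curve(disease_model(14, 0.1), ages = seq(0.5, 109.5, 1),
                    constants = ct_default)
  fit <- fit_2p(cv, ct_default)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$xc - 14), 0.1)
  expect_lt(abs(fit$model$s / 0.1 - 1), 0.02)
  expect_gt(fit$r_squared, 0.999)
})

test_that("two-parameter recovery survives 5% multiplicative noise", {
  cv <- synthetic_curve(disease_model(14, 0.1), seed = 7, noise = 0.05,
                        constants = ct_default)
  fit <- fit_2p(cv, ct_default)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$xc - 14), 0.5)
  expect_lt(abs(fit$model$s / 0.1 - 1), 0.2)
})

test_that("a flat curve yields an honest non-explanatory fit", {
  flat <- incidence_curve(seq(30.5, 79.5, 1), rep(2e-3, 50))
  fit <- fit_2p(flat, ct_default)
  expect_true(fit$converged)
  expect_lte(fit$r_squared, 0)
})

test_that("noiseless three-parameter round trip recovers all parameters", {
  cv <- model_curve(disease_model(14, 0.1, sigma = 2),
                    ages = seq(0.5, 109.5, 1), constants = ct_default)
  fit <- fit_3p(cv, ct_default)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$xc - 14), 0.3)
  expect_lt(abs(fit$model$sigma - 2), 0.4)
  expect_lt(abs(fit$model$s / 0.1 - 1), 0.1)
  expect_gt(fit$r_squared, 0.999)
})

test_that("three-parameter fits respect the nested-model structure", {
  cv <- model_curve(disease_model(13, 0.05), ages = seq(0.5, 109.5, 1),
                    constants = ct_default)
  f2 <- fit_2p(cv, ct_default)
  f3 <- fit_3p(cv, ct_default)
  expect_lte(f3$model$sigma, 0.2)          # sigma = 0 generator
  expect_lte(f3$loss, f2$loss + 1e-10)     # nesting: 3p never worse
  noisy <- synthetic_curve(disease_model(13, 0.05, 1), seed = 3,
                           noise = 0.05, constants = ct_default)
  expect_lte(fit_3p(noisy, ct_default)$loss,
             fit_2p(noisy, ct_default)$loss + 1e-10)
})

test_that("rescaling incidence moves s, not the threshold", {
  cv <- synthetic_curve(disease_model(14, 0.05), seed = 5, noise = 0.02,
                        constants = ct_default)
  f1 <- fit_2p(cv, ct_default)
  cv2 <- incidence_curve(cv$age, cv$incidence * 2)
  f2 <- fit_2p(cv2, ct_default)
  expect_gt(f2$model$s, f1$model$s)
  expect_lt(abs(f2$model$xc - f1$model$xc), 0.5)
})

test_that("count-based weights are used when available", {
  m <- disease_model(14, 0.1)
  ages <- seq(0.5, 99.5, 1)
  py <- rep(1e5, length(ages))
  cases <- round(incidence_2p(ages, m, ct_default) * py)
  cv <- incidence_curve(ages, cases / py, cases, py)
  fit <- fit_2p(cv, ct_default)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$xc - 14), 0.5)
  expect_gt(fit$r_squared, 0.99)
})

test_that("fits refuse curves with too few points", {
  cv <- incidence_curve(c(50, 60, 70), c(1e-3, 2e-3, 4e-3))
  expect_error(fit_2p(cv), "at least 4")
  cv4 <- incidence_curve(c(50, 60, 70, 80), c(1e-3, 2e-3, 4e-3, 8e-3))
  expect_error(fit_3p(cv4), "at least 5")
})
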