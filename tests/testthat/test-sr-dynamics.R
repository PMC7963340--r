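test_that("degenerate SR limits are exact", {
  # no production, no noise: the process never leaves zero
  p0 <- sr_parameters(eta = 0, beta = 1, kappa = 1, epsilon = 0)
  tr <- simulate_trajectory(p0, horizon = 20, dt = 0.05, seed = 1)
  expect_true(all(tr$values == 0))
  # negligible removal, no noise: X(t) = eta t^2 / 2 (Euler error O(dt))
  p1 <- sr_parameters(eta = 0.1, beta = 1, kappa = 1e9, epsilon = 0)
  tr1 <- simulate_trajectory(p1, horizon = 50, dt = 0.01, seed = 1)
  expect_equal(tr1$values[length(tr1$values)], 0.1 * 50^2 / 2,
               tolerance = 1e-3)
  expect_error(simulate_trajectory(p1, horizon = 0, dt = 0.01),
               "horizon")
  expect_error(simulate_trajectory(p1, horizon = 10, dt = -1), "dt")
})

test_that("identical seeds give bit-identical trajectories", {
  p <- sr_cal()
  a <- simulate_trajectory(p, horizon = 30, dt = 0.02, seed = 99)
  b <- simulate_trajectory(p, horizon = 30, dt = 0.02, seed = 99)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0))
  expect_equal(length(a$times), length(a$values))
})

test_that("coarse-step sample means agree with a 10x finer integration", {
  p <- sr_cal()
  n <- 2000
  probe <- function(dt) {
    set.seed(5)
    res <- srincidence:::sr_engine(p, n = n, dt = dt, horizon = 90,
                                   save_every = as.integer(30 / dt),
                                   n_save = n)
    res$paths[[1]][c(2, 3, 4), ]  # ages 30, 60, 90
  }
  coarse <- probe(0.05)
  fine <- probe(0.005)
  for (r in 1:3) {
    se <- sqrt(stats::var(coarse[r, ]) / n + stats::var(fine[r, ]) / n)
    expect_lt(abs(mean(coarse[r, ]) - mean(fine[r, ])),
              3 * se + 0.02 * mean(fine[r, ]))
  }
})

test_that("first-passage sampling respects its contract", {
  p <- sr_cal()
  expect_error(first_passage_times(p, threshold = 0, n = 10), "positive")
  expect_error(first_passage_times(p, threshold = -2, n = 10), "positive")
  # starting at or above the threshold crosses immediately
  set.seed(1)
  res <- srincidence:::sr_engine(p, n = 50, dt = 0.01, horizon = 1,
                                 thresholds = 0.5, x0 = 1)
  expect_true(all(res$crossings[[1]][, 1] == 0))
  fp <- first_passage_times(p, 17, n = 500, dt = 0.05, horizon = 110,
                            seed = 3)
  expect_true(all(is.na(fp$ages) | fp$ages <= fp$horizon))
  expect_equal(sum(is.na(fp$ages)) + sum(!is.na(fp$ages)), fp$n)
})

test_that("crossing ages are monotone in the threshold on shared noise", {
  p <- sr_cal()
  set.seed(11)
  res <- srincidence:::sr_engine(p, n = 300, dt = 0.02, horizon = 110,
                                 thresholds = c(12, 14, 16))
  cr <- res$crossings[[1]]
  cr[is.na(cr)] <- Inf
  expect_true(all(cr[, 1] <= cr[, 2]))
  expect_true(all(cr[, 2] <= cr[, 3]))
  # crossing fraction at the death threshold is monotone in the horizon
  fr <- colMeans(!is.infinite(cr))
  expect_true(all(fr >= 0 & fr <= 1))
  crossed_by <- function(h) mean(cr[, 3] <= h)
  expect_true(all(diff(vapply(c(70, 90, 110), crossed_by,
                              numeric(1))) >= 0))
})

test_that("empirical hazard saturates when everyone crosses at once", {
  sm <- structure(list(threshold = 5, ages = rep(2, 40), n = 40L,
                       seed = 1L, horizon = 10),
                  class = "first_passage_sample")
  eh <- empirical_hazard(sm, bin_width = 5)
  expect_equal(eh$incidence[1], 1 / 5)   # 40 crossers / (40 * 5 py)
  expect_equal(nrow(eh), 1L)             # no one left at risk afterwards
  expect_error(empirical_hazard(structure(list(threshold = 5,
                                               ages = numeric(0), n = 0L,
                                               seed = 1L, horizon = 10),
                                          class = "first_passage_sample")),
               "empty")
})

test_that("empirical hazard recovers the analytic hazard from inverse-CDF draws", {
  hp <- hazard_params_from_threshold(14, ct_default)
  n <- 50000
  set.seed(8)
  ages <- survival_inverse(stats::runif(n), hp)
  ages[ages > 110] <- NA
  sm <- structure(list(threshold = 14, ages = ages, n = as.integer(n),
                       seed = 8L, horizon = 110),
                  class = "first_passage_sample")
  eh <- empirical_hazard(sm, bin_width = 5)
  sel <- eh$cases >= 10
  target <- bin_hazard_target(eh$age[sel] - 2.5, eh$age[sel] + 2.5, hp)
  # binomial error of the per-bin crossing probability
  n_risk <- eh$person_years[sel] / 5
  se <- sqrt(target * 5 * (1 - target * 5) / n_risk) / 5
  expect_true(all(abs(eh$incidence[sel] - target) < 4 * se))
  expect_lt(mean(abs(eh$incidence[sel] - target) / se), 1.5)
})

test_that("calibrated parameters reproduce the death-hazard slope", {
  p <- sr_cal()
  fp <- first_passage_times(p, 17, n = 8000, dt = 0.05, horizon = 110,
                            seed = 4)
  eh <- empirical_hazard(fp, bin_width = 5)
  sel <- eh$age >= 40 & eh$age <= 77 & eh$cases >= 10
  slope <- stats::coef(stats::lm(log(eh$incidence[sel]) ~ eh$age[sel],
                                 weights = eh$cases[sel]))[[2]]
  expect_lt(abs(slope - 0.132) / 0.132, 0.15)
})

test_that("log-hazard slopes rise with the threshold like eta * Xc / epsilon", {
  p <- sr_cal()
  set.seed(12)
  thr <- c(12, 14, 16)
  res <- srincidence:::sr_engine(p, n = 6000, dt = 0.05, horizon = 110,
                                 thresholds = thr)
  slopes <- vapply(seq_along(thr), function(k) {
    ages <- res$crossings[[1]][, k]
    sm <- structure(list(threshold = thr[k], ages = ages, n = 6000L,
                         seed = 12L, horizon = res$horizon),
                    class = "first_passage_sample")
    eh <- empirical_hazard(sm, bin_width = 5)
    # rising limb: bins up to the age where a third are still at risk
    lim <- stats::quantile(ages, 0.67, na.rm = TRUE)
    sel <- eh$cases >= 20 & eh$age <= lim
    stats::coef(stats::lm(log(eh$incidence[sel]) ~ eh$age[sel],
                          weights = eh$cases[sel]))[[2]]
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
  # and the increments track the analytic slope map a = a0 + a1 Xc
  pred <- ct_default$a0 + ct_default$a1 * thr
  expect_lt(max(abs(slopes - pred) / pred), 0.35)
})

test_that("calibration rejects degenerate threshold sets and recovers eta/epsilon", {
  expect_error(calibrate_sr_parameters(thresholds = 14), "3 distinct")
  expect_error(calibrate_sr_parameters(thresholds = c(0, 5, 10)),
               "Xdeath")
  truth <- sr_cal()
  # target hazards generated from the known ground truth
  set.seed(21)
  thr <- c(13, 15, 17)
  res <- srincidence:::sr_engine(truth, n = 20000, dt = 0.05,
                                 horizon = 110, thresholds = thr)
  targets <- lapply(seq_along(thr), function(k) {
    sm <- structure(list(threshold = thr[k],
                         ages = res$crossings[[1]][, k], n = 20000L,
                         seed = 21L, horizon = res$horizon),
                    class = "first_passage_sample")
    eh <- empirical_hazard(sm, bin_width = 5)
    sel <- eh$cases >= 10
    stats::approxfun(eh$age[sel], log(eh$incidence[sel]), rule = 2)
  })
  names(targets) <- as.character(thr)
  target_fn <- function(t, xc) exp(targets[[as.character(xc)]](t))
  start <- sr_parameters(truth$eta * 1.6, truth$beta * 0.7,
                         truth$kappa * 1.5, truth$epsilon * 0.6)
  fit <- calibrate_sr_parameters(thresholds = thr, n = 1500, seed = 31,
                                 dt = 0.1, target_hazard = target_fn,
                                 start = start, maxit = 150)
  expect_lt(abs((fit$eta / fit$epsilon) / (truth$eta / truth$epsilon) - 1),
            0.2)
})
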