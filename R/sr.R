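#' Parameters of the saturated-removal (SR) senescent-cell process
#'
#' The SR model describes whole-body senescent-cell abundance `X(t)` by
#' \deqn{dX = \left(\eta t - \frac{\beta X}{\kappa + X}\right) dt
#'            + \sqrt{2\epsilon}\, dW}
#' with a production rate that rises linearly with age, removal that
#' saturates in `X` (high loads slow their own clearance), and white
#' noise. Units: `X` is scaled so that young-adult levels are of order 1
#' and the death threshold is 17; time is in years.
#'
#' `eta` and `epsilon` may be zero (deterministic / production-free
#' limits used for verification); `beta` and `kappa` must be positive.
#'
#' @param eta Production-rate slope, X-units per year squared.
#' @param beta Maximal removal rate, X-units per year.
#' @param kappa Removal half-saturation, X-units.
#' @param epsilon Noise intensity, X-units squared per year.
#' @return An object of class `"sr_parameters"`.
#' @export
sr_parameters <- function(eta, beta, kappa, epsilon) {
  stopifnot(is.numeric(eta), eta >= 0, is.numeric(beta), beta > 0,
            is.numeric(kappa), kappa > 0, is.numeric(epsilon), epsilon >= 0)
  structure(list(eta = eta, beta = beta, kappa = kappa, epsilon = epsilon),
            class = "sr_parameters")
}

.sr_cache <- new.env(parent = emptyenv())

#' Default (calibrated) SR parameters
#'
#' Returns the package's shipped SR parameters, obtained by running
#' [calibrate_sr_parameters()] against the analytic hazard family of
#' [regression_constants()] across thresholds 12..17. The values and
#' calibration metadata live in `inst/extdata/sr_config.yaml`.
#'
#' @return An [sr_parameters()] object with a `"calibration"` attribute.
#' @export
sr_default_parameters <- function() {
  if (is.null(.sr_cache$default)) {
    cfg <- yaml::read_yaml(system.file("extdata", "sr_config.yaml",
                                       package = "srincidence"))
    p <- sr_parameters(cfg$sr$eta, cfg$sr$beta, cfg$sr$kappa, cfg$sr$epsilon)
    attr(p, "calibration") <- cfg$calibration
    .sr_cache$default <- p
  }
  .sr_cache$default
}

# normalise a treatment schedule into the (start, interval, kill,
# sensitive) vector the C++ engine expects; NULL = untreated arm
as_engine_schedule <- function(schedule) {
  if (is.null(schedule)) return(c(0, 0, 0, 1))
  stopifnot(inherits(schedule, "treatment_schedule"))
  c(schedule$start_age, schedule$interval, schedule$kill_fraction,
    schedule$sensitive_fraction)
}

# low-level wrapper around the C++ engine; thresholds: n x K matrix
sr_engine <- function(params, n, dt, horizon, thresholds = NULL,
                      schedules = list(NULL), save_every = 0L, n_save = 0L,
                      tissue = list(), x0 = 0) {
  stopifnot(inherits(params, "sr_parameters"), dt > 0, horizon > 0, n >= 1)
  if (is.null(thresholds)) thresholds <- matrix(numeric(0), nrow = n, ncol = 0)
  if (is.vector(thresholds)) {
    thresholds <- matrix(rep(thresholds, each = n), nrow = n)
  }
  cpp_sr_simulate(as.integer(n), dt, horizon,
                  params$eta, params$beta, params$kappa, params$epsilon,
                  x0, thresholds, lapply(schedules, as_engine_schedule),
                  as.integer(save_every), as.integer(n_save), tissue)
}

#' Simulate one SR trajectory
#'
#' Euler-Maruyama integration of the SR stochastic differential equation,
#' with `X` clamped to non-negative values after each step. If a
#' [treatment_schedule()] is supplied, the drug-sensitive pool is reduced
#' by the kill fraction at each application age. Identical inputs and
#' seed give bit-identical output.
#'
#' @param params An [sr_parameters()] object.
#' @param horizon Final age, years.
#' @param dt Integration step, years.
#' @param seed Integer RNG seed.
#' @param schedule Optional [treatment_schedule()].
#' @param x0 Initial abundance at age 0.
#' @return An object of class `"sr_trajectory"`: list with `times`,
#'   `values` and `events` (applied treatment ages and kill fraction).
#' @export
#' @examples
#' tr <- simulate_trajectory(sr_parameters(5, 570, 2.8, 560),
#'                           horizon = 100, dt = 0.05, seed = 1)
#' range(tr$values)
simulate_trajectory <- function(params, horizon, dt = 0.01, seed = 1L,
                                schedule = NULL, x0 = 0) {
  if (dt <= 0) stop("dt must be positive")
  if (horizon <= 0) stop("horizon must be positive")
  set.seed(seed)
  res <- sr_engine(params, n = 1L, dt = dt, horizon = horizon,
                   schedules = list(schedule), save_every = 1L, n_save = 1L,
                   x0 = x0)
  events <- data.frame(age = numeric(0), fraction_removed = numeric(0))
  if (!is.null(schedule) && schedule$kill_fraction > 0) {
    ages <- seq(schedule$start_age, res$horizon, by = schedule$interval)
    events <- data.frame(age = ages,
                         fraction_removed = schedule$kill_fraction)
  }
  structure(list(times = res$path_times,
                 values = as.vector(res$paths[[1]]),
                 events = events),
            class = "sr_trajectory")
}

#' First-passage ages across a threshold
#'
#' Simulates `n` independent SR trajectories and records the first age at
#' which `X(t) >= threshold` (pure first passage, no dwell-time
#' requirement); individuals that never cross by the horizon are censored
#' (`NA` age). The crossing probability rises approximately exponentially
#' with age, with a log-slope close to `eta * threshold / epsilon`.
#'
#' @param params An [sr_parameters()] object.
#' @param threshold Crossing threshold, X-units, `> 0`.
#' @param n Number of individuals.
#' @param dt Integration step, years.
#' @param horizon Censoring age, years.
#' @param seed Integer RNG seed.
#' @return An object of class `"first_passage_sample"`: list with
#'   `threshold`, `ages` (`NA` = censored), `n`, `seed`, `horizon`.
#' @export
first_passage_times <- function(params, threshold, n, dt = 0.01,
                                horizon = 110, seed = 1L) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  res <- sr_engine(params, n = n, dt = dt, horizon = horizon,
                   thresholds = threshold)
  structure(list(threshold = threshold,
                 ages = as.vector(res$crossings[[1]]),
                 n = as.integer(n), seed = as.integer(seed),
                 horizon = res$horizon),
            class = "first_passage_sample")
}

#' Empirical hazard of a first-passage sample
#'
#' Life-table hazard estimate: crossings per age bin divided by the
#' person-years of individuals still at risk at the start of the bin
#' (prior crossers are excluded; censored individuals remain at risk to
#' the horizon). By construction the sum over bins of hazard x at-risk
#' person-years equals the number of crossers.
#'
#' @param sample A [first_passage_times()] result.
#' @param bin_width Age-bin width, years.
#' @return An [incidence_curve()] with bin-center ages, hazard per year,
#'   crossing counts and at-risk person-years.
#' @export
empirical_hazard <- function(sample, bin_width = 1) {
  stopifnot(inherits(sample, "first_passage_sample"))
  if (bin_width <= 0) stop("bin_width must be positive")
  ages <- sample$ages
  if (length(ages) == 0L) stop("empty first-passage sample")
  edges <- seq(0, sample$horizon + bin_width, by = bin_width)
  nb <- length(edges) - 1L
  crossed <- !is.na(ages)
  d <- tabulate(findInterval(ages[crossed], edges), nb)
  # at risk at bin start: not yet crossed by the left edge
  n_at_risk <- sample$n - c(0, cumsum(d))[seq_len(nb)]
  keep <- n_at_risk > 0 & edges[-length(edges)] < sample$horizon
  incidence_curve(ages = (edges[-length(edges)] + bin_width / 2)[keep],
                  incidence = (d / (n_at_risk * bin_width))[keep],
                  cases = d[keep],
                  person_years = (n_at_risk * bin_width)[keep])
}

# empirical log-hazard slope over an age window, weighted by event counts
log_hazard_slope <- function(curve, age_min = 30, age_max = 100) {
  sel <- curve$age >= age_min & curve$age <= age_max &
    is.finite(curve$incidence) & curve$incidence > 0
  if (sum(sel) < 3) stop("too few bins with events to estimate a slope")
  w <- if (!is.null(curve$cases)) curve$cases[sel] else rep(1, sum(sel))
  stats::coef(stats::lm(log(curve$incidence[sel]) ~ curve$age[sel],
                        weights = w))[[2]]
}

#' Calibrate SR parameters to a target hazard family
#'
#' Finds `(eta, beta, kappa, epsilon)` whose simulated first-passage
#' hazards across a set of thresholds match target hazard curves --- by
#' default the analytic family `h(t | Xc)` of the supplied
#' [regression_constants()]. The loss is an event-count-weighted sum of
#' squared log-hazard differences over 5-year age bins; common random
#' numbers (the seed is reset before every evaluation) keep the loss
#' smooth in the parameters. A coarse log-grid scan over
#' `(epsilon, kappa)` --- with `eta/epsilon` and `beta/epsilon` initialised
#' from the slope and amplitude coefficients of the regression map ---
#' precedes Nelder-Mead refinement of all four log-parameters.
#'
#' @param constants A [regression_constants()] object (supplies the
#'   default target hazards and the admissible threshold range).
#' @param thresholds At least 3 distinct thresholds in `(0, Xdeath]`.
#' @param n Simulated individuals per loss evaluation.
#' @param seed Integer seed; the result is deterministic given it.
#' @param dt Integration step for calibration runs, years.
#' @param horizon Simulation horizon, years.
#' @param target_hazard Optional `function(t, xc)` returning the target
#'   hazard; defaults to the analytic family of `constants`.
#' @param start Optional [sr_parameters()] starting point (skips the
#'   coarse scan).
#' @param maxit Nelder-Mead iteration budget.
#' @return An [sr_parameters()] object with attributes `loss`,
#'   `converged` and `calibration` (metadata). Non-convergence is flagged,
#'   not silently ignored.
#' @export
calibrate_sr_parameters <- function(constants = regression_constants(),
                                    thresholds = 12:17,
                                    n = 2000, seed = 1L,
                                    dt = 0.05, horizon = 110,
                                    target_hazard = NULL,
                                    start = NULL, maxit = 200) {
  thresholds <- sort(unique(thresholds))
  if (length(thresholds) < 3)
    stop("calibration needs at least 3 distinct thresholds")
  if (any(thresholds <= 0) || any(thresholds > constants$Xdeath))
    stop("thresholds must lie in (0, Xdeath]")
  if (is.null(target_hazard)) {
    target_hazard <- function(t, xc)
      hazard(t, hazard_params_from_threshold(xc, constants))
  }

  bw <- 5
  # expected life-table hazard of a bin [lb, rb] under a target hazard
  # curve: (1 - exp(-integral of h)) / bw, Simpson quadrature
  bin_target <- function(lb, rb, xc) {
    tt <- cbind(lb, (lb + rb) / 2, rb)
    ih <- (rb - lb) / 6 *
      (target_hazard(tt[, 1], xc) + 4 * target_hazard(tt[, 2], xc) +
         target_hazard(tt[, 3], xc))
    (1 - exp(-ih)) / (rb - lb)
  }
  loss_fn <- function(logp) {
    p <- sr_parameters(exp(logp[1]), exp(logp[2]), exp(logp[3]), exp(logp[4]))
    set.seed(seed)
    res <- sr_engine(p, n = n, dt = dt, horizon = horizon,
                     thresholds = thresholds)
    total <- 0
    for (k in seq_along(thresholds)) {
      sm <- structure(list(threshold = thresholds[k],
                           ages = res$crossings[[1]][, k],
                           n = as.integer(n), seed = seed,
                           horizon = res$horizon),
                      class = "first_passage_sample")
      eh <- empirical_hazard(sm, bin_width = bw)
      sel <- eh$cases >= 5
      if (!any(sel)) {
        total <- total + 50  # no events at this threshold: heavy penalty
        next
      }
      target <- bin_target(eh$age[sel] - bw / 2, eh$age[sel] + bw / 2,
                           thresholds[k])
      total <- total +
        sum(eh$cases[sel] * (log(eh$incidence[sel]) - log(target))^2) /
        sum(eh$cases[sel])
    }
    total / length(thresholds)
  }

  if (is.null(start)) {
    # ratios eta/eps and beta/eps from the slope and amplitude maps of
    # the analytic family; scan the absolute noise scale and kappa
    r_eta <- constants$a1
    r_beta <- -constants$A1
    grid <- expand.grid(leps = log(10) * seq(0.5, 3, by = 0.5),
                        lkap = log(10) * seq(-0.5, 1.25, by = 0.35))
    vals <- apply(grid, 1, function(g) {
      loss_fn(c(log(r_eta) + g[1], log(r_beta) + g[1], g[2], g[1]))
    })
    best <- grid[which.min(vals), ]
    start_log <- c(log(r_eta) + best$leps, log(r_beta) + best$leps,
                   best$lkap, best$leps)
  } else {
    stopifnot(inherits(start, "sr_parameters"))
    start_log <- log(c(start$eta, start$beta, start$kappa, start$epsilon))
  }

  opt <- stats::optim(start_log, loss_fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-4))
  out <- sr_parameters(exp(opt$par[1]), exp(opt$par[2]),
                       exp(opt$par[3]), exp(opt$par[4]))
  attr(out, "loss") <- opt$value
  attr(out, "converged") <- opt$convergence == 0 && is.finite(opt$value)
  attr(out, "calibration") <- list(
    thresholds = thresholds, n = n, seed = seed, dt = dt,
    horizon = horizon, loss = opt$value,
    converged = opt$convergence == 0)
  if (!attr(out, "converged"))
    warning("SR calibration did not converge within the iteration budget; ",
            "inspect attr(, 'loss')", call. = FALSE)
  out
}
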