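# vectorised survival inversion for per-individual hazard parameters
survival_inverse_vec <- function(p, A, b, a) {
  z <- exp(log1p(b) - (a * b / A) * log(p)) - 1
  t <- ifelse(z > 0, (log(pmax(z, .Machine$double.xmin)) - log(b)) / a, Inf)
  pmax(t, 0)
}

threshold_hazard_coefs <- function(xc, constants) {
  list(A = exp(constants$A0 + constants$A1 * xc),
       b = exp(constants$b0 + constants$b1 * xc),
       a = constants$a0 + constants$a1 * xc)
}

#' Cohort specification
#'
#' Describes a synthetic cohort: `n` individuals followed from age 0 to
#' `horizon`, disease onsets generated either by explicit SR trajectories
#' (`mode = "sde"`, first passage of each individual's threshold) or by
#' inverse-CDF sampling from the closed-form onset survival
#' (`mode = "closed-form"`).
#'
#' @param n Number of individuals.
#' @param model A [disease_model()].
#' @param mode `"closed-form"` or `"sde"`.
#' @param horizon Follow-up limit in years (at most 110).
#' @param seed Integer RNG seed.
#' @param dt Integration step for SDE mode, years.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n, model, mode = c("closed-form", "sde"),
                        horizon = 110, seed = 1L, dt = 0.01) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n), n >= 1, inherits(model, "disease_model"),
            horizon > 0, horizon <= 110, dt > 0)
  structure(list(n = as.integer(n), model = model, mode = mode,
                 horizon = horizon, seed = as.integer(seed), dt = dt),
            class = "cohort_spec")
}

# shared cohort generator; schedules is a list of treatment schedules
# (NULL = untreated arm), all arms paired on the same noise and the same
# susceptibility/threshold/death draws. Returns one event table per arm.
cohort_engine <- function(spec, schedules = list(NULL),
                          constants = regression_constants(),
                          sr = sr_default_parameters(),
                          susceptible_deaths = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  model <- spec$model
  set.seed(spec$seed)
  sus <- stats::runif(n) < model$s

  thr <- rep(NA_real_, n)
  if (model$sigma > 0) {
    # truncated-normal threshold draws by rejection below 0
    ns <- sum(sus)
    draws <- numeric(0)
    while (length(draws) < ns) {
      cand <- stats::rnorm(ns, model$xc, model$sigma)
      draws <- c(draws, cand[cand > 0])
    }
    thr[sus] <- draws[seq_len(ns)]
  } else {
    thr[sus] <- model$xc
  }

  # death ages for everyone from the death hazard; under the default
  # (closed-form) accounting convention, susceptibles leave the at-risk
  # pool only through onset, so their deaths are not applied
  hd <- death_hazard_params(constants)
  death <- survival_inverse(stats::runif(n), hd)
  death_applies <- if (susceptible_deaths) rep(TRUE, n) else !sus
  death_age <- ifelse(death_applies & death <= spec$horizon, death, NA_real_)

  onset_raw <- vector("list", length(schedules))
  if (spec$mode == "closed-form") {
    if (any(!vapply(schedules, is.null, logical(1))))
      stop("treatment schedules require mode = 'sde' ",
           "(no closed-form treated solution)")
    u <- stats::runif(n)
    on <- rep(NA_real_, n)
    if (any(sus)) {
      co <- threshold_hazard_coefs(thr[sus], constants)
      on[sus] <- survival_inverse_vec(u[sus], co$A, co$b, co$a)
    }
    on[!is.na(on) & on > spec$horizon] <- NA_real_
    onset_raw <- list(on)
  } else {
    ns <- sum(sus)
    if (ns > 0) {
      res <- sr_engine(sr, n = ns, dt = spec$dt, horizon = spec$horizon,
                       thresholds = matrix(thr[sus], ncol = 1),
                       schedules = schedules)
      for (a in seq_along(schedules)) {
        on <- rep(NA_real_, n)
        on[sus] <- res$crossings[[a]][, 1]
        onset_raw[[a]] <- on
      }
    } else {
      onset_raw <- rep(list(rep(NA_real_, n)), length(schedules))
    }
  }

  out <- lapply(onset_raw, function(on) {
    # onset observed only while the individual is alive
    on[!is.na(on) & !is.na(death_age) & on > death_age] <- NA_real_
    structure(data.frame(id = seq_len(n), susceptible = sus,
                         threshold = thr, onset_age = on,
                         death_age = death_age),
              horizon = spec$horizon, class = c("event_table", "data.frame"))
  })
  out
}

#' Simulate an individual-level cohort
#'
#' Each individual is susceptible with probability `s`; susceptible
#' thresholds are the model `xc` (two-parameter) or truncated-normal
#' draws (three-parameter). Onset is the first passage of the SR process
#' across the individual threshold (`mode = "sde"`) or an inverse-CDF
#' draw from the closed-form onset survival (`mode = "closed-form"`).
#' Death ages are drawn from the death hazard.
#'
#' By default the at-risk accounting matches the closed-form incidence
#' formula: susceptible individuals leave the pool only through onset,
#' non-susceptible individuals through death. Set
#' `susceptible_deaths = TRUE` to apply death to everyone, which exposes
#' the approximation the closed form makes.
#'
#' @param spec A [cohort_spec()].
#' @param constants A [regression_constants()] object.
#' @param sr [sr_parameters()] for SDE mode.
#' @param schedule Optional [treatment_schedule()] (SDE mode only).
#' @param susceptible_deaths Apply death draws to susceptibles too.
#' @return An event table (class `"event_table"`): one row per individual
#'   with `id`, `susceptible`, `threshold`, `onset_age`, `death_age`
#'   (`NA` = censored at the horizon), and the horizon as an attribute.
#' @export
simulate_cohort <- function(spec, constants = regression_constants(),
                            sr = sr_default_parameters(), schedule = NULL,
                            susceptible_deaths = FALSE) {
  cohort_engine(spec, list(schedule), constants, sr,
                susceptible_deaths)[[1]]
}

#' Aggregate an event table to an incidence curve
#'
#' Per age bin: `cases` = onsets in the bin; `person_years` = at-risk
#' time summed over individuals alive and disease-free; incidence =
#' cases / person-years. Individuals leave the at-risk pool at onset or
#' death, whichever comes first. Bins with zero person-years get `NA`
#' incidence (missing, not zero).
#'
#' @param events An event table from [simulate_cohort()].
#' @param bin_width Bin width in years.
#' @return An [incidence_curve()] with bin-center ages.
#' @export
aggregate_incidence <- function(events, bin_width = 1) {
  stopifnot(inherits(events, "event_table"), bin_width > 0)
  if (nrow(events) == 0L) stop("empty event table")
  horizon <- attr(events, "horizon")
  exit <- pmin(ifelse(is.na(events$onset_age), Inf, events$onset_age),
               ifelse(is.na(events$death_age), Inf, events$death_age),
               horizon)
  rate_curve(event_ages = events$onset_age[!is.na(events$onset_age)],
             exit_ages = exit, horizon = horizon, bin_width = bin_width)
}

# exact person-year bookkeeping shared by cohort aggregation and
# tissue-collapse incidence
rate_curve <- function(event_ages, exit_ages, horizon, bin_width) {
  edges <- seq(0, ceiling(horizon / bin_width) * bin_width, by = bin_width)
  nb <- length(edges) - 1L
  cases <- tabulate(findInterval(event_ages, edges), nb)
  idx <- findInterval(exit_ages, edges)  # bin holding each exit
  idx[idx > nb] <- nb + 1L
  cnt <- tabulate(idx, nb)
  sums <- numeric(nb)
  inb <- idx <= nb
  if (any(inb)) {
    rs <- rowsum(exit_ages[inb], idx[inb])
    sums[as.integer(rownames(rs))] <- rs[, 1]
  }
  exited_by <- cumsum(cnt)
  n_full <- length(exit_ages) - exited_by   # exit beyond the bin's right edge
  py <- n_full * bin_width + (sums - edges[seq_len(nb)] * cnt)
  inc <- ifelse(py > 0, cases / py, NA_real_)
  keep <- seq_len(max(which(py > 0)))
  incidence_curve(ages = (edges[-length(edges)] + bin_width / 2)[keep],
                  incidence = inc[keep], cases = cases[keep],
                  person_years = py[keep])
}

#' Write a deterministic incidence fixture
#'
#' Simulates a cohort, aggregates it to an incidence table, optionally
#' applies multiplicative log-normal noise, and writes a CSV in the
#' package's standard dialect. The same spec and seed always produce a
#' byte-identical file. Noisy fixtures carry only `age` and `incidence`
#' columns (counts would no longer be consistent with the rates).
#'
#' @param name Fixture name (becomes `<name>.csv`).
#' @param spec A [cohort_spec()].
#' @param noise Relative standard deviation of multiplicative log-normal
#'   noise; 0 for none.
#' @param dir Output directory.
#' @param overwrite Overwrite an existing file.
#' @param bin_width Aggregation bin width, years.
#' @inheritParams simulate_cohort
#' @return The written [incidence_curve()], invisibly (with the file path
#'   as attribute `"path"`).
#' @export
make_fixture <- function(name, spec, noise = 0, dir = ".",
                         overwrite = FALSE, bin_width = 1,
                         constants = regression_constants(),
                         sr = sr_default_parameters()) {
  path <- file.path(dir, paste0(name, ".csv"))
  if (file.exists(path) && !overwrite)
    stop("fixture file ", path, " exists; use overwrite = TRUE")
  events <- simulate_cohort(spec, constants, sr)
  curve <- aggregate_incidence(events, bin_width)
  if (noise > 0) {
    # noise drawn from the stream continuing after the cohort simulation,
    # so the fixture stays deterministic in the spec seed
    fac <- exp(noise * stats::rnorm(nrow(curve)))
    curve <- incidence_curve(curve$age, curve$incidence * fac)
  }
  write_incidence_csv(curve, path)
  attr(curve, "path") <- path
  invisible(curve)
}

#' Noisy closed-form incidence curve
#'
#' Evaluates the exact model incidence on an age grid and applies
#' multiplicative log-normal noise; the standard synthetic input for
#' parameter-recovery checks.
#'
#' @param model A [disease_model()].
#' @param ages Bin-center ages.
#' @param noise Relative standard deviation of the noise.
#' @param seed Integer RNG seed.
#' @param constants A [regression_constants()] object.
#' @return An [incidence_curve()].
#' @export
synthetic_curve <- function(model, ages = seq(0.5, 109.5, by = 1),
                            noise = 0.05, seed = 1L,
                            constants = regression_constants()) {
  set.seed(seed)
  inc <- model_incidence(ages, model, constants)
  incidence_curve(ages, inc * exp(noise * stats::rnorm(length(ages))))
}
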