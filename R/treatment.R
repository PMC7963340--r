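#' Intermittent senolytic treatment schedule
#'
#' Senescent cells are produced in two pools: a drug-sensitive fraction
#' (`sensitive_fraction` of production) and an insensitive remainder;
#' both compete for the same saturating removal capacity. At each
#' application age (every `interval` years from `start_age`) the
#' treatment removes `kill_fraction` of the sensitive pool.
#'
#' @param start_age First application age, years.
#' @param interval Time between applications, years (e.g. `30/365.25`
#'   for monthly treatment).
#' @param kill_fraction Fraction of the sensitive pool removed per
#'   application, in `[0, 1]`.
#' @param sensitive_fraction Fraction of production that is
#'   drug-sensitive, in `[0, 1]`.
#' @return An object of class `"treatment_schedule"`.
#' @export
#' @examples
#' treatment_schedule(60, 30 / 365.25, 1, 0.25)  # monthly from age 60
treatment_schedule <- function(start_age, interval, kill_fraction = 1,
                               sensitive_fraction = 0.25) {
  stopifnot(is.numeric(start_age), start_age >= 0,
            is.numeric(interval), interval > 0,
            kill_fraction >= 0, kill_fraction <= 1,
            sensitive_fraction >= 0, sensitive_fraction <= 1)
  structure(list(start_age = start_age, interval = interval,
                 kill_fraction = kill_fraction,
                 sensitive_fraction = sensitive_fraction),
            class = "treatment_schedule")
}

#' Simulate a cohort under senolytic treatment
#'
#' SDE-mode cohort simulation with the treatment applied to each
#' individual's trajectory; onsets are first passages of the total
#' abundance across the individual threshold. A kill fraction of zero
#' reproduces the untreated cohort exactly (same seed, same noise).
#'
#' @param spec A [cohort_spec()] with `mode = "sde"`.
#' @param schedule A [treatment_schedule()].
#' @inheritParams simulate_cohort
#' @return An event table (see [simulate_cohort()]).
#' @export
simulate_treated_cohort <- function(spec, schedule,
                                    constants = regression_constants(),
                                    sr = sr_default_parameters(),
                                    susceptible_deaths = FALSE) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  if (spec$mode != "sde")
    stop("treatment acts on trajectories: use a cohort spec with ",
         "mode = 'sde' (no closed-form treated solution exists)")
  simulate_cohort(spec, constants, sr, schedule = schedule,
                  susceptible_deaths = susceptible_deaths)
}

#' Simulate paired treatment arms on shared noise
#'
#' Integrates one SR noise realisation per individual and applies each
#' schedule to it, so arm contrasts are free of between-arm Monte-Carlo
#' variation and each individual's treated crossing age is at least its
#' untreated one.
#'
#' @param spec A [cohort_spec()] with `mode = "sde"`.
#' @param schedules List of [treatment_schedule()] objects; `NULL`
#'   elements are untreated arms.
#' @inheritParams simulate_cohort
#' @return A list of event tables, one per schedule.
#' @export
simulate_paired_cohorts <- function(spec, schedules,
                                    constants = regression_constants(),
                                    sr = sr_default_parameters(),
                                    susceptible_deaths = FALSE) {
  if (spec$mode != "sde") stop("paired arms require mode = 'sde'")
  cohort_engine(spec, schedules, constants, sr, susceptible_deaths)
}

#' Horizontal shift between incidence curves
#'
#' Quantifies by how many years a treatment pushes the incidence curve
#' toward younger ages: every treated point inside `age_window` is
#' matched, by monotone interpolation of log-incidence on the rising limb
#' of the untreated curve, to the untreated age with equal incidence; the
#' shift is the mean of (treated age - matched untreated age). Treated
#' points whose incidence falls outside the untreated range cannot be
#' matched and are dropped.
#'
#' @param untreated,treated [incidence_curve()] objects on compatible
#'   grids; the untreated curve must be strictly increasing over its
#'   positive-incidence bins between `ref_age_min` and the window end
#'   (its rising limb).
#' @param age_window Ages (years) of treated points to match; the upper
#'   end should sit at or below the untreated peak.
#' @param ref_age_min Youngest untreated age used for the reference
#'   interpolation (bins below this are typically too sparse to be
#'   reliably monotone).
#' @return Shift in years (positive = treated curve sits at older ages
#'   for equal incidence).
#' @export
incidence_shift_years <- function(untreated, treated,
                                  age_window = c(60, 80),
                                  ref_age_min = 30) {
  stopifnot(inherits(untreated, "incidence_curve"),
            inherits(treated, "incidence_curve"),
            length(age_window) == 2L, age_window[1] < age_window[2])
  ref <- untreated[is.finite(untreated$incidence) &
                     untreated$incidence > 0 &
                     untreated$age >= ref_age_min &
                     untreated$age <= age_window[2], , drop = FALSE]
  if (nrow(ref) < 2)
    stop("untreated curve has too few positive bins in the reference range")
  if (any(diff(ref$incidence) <= 0))
    stop("untreated incidence is not strictly increasing below age ",
         age_window[2], "; use a narrower age window or wider bins")
  tr <- treated[treated$age >= age_window[1] &
                  treated$age <= age_window[2] &
                  is.finite(treated$incidence) & treated$incidence > 0,
                , drop = FALSE]
  matchable <- tr$incidence >= min(ref$incidence) &
    tr$incidence <= max(ref$incidence)
  if (!any(matchable))
    stop("no treated point falls within the untreated incidence range")
  matched_age <- stats::approx(x = log(ref$incidence), y = ref$age,
                               xout = log(tr$incidence[matchable]))$y
  mean(tr$age[matchable] - matched_age)
}

#' Prevalence reduction from paired event tables
#'
#' Fraction by which treatment reduces the number of individuals with
#' disease onset by `to_age`:
#' `1 - (treated onsets) / (untreated onsets)`.
#'
#' @param events_untreated,events_treated Event tables from the same
#'   cohort spec (paired seed lineage; equal size enforced).
#' @param to_age Cumulation age, years.
#' @return Reduction as a fraction in `[0, 1]` (0 = no effect).
#' @export
prevalence_reduction <- function(events_untreated, events_treated,
                                 to_age = 90) {
  stopifnot(inherits(events_untreated, "event_table"),
            inherits(events_treated, "event_table"))
  if (nrow(events_untreated) != nrow(events_treated))
    stop("paired event tables must have the same cohort size")
  n_u <- sum(events_untreated$onset_age <= to_age, na.rm = TRUE)
  n_t <- sum(events_treated$onset_age <= to_age, na.rm = TRUE)
  if (n_u == 0) stop("no untreated onsets by age ", to_age)
  1 - n_t / n_u
}

#' Treatment outcome summary
#'
#' Runs the paired untreated/treated simulation for one schedule and
#' summarises the incidence-curve shift, fold reduction of incidence at
#' selected ages, and the prevalence reduction to age 90.
#'
#' @param spec A [cohort_spec()] with `mode = "sde"`.
#' @param schedule A [treatment_schedule()].
#' @param bin_width Bin width (years) of the summary incidence curves.
#' @param age_window Window passed to [incidence_shift_years()].
#' @param fold_at Ages (bin lower edges, 1-year bins) at which to report
#'   untreated/treated incidence fold reductions.
#' @inheritParams simulate_cohort
#' @return A list of class `"treatment_outcome"`: `untreated`, `treated`
#'   (curves), `shift_years`, `fold_reduction_at` (named vector),
#'   `prevalence_reduction_to_90`.
#' @export
treatment_outcome <- function(spec, schedule, bin_width = 5,
                              age_window = c(60, 80),
                              fold_at = schedule$start_age,
                              constants = regression_constants(),
                              sr = sr_default_parameters()) {
  arms <- simulate_paired_cohorts(spec, list(NULL, schedule), constants, sr)
  cu <- aggregate_incidence(arms[[1]], bin_width)
  ct <- aggregate_incidence(arms[[2]], bin_width)
  fold <- vapply(fold_at, function(a0) {
    iu <- bin_rate(arms[[1]], a0, a0 + 1)
    it <- bin_rate(arms[[2]], a0, a0 + 1)
    if (is.na(it) || it == 0) Inf else iu / it
  }, numeric(1))
  names(fold) <- fold_at
  structure(list(untreated = cu, treated = ct,
                 shift_years = incidence_shift_years(cu, ct, age_window),
                 fold_reduction_at = fold,
                 prevalence_reduction_to_90 =
                   prevalence_reduction(arms[[1]], arms[[2]], 90)),
            class = "treatment_outcome")
}

# incidence rate of one [a0, a1) age bin of an event table
bin_rate <- function(events, a0, a1) {
  horizon <- attr(events, "horizon")
  exit <- pmin(ifelse(is.na(events$onset_age), Inf, events$onset_age),
               ifelse(is.na(events$death_age), Inf, events$death_age),
               horizon)
  cases <- sum(!is.na(events$onset_age) & events$onset_age >= a0 &
                 events$onset_age < a1)
  py <- sum(pmax(0, pmin(exit, a1) - a0))
  if (py <= 0) NA_real_ else cases / py
}

#' Scan treatment interval and efficacy
#'
#' Incidence-curve shift (years) for every combination of treatment
#' interval and per-application kill fraction, all arms paired on one
#' noise realisation. Shifts grow as applications become more frequent
#' or more effective.
#'
#' @param spec A [cohort_spec()] with `mode = "sde"`.
#' @param intervals Treatment intervals in years.
#' @param efficacies Kill fractions per application.
#' @param start_age Treatment start age, years.
#' @param sensitive_fraction Drug-sensitive production fraction.
#' @param bin_width,age_window Passed to the shift computation.
#' @inheritParams simulate_cohort
#' @return Matrix of shifts (rows = intervals, columns = efficacies).
#' @export
scan_treatment <- function(spec, intervals, efficacies, start_age = 60,
                           sensitive_fraction = 0.25, bin_width = 5,
                           age_window = c(60, 80),
                           constants = regression_constants(),
                           sr = sr_default_parameters()) {
  if (length(intervals) == 0 || length(efficacies) == 0)
    stop("interval and efficacy grids must be non-empty")
  grid <- expand.grid(interval = intervals, kill = efficacies)
  schedules <- c(list(NULL), lapply(seq_len(nrow(grid)), function(i) {
    treatment_schedule(start_age, grid$interval[i], grid$kill[i],
                       sensitive_fraction)
  }))
  arms <- simulate_paired_cohorts(spec, schedules, constants, sr)
  cu <- aggregate_incidence(arms[[1]], bin_width)
  shifts <- vapply(seq_len(nrow(grid)), function(i) {
    ct <- aggregate_incidence(arms[[i + 1]], bin_width)
    tryCatch(incidence_shift_years(cu, ct, age_window),
             error = function(e) NA_real_)
  }, numeric(1))
  matrix(shifts, nrow = length(intervals),
         dimnames = list(interval = as.character(intervals),
                         efficacy = as.character(efficacies)))
}
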