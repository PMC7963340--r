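#' Incidence curve container
#'
#' A validated data frame of per-age incidence rates: bin-center `age`
#' (years, strictly increasing), `incidence` (events per person-year at
#' risk), and optionally integer `cases` and `person_years` exposure, in
#' which case `incidence` must equal `cases / person_years`. Bins with no
#' person-years carry `NA` incidence (missing, not zero).
#'
#' @param ages Bin-center ages, years, strictly increasing.
#' @param incidence Rates per person-year, `>= 0` or `NA`.
#' @param cases Optional event counts per bin.
#' @param person_years Optional person-years at risk per bin.
#' @return A data frame of class `"incidence_curve"`.
#' @export
incidence_curve <- function(ages, incidence, cases = NULL,
                            person_years = NULL) {
  stopifnot(is.numeric(ages), is.numeric(incidence),
            length(ages) == length(incidence))
  if (length(ages) == 0L) stop("incidence curve must have at least one bin")
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  if (any(incidence < 0, na.rm = TRUE)) stop("incidence must be non-negative")
  df <- data.frame(age = ages, incidence = incidence)
  if (!is.null(cases) || !is.null(person_years)) {
    if (is.null(cases) || is.null(person_years))
      stop("cases and person_years must be supplied together")
    stopifnot(length(cases) == length(ages),
              length(person_years) == length(ages))
    ok <- person_years > 0
    if (any(abs(incidence[ok] - cases[ok] / person_years[ok]) > 1e-9,
            na.rm = TRUE))
      stop("incidence must equal cases / person_years (within 1e-9)")
    df$cases <- cases
    df$person_years <- person_years
  }
  class(df) <- c("incidence_curve", "data.frame")
  df
}

#' Mean log-slope of an incidence curve
#'
#' Ordinary least-squares slope of `log(incidence)` against age over the
#' bins with positive incidence inside `[age_min, age_max]`; the summary
#' statistic used to classify diseases as age-related. The conventional
#' window is ages 30--80.
#'
#' @param curve An [incidence_curve()].
#' @param age_min,age_max Age window, years.
#' @return Slope, per year.
#' @export
#' @examples
#' cv <- incidence_curve(30:80, 1e-4 * exp(0.07 * (30:80)))
#' mean_log_slope(cv)  # 0.07
mean_log_slope <- function(curve, age_min = 30, age_max = 80) {
  stopifnot(inherits(curve, "incidence_curve"))
  sel <- curve$age >= age_min & curve$age <= age_max &
    is.finite(curve$incidence) & curve$incidence > 0
  if (sum(sel) < 3)
    stop("only ", sum(sel), " bins with positive incidence in [", age_min,
         ", ", age_max, "]; at least 3 are required")
  x <- curve$age[sel]
  y <- log(curve$incidence[sel])
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Classify age-relatedness from the incidence log-slope
#'
#' A disease is at least mildly age-related if its mean incidence
#' log-slope over ages 30--80 reaches 3% per year, and strongly
#' age-related at 7% per year. Class edges are closed on the left
#' (a slope of exactly 0.03 is "mild", 0.07 is "strong").
#'
#' @param slope Log-slope, per year (finite).
#' @return One of `"not"`, `"mild"`, `"strong"`.
#' @export
classify_age_related <- function(slope) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (slope >= 0.07) "strong" else if (slope >= 0.03) "mild" else "not"
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` on the linear incidence scale.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return R-squared (may be negative for fits worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) stop("observed values have zero variance")
  1 - sum((observed - predicted)^2) / sstot
}

# weights: inverse squared 95% CI half-width (normal approximation to the
# Poisson rate) when counts are present, floored at the smallest positive
# half-width; uniform otherwise
fit_weights <- function(curve) {
  if (is.null(curve$cases)) return(rep(1, nrow(curve)))
  hw <- 1.96 * sqrt(pmax(curve$cases, 1)) / curve$person_years
  hw[!is.finite(hw)] <- NA
  floor_hw <- min(hw[hw > 0], na.rm = TRUE)
  w <- 1 / pmax(hw, floor_hw)^2
  w[!is.finite(w)] <- 0
  w
}

fit_objective <- function(curve, constants, w) {
  obs <- curve$incidence
  sel <- is.finite(obs)
  function(par) {
    # par = (xc, log10 s[, sigma])
    s <- 10^par[2]
    sigma <- if (length(par) >= 3) par[3] else 0
    if (par[1] <= 0 || s <= 0 || s > 1 || sigma < 0) return(1e12)
    m <- suppressWarnings(disease_model(par[1], s, sigma))
    pred <- model_incidence(curve$age, m, constants)
    sum(w[sel] * (obs[sel] - pred[sel])^2)
  }
}

finish_fit <- function(curve, constants, best, kind) {
  s <- 10^best$par[2]
  sigma <- if (length(best$par) >= 3) best$par[3] else 0
  model <- suppressWarnings(disease_model(best$par[1], s, sigma))
  sel <- is.finite(curve$incidence)
  pred <- model_incidence(curve$age, model, constants)
  rsq <- tryCatch(r_squared(curve$incidence[sel], pred[sel]),
                  error = function(e) -Inf)  # zero-variance (flat) input
  structure(list(model = model,
                 r_squared = rsq,
                 loss = best$value,
                 converged = best$converged,
                 n_points = sum(sel),
                 model_kind = kind),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: Xc = %.3f, s = %.4g", x$model_kind,
              x$model$xc, x$model$s))
  if (x$model_kind == "three-parameter")
    cat(sprintf(", sigma = %.3f", x$model$sigma))
  cat(sprintf("\nR^2 = %.4f, loss = %.4g, %d points, converged: %s\n",
              x$r_squared, x$loss, x$n_points, x$converged))
  invisible(x)
}

# multi-start local refinement from the best grid cells; Nelder-Mead
# with box constraints enforced by clamping (the objective is cheap and
# can be exactly zero at the optimum, where quasi-Newton line searches
# terminate abnormally)
refine_starts <- function(obj, starts, lower, upper) {
  obj_boxed <- function(par) obj(pmin(pmax(par, lower), upper))
  best <- list(value = Inf, par = starts[[1]], converged = FALSE)
  for (p0 in starts) {
    opt <- tryCatch(
      stats::optim(p0, obj_boxed, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value < best$value) {
      best <- list(value = opt$value,
                   par = pmin(pmax(opt$par, lower), upper),
                   converged = opt$convergence == 0)
    }
  }
  best
}

#' Fit the two-parameter model to an incidence curve
#'
#' Weighted least squares on the linear incidence scale over
#' `(Xc, log10 s)`: a coarse grid (`Xc` in steps of 0.5, `log10 s` in
#' steps of 0.25) followed by local refinement from the best five grid
#' cells. Deterministic (no randomness). When case counts are available
#' the weights are the inverse squared 95% CI half-widths of the rates.
#'
#' By default thresholds are capped at the death threshold; diseases with
#' steeper slopes than mortality (dementia-like curves) can be fit with
#' `allow_super_death = TRUE`, which extends the threshold range to 25.
#'
#' @param curve An [incidence_curve()] with at least 4 usable points.
#' @param constants A [regression_constants()] object.
#' @param allow_super_death Permit fitted `Xc` above `Xdeath`.
#' @return A `"fit_result"`: list with `model` ([disease_model()]),
#'   `r_squared`, `loss`, `converged`, `n_points`, `model_kind`.
#' @export
fit_2p <- function(curve, constants = regression_constants(),
                   allow_super_death = FALSE) {
  stopifnot(inherits(curve, "incidence_curve"))
  if (sum(is.finite(curve$incidence)) < 4)
    stop("fit_2p needs at least 4 data points")
  xc_max <- if (allow_super_death) 25 else constants$Xdeath
  w <- fit_weights(curve)
  obj <- fit_objective(curve, constants, w)
  grid <- expand.grid(xc = seq(5, xc_max, by = 0.5),
                      ls = seq(-5, 0, by = 0.25))
  vals <- mapply(function(xc, ls) obj(c(xc, ls)), grid$xc, grid$ls)
  ord <- order(vals)[1:5]
  starts <- lapply(ord, function(i) c(grid$xc[i], grid$ls[i]))
  best <- refine_starts(obj, starts, lower = c(5, -5), upper = c(xc_max, 0))
  finish_fit(curve, constants, best, "two-parameter")
}

#' Fit the three-parameter model to an incidence curve
#'
#' As [fit_2p()] with the threshold spread `sigma` (grid 0..5 in steps of
#' 0.5) added. The refined two-parameter optimum is always included among
#' the refinement starts (with `sigma = 0`), so the three-parameter loss
#' never exceeds the two-parameter loss beyond solver tolerance.
#'
#' @inheritParams fit_2p
#' @param curve An [incidence_curve()] with at least 5 usable points.
#' @return A `"fit_result"` (see [fit_2p()]).
#' @export
fit_3p <- function(curve, constants = regression_constants(),
                   allow_super_death = FALSE) {
  stopifnot(inherits(curve, "incidence_curve"))
  if (sum(is.finite(curve$incidence)) < 5)
    stop("fit_3p needs at least 5 data points")
  xc_max <- if (allow_super_death) 25 else constants$Xdeath
  w <- fit_weights(curve)
  obj <- fit_objective(curve, constants, w)

  sel <- is.finite(curve$incidence)
  obs <- curve$incidence[sel]
  wts <- w[sel]
  t_obs <- curve$age[sel]
  Sd <- survival(t_obs, death_hazard_params(constants))
  ls_grid <- seq(-5, 0, by = 0.25)
  s_grid <- 10^ls_grid

  # grid over (xc, sigma); for each cell the threshold-integral pieces
  # N(t), D(t) are shared across the whole s grid
  cells <- expand.grid(xc = seq(5, xc_max, by = 0.5),
                       sigma = seq(0, 5, by = 0.5))
  best_grid <- list(val = Inf, par = NULL)
  top <- list()
  for (i in seq_len(nrow(cells))) {
    xc <- cells$xc[i]; sigma <- cells$sigma[i]
    if (sigma == 0) {
      hp <- hazard_params_from_threshold(xc, constants)
      Ss <- survival(t_obs, hp)
      N <- hazard(t_obs, hp) * Ss
      D <- Ss
    } else {
      xs <- seq(xc - 5 * sigma, xc + 5 * sigma, length.out = 61)
      xs <- xs[xs > 0]
      wq <- stats::dnorm(xs, xc, sigma); wq <- wq / sum(wq)
      A <- exp(constants$A0 + constants$A1 * xs)
      b <- exp(constants$b0 + constants$b1 * xs)
      a <- constants$a0 + constants$a1 * xs
      u <- outer(t_obs, a) + rep(log(b), each = length(t_obs))
      H <- stats::plogis(u) * rep(A / b, each = length(t_obs))
      S <- exp(-(log1pexp(u) - rep(log1p(b), each = length(t_obs))) *
                 rep(A / (a * b), each = length(t_obs)))
      N <- as.vector((H * S) %*% wq)
      D <- as.vector(S %*% wq)
    }
    for (j in seq_along(s_grid)) {
      s <- s_grid[j]
      pred <- s * N / (s * D + (1 - s) * Sd)
      v <- sum(wts * (obs - pred)^2)
      if (v < best_grid$val) best_grid <- list(val = v)
      top[[length(top) + 1L]] <- list(v = v, par = c(xc, ls_grid[j], sigma))
    }
  }
  vs <- vapply(top, function(x) x$v, numeric(1))
  starts <- lapply(order(vs)[1:5], function(i) top[[i]]$par)
  # nested-model guarantee: refine from the 2p optimum as well
  f2 <- fit_2p(curve, constants, allow_super_death)
  starts <- c(starts, list(c(f2$model$xc, log10(f2$model$s), 0)))
  best <- refine_starts(obj, starts, lower = c(5, -5, 0),
                        upper = c(xc_max, 0, 5))
  finish_fit(curve, constants, best, "three-parameter")
}
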