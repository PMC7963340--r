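#' Disease model: threshold(s) and susceptible fraction
#'
#' In the two-parameter model a disease is characterised by a single
#' senescent-cell threshold `xc` and a susceptible fraction `s`: only a
#' fraction `s` of the population has a reachable threshold, and onset
#' occurs when an individual's senescent-cell abundance first crosses it.
#' The three-parameter model draws each susceptible individual's threshold
#' from a normal distribution with mean `xc` and standard deviation
#' `sigma` (truncated at positive values).
#'
#' Thresholds above the death threshold are permitted (used for
#' dementia-like incidence curves with exceptionally steep slopes) but
#' flagged with a warning.
#'
#' @param xc Threshold mean, X-units, `xc > 0`.
#' @param s Susceptible fraction in `(0, 1]`.
#' @param sigma Threshold standard deviation in X-units; `0` gives the
#'   two-parameter model.
#' @param xdeath Death threshold used only for the above-death warning.
#' @return An object of class `"disease_model"`.
#' @export
#' @examples
#' disease_model(xc = 14, s = 0.1)
disease_model <- function(xc, s, sigma = 0, xdeath = 17) {
  stopifnot(is.numeric(xc), length(xc) == 1L, xc > 0,
            is.numeric(s), length(s) == 1L, s > 0, s <= 1,
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (xc > xdeath) {
    warning("threshold xc = ", xc, " exceeds the death threshold ", xdeath,
            "; incidence slope exceeds the mortality slope", call. = FALSE)
  }
  structure(list(xc = xc, s = s, sigma = sigma), class = "disease_model")
}

#' Two-parameter incidence curve
#'
#' Population incidence rate of a disease with threshold `xc` and
#' susceptible fraction `s`:
#' \deqn{I(t) = \frac{s\, h(t)\, S_s(t)}{s\, S_s(t) + (1-s)\, S_d(t)}}
#' where `h` and `S_s` are the disease hazard and survival for the
#' threshold `xc` (via [hazard_params_from_threshold()]) and `S_d` is the
#' death survival with parameters `(Ad, bd, ad)`. Susceptible individuals
#' leave the at-risk pool by disease onset; non-susceptible individuals by
#' death. At old ages most susceptibles have already succumbed, so the
#' at-risk pool is dominated by non-susceptibles and incidence declines.
#'
#' @param t Age(s) in years; vectorised.
#' @param model A [disease_model()]; `sigma` is ignored (taken as 0).
#' @param constants A [regression_constants()] object.
#' @return Incidence rate(s) per person-year.
#' @export
#' @examples
#' incidence_2p(seq(40, 100, 10), disease_model(14, 0.1))
incidence_2p <- function(t, model, constants = regression_constants()) {
  stopifnot(inherits(model, "disease_model"), all(t >= 0))
  hp <- hazard_params_from_threshold(model$xc, constants)
  hd <- death_hazard_params(constants)
  s <- model$s
  Ss <- survival(t, hp)
  Sd <- survival(t, hd)
  s * hazard(t, hp) * Ss / (s * Ss + (1 - s) * Sd)
}

#' Three-parameter incidence curve
#'
#' Extends [incidence_2p()] with a normal distribution of thresholds
#' (mean `xc`, sd `sigma`) across the susceptible fraction:
#' \deqn{I(t) = \frac{\int h(t|X_c)\, C_s(t, X_c)\, P(X_c)\, dX_c}
#'                   {\int C_s(t, X_c)\, P(X_c)\, dX_c + C(t)}}
#' with \eqn{C_s = s\, S_s(t|X_c)} and \eqn{C = (1-s)\, S_d(t)}.
#' The threshold integral uses 201 evenly spaced quadrature nodes on
#' `xc` ± 5 `sigma`, truncated below at positive thresholds with weight
#' renormalisation. `sigma = 0` returns [incidence_2p()] exactly.
#'
#' A wider threshold distribution admits low thresholds reached at young
#' ages, so increasing `sigma` at fixed `(xc, s)` flattens the log-slope
#' of the incidence curve.
#'
#' @inheritParams incidence_2p
#' @param model A [disease_model()] with `sigma >= 0`.
#' @param nodes Number of quadrature nodes.
#' @return Incidence rate(s) per person-year.
#' @export
incidence_3p <- function(t, model, constants = regression_constants(),
                         nodes = 201L) {
  stopifnot(inherits(model, "disease_model"), all(t >= 0), nodes >= 3L)
  if (model$sigma == 0) {
    return(incidence_2p(t, model, constants))
  }
  xs <- seq(model$xc - 5 * model$sigma, model$xc + 5 * model$sigma,
            length.out = nodes)
  keep <- xs > 0
  if (!any(keep)) stop("threshold distribution has no mass at positive Xc")
  xs <- xs[keep]
  w <- stats::dnorm(xs, model$xc, model$sigma)
  w <- w / sum(w)

  # matrices (ages x nodes) of hazard and survival per node threshold
  A <- exp(constants$A0 + constants$A1 * xs)
  b <- exp(constants$b0 + constants$b1 * xs)
  a <- constants$a0 + constants$a1 * xs
  u <- outer(t, a) + rep(log(b), each = length(t))
  H <- stats::plogis(u) * rep(A / b, each = length(t))
  cumh <- (log1pexp(u) - rep(log1p(b), each = length(t))) *
    rep(A / (a * b), each = length(t))
  S <- exp(-cumh)

  num <- as.vector((H * S) %*% w)
  den <- as.vector(S %*% w)
  Sd <- survival(t, death_hazard_params(constants))
  model$s * num / (model$s * den + (1 - model$s) * Sd)
}

#' Incidence for a disease model (dispatch on sigma)
#'
#' Calls [incidence_3p()] when `model$sigma > 0`, else [incidence_2p()].
#'
#' @inheritParams incidence_2p
#' @return Incidence rate(s) per person-year.
#' @export
model_incidence <- function(t, model, constants = regression_constants()) {
  if (model$sigma > 0) incidence_3p(t, model, constants)
  else incidence_2p(t, model, constants)
}

#' Age of maximal incidence
#'
#' Argmax of the model incidence on a grid (ties broken to the youngest
#' age). If the curve is monotone over the whole grid the corresponding
#' endpoint is returned with a warning. For small susceptible fractions
#' the peak age rises approximately linearly with the threshold `xc`.
#'
#' @inheritParams incidence_2p
#' @param ages Evaluation grid in years.
#' @return Age of maximal incidence, years.
#' @export
peak_age <- function(model, constants = regression_constants(),
                     ages = seq(0, 110, by = 0.1)) {
  inc <- model_incidence(ages, model, constants)
  d <- diff(inc)
  if (all(d >= 0) || all(d <= 0)) {
    warning("incidence is monotone on the grid; returning the grid endpoint",
            call. = FALSE)
    return(if (all(d >= 0)) ages[length(ages)] else ages[1])
  }
  ages[which.max(inc)]
}

#' Exact model incidence on an age grid, as an incidence curve
#'
#' Convenience wrapper returning an [incidence_curve()] of
#' [model_incidence()] values; the noiseless backbone of synthetic
#' fixtures.
#'
#' @inheritParams incidence_2p
#' @param ages Bin-center ages, years.
#' @return An [incidence_curve()].
#' @export
model_curve <- function(model, ages = seq(0.5, 109.5, by = 1),
                        constants = regression_constants()) {
  incidence_curve(ages, model_incidence(ages, model, constants))
}
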