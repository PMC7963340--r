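#' Regression constants of the threshold-to-hazard map
#'
#' The first-passage hazard of the saturated-removal (SR) process across a
#' threshold `Xc` is well approximated by a logistic-in-time hazard
#' \eqn{h(t) = A e^{at} / (1 + b e^{at})} whose parameters depend
#' log-linearly (natural log) on the threshold:
#' \eqn{\log A = A_0 + A_1 X_c}, \eqn{\log b = b_0 + b_1 X_c},
#' \eqn{a = a_0 + a_1 X_c}. Death corresponds to the threshold
#' `Xdeath`, with hazard parameters `(Ad, bd, ad)`.
#'
#' The defaults reproduce the death parameters from the threshold map to
#' within rounding of the printed coefficients (see
#' [hazard_params_from_threshold()]), which pins down the natural-log
#' convention.
#'
#' @param A0,A1 Intercept and slope of `log A` versus threshold.
#' @param b0,b1 Intercept and slope of `log b` versus threshold.
#' @param a0,a1 Intercept and slope (per year per X-unit) of `a` versus
#'   threshold.
#' @param Ad,bd,ad Death-hazard parameters (amplitude per year,
#'   dimensionless saturation, slope per year).
#' @param Xdeath Death threshold in X-units.
#' @return An object of class `"regression_constants"`.
#' @export
#' @examples
#' ct <- regression_constants()
#' hazard_params_from_threshold(17, ct)
regression_constants <- function(A0 = 4.14, A1 = -1.01,
                                 b0 = 2.24, b1 = -0.81,
                                 a0 = -0.0186, a1 = 0.0089,
                                 Ad = 2.22e-6, bd = 9.774e-6, ad = 0.132,
                                 Xdeath = 17) {
  stopifnot(is.numeric(ad), ad > 0, Ad > 0, bd > 0, Xdeath > 0)
  structure(
    list(A0 = A0, A1 = A1, b0 = b0, b1 = b1, a0 = a0, a1 = a1,
         Ad = Ad, bd = bd, ad = ad, Xdeath = Xdeath),
    class = "regression_constants"
  )
}

#' Hazard parameters
#'
#' Container for the logistic-in-time hazard
#' \eqn{h(t) = A e^{at}/(1 + b e^{at})}.
#'
#' @param A Amplitude (per year), `A > 0`.
#' @param b Saturation constant (dimensionless), `b > 0`.
#' @param a Exponential slope (per year); may be negative for very low
#'   thresholds.
#' @return An object of class `"hazard_params"`.
#' @export
hazard_params <- function(A, b, a) {
  stopifnot(is.numeric(A), is.numeric(b), is.numeric(a),
            length(A) == 1L, length(b) == 1L, length(a) == 1L,
            A > 0, b > 0, is.finite(a))
  structure(list(A = A, b = b, a = a), class = "hazard_params")
}

#' Map a disease threshold to hazard parameters
#'
#' Evaluates the log-linear regression map (natural logarithm):
#' `A = exp(A0 + A1 * xc)`, `b = exp(b0 + b1 * xc)`, `a = a0 + a1 * xc`.
#' At `xc = Xdeath = 17` the map reproduces the death parameters
#' `(Ad, bd, ad)` to within the rounding of the printed coefficients.
#'
#' @param xc Disease threshold in X-units, `xc > 0`.
#' @param constants A [regression_constants()] object.
#' @return A [hazard_params()] object.
#' @export
hazard_params_from_threshold <- function(xc, constants = regression_constants()) {
  stopifnot(inherits(constants, "regression_constants"),
            is.numeric(xc), length(xc) == 1L, xc > 0)
  hazard_params(A = exp(constants$A0 + constants$A1 * xc),
                b = exp(constants$b0 + constants$b1 * xc),
                a = constants$a0 + constants$a1 * xc)
}

#' Death-hazard parameters
#'
#' Convenience accessor for the `(Ad, bd, ad)` triple of a
#' [regression_constants()] object.
#'
#' @inheritParams hazard_params_from_threshold
#' @return A [hazard_params()] object.
#' @export
death_hazard_params <- function(constants = regression_constants()) {
  hazard_params(constants$Ad, constants$bd, constants$ad)
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  small <- x < 35
  out[small] <- log1p(exp(x[small]))
  out
}

#' Logistic-in-time hazard
#'
#' \eqn{h(t) = A e^{at}/(1 + b e^{at})}, evaluated in log-space as
#' `(A/b) * plogis(a t + log b)` so it is stable for arbitrarily large
#' `a * t`. For `a > 0` the hazard rises exponentially (Gompertz-like) and
#' plateaus at `A/b`.
#'
#' @param t Age(s) in years, `t >= 0`; vectorised.
#' @param hp A [hazard_params()] object.
#' @return Hazard rate(s), per year.
#' @export
hazard <- function(t, hp) {
  stopifnot(inherits(hp, "hazard_params"), all(t >= 0))
  (hp$A / hp$b) * stats::plogis(hp$a * t + log(hp$b))
}

#' Survival function of the logistic-in-time hazard
#'
#' Exact integral of [hazard()]:
#' \eqn{S(t) = [(1 + b e^{at})/(1 + b)]^{-A/(ab)}}, computed in log-space.
#' The removable singularity at `a = 0` is handled by the limit form
#' `exp(-A t / (1 + b))`.
#'
#' @inheritParams hazard
#' @return Survival probability(ies) in `[0, 1]`.
#' @export
survival <- function(t, hp) {
  stopifnot(inherits(hp, "hazard_params"), all(t >= 0))
  exp(-cumulative_hazard(t, hp))
}

#' Cumulative hazard of the logistic-in-time hazard
#'
#' \eqn{H(t) = (A/(ab)) [\log(1 + b e^{at}) - \log(1 + b)]}, with the
#' `a = 0` limit `A t / (1 + b)`.
#'
#' @inheritParams hazard
#' @return Cumulative hazard(s), dimensionless.
#' @export
cumulative_hazard <- function(t, hp) {
  stopifnot(inherits(hp, "hazard_params"), all(t >= 0))
  if (abs(hp$a) < 1e-12) {
    hp$A * t / (1 + hp$b)
  } else {
    (hp$A / (hp$a * hp$b)) * (log1pexp(hp$a * t + log(hp$b)) - log1p(hp$b))
  }
}

#' Invert the survival function
#'
#' Solves `survival(t, hp) = p` for `t`; used for inverse-CDF sampling of
#' onset and death ages in closed-form cohorts.
#'
#' @param p Survival probability(ies) in `(0, 1]`.
#' @inheritParams hazard
#' @return Age(s) in years at which survival first reaches `p`.
#' @export
survival_inverse <- function(p, hp) {
  stopifnot(inherits(hp, "hazard_params"), all(p > 0), all(p <= 1))
  if (abs(hp$a) < 1e-12) {
    return(-log(p) * (1 + hp$b) / hp$A)
  }
  # S = ((1 + b e^{at})/(1+b))^(-A/(ab))  =>
  # b e^{at} = (1+b) S^(-ab/A) - 1
  z <- exp(log1p(hp$b) - (hp$a * hp$b / hp$A) * log(p)) - 1
  t <- ifelse(z > 0, (log(pmax(z, .Machine$double.xmin)) - log(hp$b)) / hp$a, Inf)
  # a < 0 makes survival plateau above 0; probabilities below the plateau
  # are never reached
  if (hp$a < 0) t[p < exp(log1p(hp$b) * hp$A / (hp$a * hp$b))] <- Inf
  t[p == 1] <- 0
  pmax(t, 0)
}
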