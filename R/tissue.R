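#' Frontline-tissue feedback circuit
#'
#' Progenitor (`S`) / differentiated (`D`) population dynamics:
#' \deqn{dS/dt = (p - q - r_1) S, \qquad dD/dt = q S - r_2 D}
#' with proliferation \eqn{p = p_{max}\, g_X(X) \prod f(\cdot)} and
#' differentiation \eqn{q = q_0 \prod f(\cdot)}. Four feedback arrows
#' (S and D acting on proliferation and on differentiation) each carry a
#' sign: positive arrows contribute a saturating factor `u/(1+u)`,
#' negative arrows `1/(1+u)`, absent arrows 1. All factors are bounded
#' by 1, so `p_max` is the true maximal proliferation rate and no
#' feedback can rescue the tissue once the progenitor removal rate
#' exceeds it. Senescent cells slow progenitor proliferation through
#' \eqn{g_X(X) = 1/(1 + X/X_{half})}.
#'
#' With four signs in \{-1, 0, +1\} there are 81 possible circuit
#' topologies.
#'
#' The default rates put cell turnover on its biological timescale of
#' days to weeks (tens per year), fast relative to the senescent-cell
#' dynamics; the tissue then tracks `X(t)` nearly instantaneously and
#' collapse behaves as a first-passage event of `X` itself.
#'
#' @param signs Length-4 integer vector in `{-1, 0, 1}`:
#'   (S->proliferation, D->proliferation, S->differentiation,
#'   D->differentiation).
#' @param p_max Maximal progenitor proliferation rate, per year.
#' @param q0 Basal differentiation rate, per year.
#' @param r1 Progenitor removal rate, per year.
#' @param r2 Differentiated-cell removal rate, per year.
#' @param x_half Senescent-cell level halving progenitor proliferation,
#'   X-units.
#' @return An object of class `"tissue_circuit"`.
#' @export
#' @examples
#' tissue_circuit(c(0, -1, 0, 0))  # differentiated cells inhibit proliferation
tissue_circuit <- function(signs = c(0, 0, 0, 0), p_max = 40, q0 = 20,
                           r1 = 6, r2 = 6, x_half = 25) {
  signs <- as.integer(signs)
  stopifnot(length(signs) == 4L, all(signs %in% c(-1L, 0L, 1L)),
            p_max > 0, q0 > 0, r1 > 0, r2 > 0, x_half > 0)
  structure(list(signs = signs, p_max = p_max, q0 = q0, r1 = r1, r2 = r2,
                 x_half = x_half),
            class = "tissue_circuit")
}

arrow_factor <- function(u, sign) {
  if (sign > 0) u / (1 + u) else if (sign < 0) 1 / (1 + u) else rep(1, length(u))
}

#' Tissue circuit right-hand side
#'
#' Time derivatives of the progenitor and differentiated populations at
#' state `(S, D)` under senescent-cell level `X`.
#'
#' @param circuit A [tissue_circuit()].
#' @param S,D Population sizes, `>= 0`.
#' @param X Senescent-cell level, `>= 0`.
#' @return Numeric `c(dS, dD)`, per year.
#' @export
circuit_dynamics <- function(circuit, S, D, X = 0) {
  stopifnot(inherits(circuit, "tissue_circuit"))
  if (any(c(S, D, X) < 0)) stop("populations and X must be non-negative")
  gx <- 1 / (1 + X / circuit$x_half)
  p <- circuit$p_max * gx * arrow_factor(S, circuit$signs[1]) *
    arrow_factor(D, circuit$signs[2])
  q <- circuit$q0 * arrow_factor(S, circuit$signs[3]) *
    arrow_factor(D, circuit$signs[4])
  c(dS = (p - q - circuit$r1) * S, dD = q * S - circuit$r2 * D)
}

tissue_rhs <- function(t, y, parms) {
  # stiff-solver trial steps may dip infinitesimally below zero
  y <- pmax(y, 0)
  list(circuit_dynamics(parms$circuit, y[1], y[2], parms$X))
}

#' Locate a tissue steady state
#'
#' Integrates the circuit to a candidate steady state, polishes it with
#' damped Newton iterations on the right-hand side, and reports the
#' Jacobian eigenvalues (by central finite differences).
#'
#' @param circuit A [tissue_circuit()].
#' @param X Senescent-cell level.
#' @param init Initial `(S, D)`.
#' @param t_max Integration time for the transient, years.
#' @return List with `S`, `D`, `residual`, `eigenvalues`, and `positive`
#'   (`TRUE` if both populations are bounded away from zero).
#' @export
tissue_steady_state <- function(circuit, X = 0, init = c(1, 1),
                                t_max = 400) {
  sol <- deSolve::ode(y = c(S = init[1], D = init[2]),
                      times = c(0, t_max / 2, t_max), func = tissue_rhs,
                      parms = list(circuit = circuit, X = X),
                      method = "lsoda")
  y <- pmax(as.numeric(sol[nrow(sol), 2:3]), 0)
  # damped Newton polish
  for (it in 1:50) {
    f <- circuit_dynamics(circuit, y[1], y[2], X)
    if (max(abs(f)) < 1e-12) break
    J <- tissue_jacobian(circuit, y, X)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- y + lambda * step
      if (all(cand >= 0)) {
        fc <- circuit_dynamics(circuit, cand[1], cand[2], X)
        if (sum(fc^2) < sum(f^2) || lambda < 1e-4) break
      }
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    y <- pmax(y + lambda * step, 0)
  }
  f <- circuit_dynamics(circuit, y[1], y[2], X)
  ev <- eigen(tissue_jacobian(circuit, y, X), only.values = TRUE)$values
  list(S = y[1], D = y[2], residual = max(abs(f)), eigenvalues = ev,
       positive = all(y > 1e-6))
}

tissue_jacobian <- function(circuit, y, X, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    hp <- pmax(h * max(1, abs(y[j])), 1e-9)
    up <- y; up[j] <- up[j] + hp
    dn <- y; dn[j] <- max(dn[j] - hp, 0)
    J[, j] <- (circuit_dynamics(circuit, up[1], up[2], X) -
                 circuit_dynamics(circuit, dn[1], dn[2], X)) / (up[j] - dn[j])
  }
  J
}

is_homeostatic <- function(circuit, X = 0) {
  ss <- tissue_steady_state(circuit, X = X)
  if (!ss$positive || ss$residual > 1e-6) return(list(ok = FALSE, ss = ss))
  if (max(Re(ss$eigenvalues)) > -1e-8) return(list(ok = FALSE, ss = ss))
  # robustness: +/-20% initial-condition perturbations must return
  for (fs in c(0.8, 1.2)) {
    for (fd in c(0.8, 1.2)) {
      sol <- deSolve::ode(y = c(S = fs * ss$S, D = fd * ss$D),
                          times = c(0, 400), func = tissue_rhs,
                          parms = list(circuit = circuit, X = X),
                          method = "lsoda")
      y <- as.numeric(sol[nrow(sol), 2:3])
      if (max(abs(y - c(ss$S, ss$D)) / pmax(c(ss$S, ss$D), 1e-12)) > 0.01)
        return(list(ok = FALSE, ss = ss))
    }
  }
  list(ok = TRUE, ss = ss)
}

#' Scan all 81 feedback topologies
#'
#' Classifies every sign assignment of the four feedback arrows as
#' homeostatic or not under a shared rate set: homeostatic means a
#' linearly stable steady state with positive progenitor and
#' differentiated populations that is re-attained after 20%
#' initial-condition perturbations.
#'
#' @param p_max,q0,r1,r2,x_half Shared circuit rates (see
#'   [tissue_circuit()]); requires `r1 < p_max`, otherwise no circuit can
#'   sustain the tissue.
#' @return Data frame with one row per topology: the four signs, the
#'   `homeostatic` flag, steady-state `S` and `D` (`NA` when absent) and
#'   the largest eigenvalue real part.
#' @export
scan_topologies <- function(p_max = 40, q0 = 20, r1 = 6, r2 = 6,
                            x_half = 25) {
  if (r1 >= p_max)
    stop("progenitor removal exceeds maximal proliferation: ",
         "homeostasis is impossible (tissue catastrophe)")
  signs <- expand.grid(s_to_p = c(-1L, 0L, 1L), d_to_p = c(-1L, 0L, 1L),
                       s_to_q = c(-1L, 0L, 1L), d_to_q = c(-1L, 0L, 1L))
  res <- lapply(seq_len(nrow(signs)), function(i) {
    circ <- tissue_circuit(as.integer(signs[i, ]), p_max, q0, r1, r2,
                           x_half)
    h <- is_homeostatic(circ)
    data.frame(signs[i, ],
               homeostatic = h$ok,
               S = if (h$ok) h$ss$S else NA_real_,
               D = if (h$ok) h$ss$D else NA_real_,
               max_re_eig = max(Re(h$ss$eigenvalues)))
  })
  do.call(rbind, res)
}

#' Incidence of tissue-collapse events under senescent-cell load
#'
#' For each simulated individual the circuit is driven by that
#' individual's stochastic SR trajectory (proliferation scaled by
#' `g_X(X(t))`); a collapse event is recorded when the differentiated
#' population first falls below `threshold_criterion` times its baseline
#' steady state. Collapse ages aggregate to an incidence curve of the
#' same threshold-crossing type as the disease model: effective
#' proliferation drops below removal once `X` exceeds the level implied
#' by `g_X(Xc) p_max = q + r1` at the operating point.
#'
#' @param circuit A [tissue_circuit()]; must be homeostatic at `X = 0`.
#' @param sr [sr_parameters()] driving the senescent-cell process.
#' @param n Number of individuals.
#' @param threshold_criterion Collapse when `D` falls below this fraction
#'   of the baseline steady state.
#' @param seed Integer RNG seed.
#' @param horizon Follow-up limit, years.
#' @param dt Integration step, years.
#' @param bin_width Aggregation bin width, years.
#' @return An [incidence_curve()] of collapse events.
#' @export
collapse_incidence <- function(circuit, sr = sr_default_parameters(),
                               n = 10000, threshold_criterion = 0.1,
                               seed = 1L, horizon = 110, dt = 0.01,
                               bin_width = 1) {
  stopifnot(inherits(circuit, "tissue_circuit"), n >= 1,
            threshold_criterion > 0, threshold_criterion < 1)
  h <- is_homeostatic(circuit, X = 0)
  if (!h$ok)
    stop("circuit is not homeostatic at X = 0; collapse incidence is ",
         "only defined for circuits that sustain the tissue in youth")
  set.seed(seed)
  res <- sr_engine(sr, n = n, dt = dt, horizon = horizon,
                   tissue = list(signs = circuit$signs,
                                 p_max = circuit$p_max, q0 = circuit$q0,
                                 r1 = circuit$r1, r2 = circuit$r2,
                                 x_half = circuit$x_half,
                                 s0 = h$ss$S, d0 = h$ss$D,
                                 d_crit = threshold_criterion * h$ss$D))
  collapse <- res$collapse_age
  exit <- ifelse(is.na(collapse), res$horizon, collapse)
  rate_curve(event_ages = collapse[!is.na(collapse)], exit_ages = exit,
             horizon = res$horizon, bin_width = bin_width)
}
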