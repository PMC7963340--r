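# shared fixtures and oracles for the test suite

ct_default <- regression_constants()

# quadrature oracle for the survival function: exp(-integral of hazard)
quad_survival <- function(t, hp) {
  vapply(t, function(tt) {
    if (tt == 0) return(1)
    exp(-stats::integrate(function(u) hazard(u, hp), 0, tt,
                          rel.tol = 1e-12, abs.tol = 1e-14)$value)
  }, numeric(1))
}

# fine-grid Riemann oracle for the threshold-distribution incidence
riemann_incidence_3p <- function(t, model, constants = ct_default,
                                 n_nodes = 1e4) {
  xs <- seq(max(model$xc - 5 * model$sigma, 1e-9),
            model$xc + 5 * model$sigma, length.out = n_nodes)
  w <- stats::dnorm(xs, model$xc, model$sigma)
  w <- w / sum(w)
  Sd <- survival(t, death_hazard_params(constants))
  vapply(seq_along(t), function(i) {
    num <- den <- 0
    for (j in seq_along(xs)) {
      hp <- hazard_params_from_threshold(xs[j], constants)
      Ss <- survival(t[i], hp)
      num <- num + w[j] * hazard(t[i], hp) * Ss
      den <- den + w[j] * Ss
    }
    model$s * num / (model$s * den + (1 - model$s) * Sd[i])
  }, numeric(1))
}

# small calibrated-parameter accessor (kept in one place so tests share
# the shipped values)
sr_cal <- function() sr_default_parameters()

# discrete-bin expected hazard for a life-table comparison
bin_hazard_target <- function(lb, rb, hp) {
  (1 - survival(rb, hp) / survival(lb, hp)) / (rb - lb)
}

make_event_table <- function(onset, death, horizon = 110,
                             susceptible = NULL, threshold = NULL) {
  n <- length(onset)
  structure(data.frame(id = seq_len(n),
                       susceptible = susceptible %||% rep(TRUE, n),
                       threshold = threshold %||% rep(14, n),
                       onset_age = onset, death_age = death),
            horizon = horizon, class = c("event_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
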