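# Saturated-removal (SR) process parameters for the human senescent-cell
# abundance X(t), in units where young-adult X is of order 1 and the
# death threshold is 17. Obtained with calibrate_sr_parameters() against
# the analytic first-passage hazard family (thresholds 12..17); see the
# `calibration` block for provenance.
sr:
  eta: 0.3047901
  beta: 34.11311
  kappa: 1.305935
  epsilon: 28.60057
calibration:
  method: calibrate_sr_parameters
  target: analytic hazard family, regression_constants() defaults
  thresholds: [12, 13, 14, 15, 16, 17]
  stages:
    - {n: 4000, seed: 20210208, dt: 0.05, horizon: 110, maxit: 400}
    - {n: 16000, seed: 20210208, dt: 0.05, horizon: 110, maxit: 250,
       start: previous stage}
    - {n: 10000, seed: 20210208, dt: 0.01, horizon: 110, maxit: 200,
       start: previous stage}
  loss: 0.003810645
  loss_units: event-weighted mean squared log-hazard difference
  converged: true
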