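#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integrator for the saturated-removal (SR) senescent-cell
// process, shared by trajectory simulation, first-passage sampling,
// cohort generation, senolytic-treatment arms and tissue-collapse runs.
//
//   dX = (eta * t - beta * X / (kappa + X)) dt + sqrt(2 * eps) dW,
//   X clamped to >= 0 after each step.
//
// Several "arms" (treatment schedules) are integrated simultaneously and
// share the per-individual, per-step noise increment, so treated and
// untreated cohorts are exactly paired. Each arm tracks the total
// abundance X and the drug-sensitive sub-pool Xs (fraction `sensitive`
// of production). The total follows the single-compartment arithmetic
// exactly, independent of the sensitive split, so a kill fraction of zero
// reproduces the untreated simulation bit for bit.
//
// RNG: R's stream, consumed in a fixed step-major / individual-minor
// order (one normal draw per individual per step, shared across arms).

// [[Rcpp::export]]
List cpp_sr_simulate(int n, double dt, double horizon,
                     double eta, double beta, double kappa, double eps,
                     double x0,
                     NumericMatrix thresholds, // n x K first-crossing targets
                     List schedules,           // per arm: (start, interval, kill, sensitive)
                     int save_every, int n_save,
                     List tissue) {            // empty, or circuit driven by arm-0 X
  if (n < 1) stop("n must be >= 1");
  if (dt <= 0 || horizon <= 0) stop("dt and horizon must be positive");
  const int steps = (int)std::llround(horizon / dt);
  const int K = thresholds.ncol();
  const int m = schedules.size();
  if (m < 1) stop("at least one arm is required");
  if (K > 0 && thresholds.nrow() != n) stop("thresholds must have n rows");

  // per-arm schedule constants
  std::vector<double> st(m), iv(m), kill(m), sens(m), next_app(m);
  for (int a = 0; a < m; ++a) {
    NumericVector sc = schedules[a];
    st[a] = sc[0]; iv[a] = sc[1]; kill[a] = sc[2]; sens[a] = sc[3];
    next_app[a] = (kill[a] > 0.0 && iv[a] > 0.0) ? st[a] : R_PosInf;
  }

  // state: total X and sensitive pool per arm
  std::vector<std::vector<double>> X(m, std::vector<double>(n, x0));
  std::vector<std::vector<double>> Xs(m);
  for (int a = 0; a < m; ++a) Xs[a].assign(n, x0 * sens[a]);

  // crossing records (age of first X >= threshold), NA if never
  std::vector<NumericMatrix> cross(m);
  for (int a = 0; a < m; ++a) {
    cross[a] = NumericMatrix(n, K);
    std::fill(cross[a].begin(), cross[a].end(), NA_REAL);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < K; ++k)
        if (x0 >= thresholds(i, k)) cross[a](i, k) = 0.0;
  }

  // optional tissue circuit (progenitor S, differentiated D), arm 0 drive
  bool has_tissue = tissue.size() > 0;
  double pmax = 0, q0 = 0, r1 = 0, r2 = 0, xhalf = 1, dcrit = 0;
  int sg_sp = 0, sg_dp = 0, sg_sq = 0, sg_dq = 0;
  std::vector<double> Scell, Dcell;
  NumericVector collapse_age;
  if (has_tissue) {
    IntegerVector sg = tissue["signs"];
    sg_sp = sg[0]; sg_dp = sg[1]; sg_sq = sg[2]; sg_dq = sg[3];
    pmax = as<double>(tissue["p_max"]);
    q0 = as<double>(tissue["q0"]);
    r1 = as<double>(tissue["r1"]);
    r2 = as<double>(tissue["r2"]);
    xhalf = as<double>(tissue["x_half"]);
    dcrit = as<double>(tissue["d_crit"]);
    Scell.assign(n, as<double>(tissue["s0"]));
    Dcell.assign(n, as<double>(tissue["d0"]));
    collapse_age = NumericVector(n, NA_REAL);
  }

  // saved trajectories (first n_save individuals, every save_every steps)
  int nsv = std::min(n_save, n);
  int nkeep = (save_every > 0) ? steps / save_every + 1 : 0;
  std::vector<NumericMatrix> paths(m);
  NumericMatrix tis_s, tis_d;
  NumericVector path_times(nkeep > 0 ? nkeep : 0);
  if (nkeep > 0) {
    for (int a = 0; a < m; ++a) paths[a] = NumericMatrix(nkeep, nsv);
    if (has_tissue) { tis_s = NumericMatrix(nkeep, nsv); tis_d = NumericMatrix(nkeep, nsv); }
    for (int a = 0; a < m; ++a)
      for (int i = 0; i < nsv; ++i) paths[a](0, i) = x0;
    if (has_tissue)
      for (int i = 0; i < nsv; ++i) { tis_s(0, i) = Scell[i]; tis_d(0, i) = Dcell[i]; }
    path_times[0] = 0.0;
  }

  const double sq = std::sqrt(2.0 * eps * dt);
  int isave = 1;

  for (int stp = 0; stp < steps; ++stp) {
    const double age = stp * dt;
    const double age_new = (stp + 1) * dt;
    const double prod = eta * age;
    for (int i = 0; i < n; ++i) {
      const double z = norm_rand();
      for (int a = 0; a < m; ++a) {
        double x = X[a][i];
        const double removal = beta * x / (kappa + x);
        const double incr = (prod - removal) * dt + sq * z;
        double xn = x + incr;
        if (xn < 0.0) xn = 0.0;
        // sensitive pool: receives its production share plus a
        // proportional share of removal and noise; kept within [0, xn]
        double ws = (x > 0.0) ? Xs[a][i] / x : sens[a];
        double xs = Xs[a][i] + (prod * sens[a] - removal * ws) * dt + sq * z * ws;
        if (xs < 0.0) xs = 0.0;
        if (xs > xn) xs = xn;
        X[a][i] = xn;
        Xs[a][i] = xs;
        for (int k = 0; k < K; ++k)
          if (ISNA(cross[a](i, k)) && xn >= thresholds(i, k))
            cross[a](i, k) = age_new;
      }
      if (has_tissue) {
        const double x = X[0][i];
        const double gx = 1.0 / (1.0 + x / xhalf);
        const double S = Scell[i], D = Dcell[i];
        auto fac = [](double u, int sg) {
          if (sg > 0) return u / (1.0 + u);
          if (sg < 0) return 1.0 / (1.0 + u);
          return 1.0;
        };
        const double p = pmax * gx * fac(S, sg_sp) * fac(D, sg_dp);
        const double q = q0 * fac(S, sg_sq) * fac(D, sg_dq);
        double Sn = S + (p - q - r1) * S * dt;
        double Dn = D + (q * S - r2 * D) * dt;
        if (Sn < 0.0) Sn = 0.0;
        if (Dn < 0.0) Dn = 0.0;
        Scell[i] = Sn;
        Dcell[i] = Dn;
        if (ISNA(collapse_age[i]) && Dn < dcrit) collapse_age[i] = age_new;
      }
    }
    // senolytic applications at the first step boundary past each
    // scheduled age: remove `kill` of the sensitive pool
    for (int a = 0; a < m; ++a) {
      while (age_new >= next_app[a] - 1e-9) {
        for (int i = 0; i < n; ++i) {
          const double removed = Xs[a][i] * kill[a];
          Xs[a][i] -= removed;
          double xn = X[a][i] - removed;
          X[a][i] = (xn < 0.0) ? 0.0 : xn;
        }
        next_app[a] += iv[a];
      }
    }
    if (nkeep > 0 && (stp + 1) % save_every == 0) {
      for (int a = 0; a < m; ++a)
        for (int i = 0; i < nsv; ++i) paths[a](isave, i) = X[a][i];
      if (has_tissue)
        for (int i = 0; i < nsv; ++i) { tis_s(isave, i) = Scell[i]; tis_d(isave, i) = Dcell[i]; }
      path_times[isave] = age_new;
      ++isave;
    }
    if (stp % 256 == 0) checkUserInterrupt();
  }

  List crossings(m), path_list(m);
  for (int a = 0; a < m; ++a) {
    crossings[a] = cross[a];
    path_list[a] = (nkeep > 0) ? paths[a] : NumericMatrix(0, 0);
  }
  List out = List::create(
    _["crossings"] = crossings,
    _["paths"] = path_list,
    _["path_times"] = path_times,
    _["horizon"] = steps * dt);
  if (has_tissue) {
    out["collapse_age"] = collapse_age;
    if (nkeep > 0) { out["tissue_s"] = tis_s; out["tissue_d"] = tis_d; }
  }
  return out;
}
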