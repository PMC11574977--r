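#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of the circular Q-learning model over a recorded session.
//
// Colors are passed as 0-based indices into the n_colors wheel grid so the
// basis activations can be tabulated once per parameter vector instead of
// per trial. The latent state is advanced deterministically given the
// recorded choices and rewards; the negative log likelihood accumulates
// -log P(chosen) under the softmax policy.
//
// par layout (natural units):
//   0 alpha, 1 kappa_basis, 2 reset_threshold0, 3 volatility,
//   4..7 location_bias[4], 8..9 size_bias[2],
//   10 pref_color_bias, 11 theta_pref, 12 prev_color_bias, 13 alpha_neg
// variant: 0 = no_reset, 1 = reset, 2 = dual_alpha
//
// [[Rcpp::export]]
List forward_pass_cpp(NumericVector par, int variant, int n_basis,
                      int n_colors, double beta_softmax, double beta_reset,
                      IntegerMatrix idx, IntegerMatrix loc,
                      IntegerMatrix sizes, IntegerVector chosen,
                      NumericVector reward, bool traces) {
  const int n = idx.nrow();
  const double alpha = par[0], kappa = par[1], thr0 = par[2], vol = par[3];
  const double prefb = par[10], theta_pref = par[11], prevb = par[12];
  const double alpha_neg = par[13];
  const double two_pi = 2.0 * M_PI;

  // basis activation table: n_colors x n_basis von Mises densities
  const double i0 = R::bessel_i(kappa, 0.0, 2.0); // exponentially scaled
  std::vector<double> B((size_t)n_colors * n_basis);
  std::vector<double> grid(n_colors), prefprox(n_colors);
  for (int k = 0; k < n_colors; ++k) {
    grid[k] = -M_PI + two_pi * k / n_colors;
    double d0 = grid[k] - theta_pref + M_PI;
    double d = d0 - two_pi * std::floor(d0 / two_pi);
    prefprox[k] = M_PI - std::fabs(d - M_PI);
    for (int i = 0; i < n_basis; ++i) {
      double mu = two_pi * i / n_basis;
      B[(size_t)k * n_basis + i] =
        std::exp(kappa * (std::cos(grid[k] - mu) - 1.0)) / (two_pi * i0);
    }
  }
  // proximity (pi - |d|) between grid colors by index difference
  std::vector<double> pd(n_colors);
  for (int k = 0; k < n_colors; ++k) {
    double d = two_pi * k / n_colors;
    if (d >= M_PI) d = two_pi - d;
    pd[k] = M_PI - d;
  }

  std::vector<double> w(n_basis, 0.0);
  int tsr = 1;              // trials since last reset (clock starts at 1)
  int prev_idx = -1;        // previously chosen color index, -1 = none
  double nll = 0.0;

  // tanh(vol * tsr) saturates quickly; tabulate the reset threshold per
  // clock value up to saturation
  int tsr_cap = 1;
  std::vector<double> thr_tab;
  if (variant != 0) {
    tsr_cap = vol > 0 ? (int)std::ceil(20.0 / vol) : 1;
    if (tsr_cap > n + 1) tsr_cap = n + 1;
    if (tsr_cap < 1) tsr_cap = 1;
    thr_tab.resize((size_t)tsr_cap + 1);
    for (int i = 1; i <= tsr_cap; ++i) {
      thr_tab[i] = thr0 / std::tanh(vol * i);
    }
  }

  NumericVector ll, rpe_out, et_out, ent_out, vch_out;
  LogicalVector reset_out;
  NumericMatrix w_out;
  if (traces) {
    ll = NumericVector(n); rpe_out = NumericVector(n);
    et_out = NumericVector(n); ent_out = NumericVector(n);
    reset_out = LogicalVector(n); vch_out = NumericVector(n);
    w_out = NumericMatrix(n, n_basis); // weights after each update
  }

  for (int t = 0; t < n; ++t) {
    double ev[3], v[3];
    for (int j = 0; j < 3; ++j) {
      const int ci = idx(t, j);
      const double *b = &B[(size_t)ci * n_basis];
      double vj = 0.0;
      for (int i = 0; i < n_basis; ++i) vj += w[i] * b[i];
      v[j] = vj;
      double e = vj + par[4 + loc(t, j)];
      const int sz = sizes(t, j);
      if (sz > 0) e += par[7 + sz];
      e += prefb * prefprox[ci];
      if (prev_idx >= 0) {
        int dk = ci - prev_idx; if (dk < 0) dk += n_colors;
        e += prevb * pd[dk];
      }
      ev[j] = e;
    }
    // softmax log-likelihood of the recorded choice
    const int ch = chosen[t];
    double m = std::max(ev[0], std::max(ev[1], ev[2]));
    double z = 0.0;
    for (int j = 0; j < 3; ++j) z += std::exp((ev[j] - m) / beta_softmax);
    double logp = (ev[ch] - m) / beta_softmax - std::log(z);
    nll -= logp;

    // update
    const int ci = idx(t, ch);
    const double *x = &B[(size_t)ci * n_basis];
    const double rpe = reward[t] - v[ch];
    double k = 0.0;
    if (variant != 0) {
      const double thr = thr_tab[tsr < tsr_cap ? tsr : tsr_cap];
      const double a = beta_reset * (std::fabs(rpe) - thr);
      // the sigmoid is numerically exactly 0/1 outside +-40
      k = a > 40.0 ? 1.0 : (a < -40.0 ? 0.0 : 1.0 / (1.0 + std::exp(-a)));
    }
    double a_eff = alpha;
    if (variant == 2 && rpe < 0) a_eff = alpha_neg;
    for (int i = 0; i < n_basis; ++i) {
      w[i] = (1.0 - k) * (w[i] + a_eff * rpe * x[i]) + k * reward[t] * x[i];
    }
    const bool reset = k >= 0.5;
    tsr = reset ? 1 : tsr + 1;
    prev_idx = ci;

    if (traces) {
      ll[t] = logp;
      rpe_out[t] = rpe;
      reset_out[t] = reset;
      vch_out[t] = v[ch];
      for (int i = 0; i < n_basis; ++i) w_out(t, i) = w[i];
      // value over the grid: estimated template (argmax, lowest index on
      // ties) and entropy of the shifted normalized value function
      double vmax = -1e300, vmin = 1e300;
      int amax = 0;
      std::vector<double> vg(n_colors);
      for (int kk = 0; kk < n_colors; ++kk) {
        const double *b = &B[(size_t)kk * n_basis];
        double s = 0.0;
        for (int i = 0; i < n_basis; ++i) s += w[i] * b[i];
        vg[kk] = s;
        if (s > vmax) { vmax = s; amax = kk; }
        if (s < vmin) vmin = s;
      }
      et_out[t] = grid[amax];
      const double dth = two_pi / n_colors;
      double norm = 0.0;
      for (int kk = 0; kk < n_colors; ++kk) {
        norm += (vg[kk] - vmin + 1.0 / n_colors) * dth;
      }
      double ent = 0.0;
      for (int kk = 0; kk < n_colors; ++kk) {
        const double p = (vg[kk] - vmin + 1.0 / n_colors) / norm;
        ent -= p * std::log(p) * dth;
      }
      ent_out[t] = ent;
    }
  }

  List out = List::create(_["nll"] = nll,
                          _["weights"] = NumericVector(w.begin(), w.end()));
  if (traces) {
    out["loglik"] = ll;
    out["rpe"] = rpe_out;
    out["reset"] = reset_out;
    out["est_template"] = et_out;
    out["entropy"] = ent_out;
    out["v_chosen"] = vch_out;
    out["weight_traj"] = w_out;
  }
  return out;
}
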