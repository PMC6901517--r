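#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integrators for the single-cell circuits and their
// signal-coupled populations.  Noise draws use R's RNG (norm_rand), so
// set.seed() on the R side gives bit-reproducible trajectories.
//
// Noise contract: <eta_x(t) eta_x(t')> = 2 T tau_x delta(t-t'), so the
// discrete increment on x is sqrt(2 T dt / tau_x) * Z after dividing the
// drift by tau_x.

// [[Rcpp::export]]
List cpp_sim_cubic(int n_cells, int n_steps, double dt,
                   double tau_a, double tau_y, double eps, double c3,
                   double alpha2, double Tnoise,
                   NumericVector s_ext, bool coupled,
                   double gamma, double K, double alpha1, double Ts,
                   int stride, int n_keep,
                   NumericVector a_init, NumericVector y_init, double s_init) {
  std::vector<double> a(n_cells), y(n_cells);
  for (int j = 0; j < n_cells; ++j) { a[j] = a_init[j]; y[j] = y_init[j]; }
  double s = s_init;
  const bool has_ext = s_ext.size() > 0;

  const int n_rec = n_steps / stride + 1;
  NumericVector rec_s(n_rec), rec_am(n_rec);
  NumericMatrix rec_a(n_rec, n_keep), rec_y(n_rec, n_keep);

  const double sig_a = std::sqrt(2.0 * Tnoise * dt / tau_a);
  const double sig_y = std::sqrt(2.0 * Tnoise * dt / tau_y);
  const double sig_s = (coupled && Ts > 0.0) ? std::sqrt(2.0 * Ts * dt) / gamma : 0.0;

  int r = 0;
  for (int step = 0; step <= n_steps; ++step) {
    double amean = 0.0;
    for (int j = 0; j < n_cells; ++j) amean += a[j];
    amean /= n_cells;
    if (step % stride == 0) {
      rec_s[r] = s; rec_am[r] = amean;
      for (int j = 0; j < n_keep; ++j) { rec_a(r, j) = a[j]; rec_y(r, j) = y[j]; }
      ++r;
    }
    if (step == n_steps) break;

    const double s_now = coupled ? s : (has_ext ? s_ext[step] : 0.0);
    double asum = 0.0;
    for (int j = 0; j < n_cells; ++j) {
      const double aj = a[j], yj = y[j];
      double da = dt * (-aj - c3 * aj * aj * aj + yj + alpha2 * s_now) / tau_a;
      double dy = dt * (-aj - eps * yj) / tau_y;
      if (Tnoise > 0.0) { da += sig_a * norm_rand(); dy += sig_y * norm_rand(); }
      a[j] = aj + da; y[j] = yj + dy;
      asum += aj;
    }
    if (coupled) {
      double ds = dt * (-K * s + alpha1 * asum) / gamma;
      if (sig_s > 0.0) ds += sig_s * norm_rand();
      s += ds;
    }
  }
  return List::create(_["s"] = rec_s, _["a_mean"] = rec_am,
                      _["a"] = rec_a, _["y"] = rec_y);
}

// FitzHugh-Nagumo population.  Signal field: tau_s sdot = -s + alpha1 * sum_j (a_j - a_rs).
// [[Rcpp::export]]
List cpp_sim_fhn(int n_cells, int n_steps, double dt,
                 double tau_a, double tau_y, double eps, double a0,
                 double alpha2, double Tnoise,
                 NumericVector s_ext, bool coupled,
                 double tau_s, double alpha1, double a_rs,
                 int stride, int n_keep,
                 NumericVector a_init, NumericVector y_init, double s_init) {
  std::vector<double> a(n_cells), y(n_cells);
  for (int j = 0; j < n_cells; ++j) { a[j] = a_init[j]; y[j] = y_init[j]; }
  double s = s_init;
  const bool has_ext = s_ext.size() > 0;

  const int n_rec = n_steps / stride + 1;
  NumericVector rec_s(n_rec), rec_am(n_rec);
  NumericMatrix rec_a(n_rec, n_keep), rec_y(n_rec, n_keep);

  const double sig_a = std::sqrt(2.0 * Tnoise * dt / tau_a);
  const double sig_y = std::sqrt(2.0 * Tnoise * dt / tau_y);

  int r = 0;
  for (int step = 0; step <= n_steps; ++step) {
    double amean = 0.0;
    for (int j = 0; j < n_cells; ++j) amean += a[j];
    amean /= n_cells;
    if (step % stride == 0) {
      rec_s[r] = s; rec_am[r] = amean;
      for (int j = 0; j < n_keep; ++j) { rec_a(r, j) = a[j]; rec_y(r, j) = y[j]; }
      ++r;
    }
    if (step == n_steps) break;

    const double s_now = coupled ? s : (has_ext ? s_ext[step] : 0.0);
    double asum = 0.0;
    for (int j = 0; j < n_cells; ++j) {
      const double aj = a[j], yj = y[j];
      double da = dt * (aj - aj * aj * aj / 3.0 - yj + alpha2 * s_now) / tau_a;
      double dy = dt * (aj - eps * yj + a0) / tau_y;
      if (Tnoise > 0.0) { da += sig_a * norm_rand(); dy += sig_y * norm_rand(); }
      a[j] = aj + da; y[j] = yj + dy;
      asum += aj - a_rs;
    }
    if (coupled) s += dt * (-s + alpha1 * asum) / tau_s;
  }
  return List::create(_["s"] = rec_s, _["a_mean"] = rec_am,
                      _["a"] = rec_a, _["y"] = rec_y);
}

// ---- Reduced glycolysis model -------------------------------------------
//
// Per-cell state: ATP, ADP, G (lumped triose/BPG pool), PYR, NAD, NADH,
// and (suspension only) ACE_in.  Reactions:
//   v1 (upper glycolysis): ATP -> ADP + G, Michaelis in ATP with Hill
//       inhibition by ATP (the PFK negative feedback);
//   v2 (condensed GAPDH+PYK): G + 2 ADP + NAD -> 2 ATP + PYR + NADH,
//       Michaelis in G (PYK saturation);
//   v3: ATP consumption k3*ATP;
//   v4 (PDC): PYR -> ACE at rate k4*PYR;
//   v5 (ADH): ACE + NADH -> NAD at rate k5*NADH*ACE;
//   v6 (glycerol shunt): NADH -> NAD at rate k6*NADH (ACE-independent
//       redox sink; without it steady intracellular ACE is forced to zero
//       because ADH would have to consume the full PDC flux).
// Adenine (ATP+ADP) and pyridine (NAD+NADH) pools are conserved.

struct GlycoPars {
  double k1, KA, KI, h, k2, KG, k3, k4, k5, k6;
};

static inline void glyco_rhs(const double* x, double ace, const GlycoPars& p,
                             double* dx) {
  const double ATP = x[0], ADP = x[1], G = x[2], PYR = x[3],
               NAD = x[4], NADH = x[5];
  const double v1 = p.k1 * ATP / (p.KA + ATP) / (1.0 + std::pow(ATP / p.KI, p.h));
  const double v2 = p.k2 * G / (p.KG + G) * ADP * NAD;
  const double v5 = p.k5 * NADH * ace;
  const double v6 = p.k6 * NADH;
  dx[0] = -v1 + 2.0 * v2 - p.k3 * ATP;
  dx[1] =  v1 - 2.0 * v2 + p.k3 * ATP;
  dx[2] =  v1 - v2;
  dx[3] =  v2 - p.k4 * PYR;
  dx[4] = -v2 + v5 + v6;
  dx[5] =  v2 - v5 - v6;
}

// Clamped intracellular ACE: 6-dim RK4.
// [[Rcpp::export]]
NumericMatrix cpp_sim_glyco_clamped(int n_steps, double dt, NumericVector pars,
                                    double ace_in, NumericVector x_init,
                                    int stride) {
  GlycoPars p = {pars[0], pars[1], pars[2], pars[3], pars[4],
                 pars[5], pars[6], pars[7], pars[8], pars[9]};
  double x[6], k1[6], k2[6], k3[6], k4[6], tmp[6];
  for (int i = 0; i < 6; ++i) x[i] = x_init[i];

  const int n_rec = n_steps / stride + 1;
  NumericMatrix rec(n_rec, 6);
  int r = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step % stride == 0) {
      for (int i = 0; i < 6; ++i) rec(r, i) = x[i];
      ++r;
    }
    if (step == n_steps) break;
    glyco_rhs(x, ace_in, p, k1);
    for (int i = 0; i < 6; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
    glyco_rhs(tmp, ace_in, p, k2);
    for (int i = 0; i < 6; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
    glyco_rhs(tmp, ace_in, p, k3);
    for (int i = 0; i < 6; ++i) tmp[i] = x[i] + dt * k3[i];
    glyco_rhs(tmp, ace_in, p, k4);
    for (int i = 0; i < 6; ++i)
      x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (!std::isfinite(x[0]))
      stop("glycolysis integration diverged at step %d", step);
  }
  return rec;
}

// Suspension: n_cells cells, each with 7-dim state (ATP, ADP, G, PYR, NAD,
// NADH, ACE_in) plus one shared ACE_ex.  Membrane exchange D*(ACE_ex-ACE_in);
// extracellular balance rho-weighted.  External ACE signal s_ext (if given)
// is added to ACE_ex seen by cells (for response measurements).
// [[Rcpp::export]]
List cpp_sim_glyco_susp(int n_cells, int n_steps, double dt, NumericVector pars,
                        double kin, double kex, double D, double rho,
                        NumericMatrix x_init, double ace_ex_init,
                        NumericVector s_ext, bool clamp_ex,
                        int stride, int n_keep) {
  GlycoPars p = {pars[0], pars[1], pars[2], pars[3], pars[4],
                 pars[5], pars[6], pars[7], pars[8], pars[9]};
  const int d = 7;
  std::vector<double> x(n_cells * d);
  for (int j = 0; j < n_cells; ++j)
    for (int i = 0; i < d; ++i) x[j * d + i] = x_init(j, i);
  double ace_ex = ace_ex_init;
  const bool has_ext = s_ext.size() > 0;

  // RK4 over the full coupled system
  std::vector<double> k(4 * (n_cells * d + 1)), tmp(n_cells * d + 1);
  const int n_rec = n_steps / stride + 1;
  NumericMatrix rec_cell(n_rec, d * n_keep);
  NumericVector rec_ex(n_rec), rec_ace_mean(n_rec);

  auto rhs = [&](const std::vector<double>& xs, double ex, double forcing,
                 double* out, double& dex) {
    double exch_sum = 0.0;
    const double ex_seen = ex + forcing;
    for (int j = 0; j < n_cells; ++j) {
      const double* xj = &xs[j * d];
      double dxj[6];
      const double ace = xj[6];
      glyco_rhs(xj, ace, p, dxj);
      const double exch = D * (ex_seen - ace);
      for (int i = 0; i < 6; ++i) out[j * d + i] = dxj[i];
      // dACE_in = production (v4) - intracellular degradation - ADH use + influx
      const double v4 = p.k4 * xj[3];
      const double v5 = p.k5 * xj[5] * ace;
      out[j * d + 6] = v4 - kin * ace - v5 + exch;
      exch_sum += exch;
    }
    dex = clamp_ex ? 0.0 : (-rho * exch_sum / n_cells - kex * ex);
  };

  std::vector<double> xs(n_cells * d), k1v(n_cells * d), k2v(n_cells * d),
      k3v(n_cells * d), k4v(n_cells * d);
  double e1, e2, e3, e4;

  int r = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step % stride == 0) {
      double am = 0.0;
      for (int j = 0; j < n_cells; ++j) am += x[j * d + 6];
      rec_ace_mean[r] = am / n_cells;
      rec_ex[r] = ace_ex;
      for (int j = 0; j < n_keep; ++j)
        for (int i = 0; i < d; ++i) rec_cell(r, j * d + i) = x[j * d + i];
      ++r;
    }
    if (step == n_steps) break;
    const double f0 = has_ext ? s_ext[step] : 0.0;

    rhs(x, ace_ex, f0, k1v.data(), e1);
    for (size_t i = 0; i < x.size(); ++i) xs[i] = x[i] + 0.5 * dt * k1v[i];
    rhs(xs, ace_ex + 0.5 * dt * e1, f0, k2v.data(), e2);
    for (size_t i = 0; i < x.size(); ++i) xs[i] = x[i] + 0.5 * dt * k2v[i];
    rhs(xs, ace_ex + 0.5 * dt * e2, f0, k3v.data(), e3);
    for (size_t i = 0; i < x.size(); ++i) xs[i] = x[i] + dt * k3v[i];
    rhs(xs, ace_ex + dt * e3, f0, k4v.data(), e4);
    for (size_t i = 0; i < x.size(); ++i)
      x[i] += dt / 6.0 * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
    ace_ex += dt / 6.0 * (e1 + 2.0 * e2 + 2.0 * e3 + e4);
    if (!std::isfinite(x[0]) || !std::isfinite(ace_ex))
      stop("suspension integration diverged at step %d", step);
  }
  return List::create(_["cells"] = rec_cell, _["ace_ex"] = rec_ex,
                      _["ace_in_mean"] = rec_ace_mean);
}
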