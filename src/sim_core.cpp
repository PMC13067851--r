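#include <Rcpp.h>
using namespace Rcpp;

// Fast rational approximation of tanh, adequate for the slow-inward gate switch.
static inline double tanh_fast(double x) {
  if (x > 3.0) return 1.0;
  if (x < -3.0) return -1.0;
  double x2 = x * x;
  return x * (27.0 + x2) / (27.0 + 9.0 * x2);
}

// One segment of explicit monodomain integration with a three-variable
// phenomenological ventricular cell model (fast inward, slow outward, slow
// inward currents gated by Heaviside switches).
//
// State vectors are column-major over an nr x nc grid. Edge weight vectors
// wN/wS/wW/wE already carry D * coupling / h^2 and are exactly zero across the
// conducting-mask boundary (zero-flux). cscale multiplies all ionic currents
// per node. iext is an external (electrical) current in du/dt units; irr is
// normalized irradiance in [0,1] driving the photocurrent
// g * irr * (u_rev - u).
//
// Frames of u are recorded after any step s (1-based within the segment) for
// which (record_offset + s) %% record_every == 0.
// [[Rcpp::export]]
List fk_segment(NumericVector u_, NumericVector v_, NumericVector w_,
                int nr, int nc,
                NumericVector wN, NumericVector wS,
                NumericVector wW, NumericVector wE,
                IntegerVector conducting,
                NumericVector cscale,
                NumericVector pars,
                NumericVector iext,
                NumericVector irr,
                double gphot, double urev,
                double dt, int n_steps,
                int record_every, int record_offset,
                bool react_on, bool diffuse_on) {
  const int n = nr * nc;
  NumericVector u = clone(u_), v = clone(v_), w = clone(w_);
  std::vector<double> unew(u.begin(), u.end());

  const double tau_d   = pars[0], tau_r  = pars[1], tau_si = pars[2],
               tau_0   = pars[3], tau_vp = pars[4], tau_v1m = pars[5],
               tau_v2m = pars[6], tau_wp = pars[7], tau_wm  = pars[8],
               u_c     = pars[9], u_v    = pars[10], u_csi  = pars[11],
               kk      = pars[12];

  const bool has_iext = iext.size() == n;
  const bool has_irr  = irr.size() == n && gphot > 0.0;

  int n_rec = 0;
  if (record_every > 0) {
    for (int s = 1; s <= n_steps; ++s)
      if ((record_offset + s) % record_every == 0) ++n_rec;
  }
  NumericVector frames(record_every > 0 ? (R_xlen_t)n * n_rec : (R_xlen_t)0);
  int rec_i = 0;
  int diverged_step = -1;

  // contiguous conducting range per column (the disc mask): tight inner loops
  // without per-node mask branches
  std::vector<int> r0(nc, -1), r1(nc, -2);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i)
      if (conducting[j * nr + i]) { if (r0[j] < 0) r0[j] = i; r1[j] = i; }
  }
  std::copy(u.begin(), u.end(), unew.begin());

  const double inv_tau_d = 1.0 / tau_d, inv_tau_r = 1.0 / tau_r,
               inv_tau_si = 0.5 / tau_si, inv_tau_0 = 1.0 / tau_0,
               inv_tau_vp = 1.0 / tau_vp, inv_tau_v1m = 1.0 / tau_v1m,
               inv_tau_v2m = 1.0 / tau_v2m, inv_tau_wp = 1.0 / tau_wp,
               inv_tau_wm = 1.0 / tau_wm;

  for (int s = 1; s <= n_steps; ++s) {
    for (int j = 0; j < nc; ++j) {
      if (r0[j] < 0) continue;
      const int off = j * nr;
      const double *up = u.begin();
      for (int i = r0[j]; i <= r1[j]; ++i) {
        const int idx = off + i;
        const double ui = up[idx];
        double du = 0.0;
        if (react_on) {
          const double vi = v[idx], wi = w[idx];
          const double p = ui >= u_c ? 1.0 : 0.0;
          const double q = ui >= u_v ? 1.0 : 0.0;
          const double Jfi = -p * vi * (1.0 - ui) * (ui - u_c) * inv_tau_d;
          const double Jso = p * inv_tau_r + (1.0 - p) * ui * inv_tau_0;
          const double Jsi = -wi * (1.0 + tanh_fast(kk * (ui - u_csi))) * inv_tau_si;
          du -= cscale[idx] * (Jfi + Jso + Jsi);
          const double dv = -p * vi * inv_tau_vp +
            (1.0 - p) * (1.0 - vi) * (q * inv_tau_v2m + (1.0 - q) * inv_tau_v1m);
          const double dw = -p * wi * inv_tau_wp +
            (1.0 - p) * (1.0 - wi) * inv_tau_wm;
          v[idx] = vi + dt * dv;
          w[idx] = wi + dt * dw;
        }
        if (has_iext) du += iext[idx];
        if (has_irr)  du += gphot * irr[idx] * (urev - ui);
        if (diffuse_on) {
          // edge weights are exactly zero across the mask boundary; guard
          // array bounds only where the mask touches the grid edge
          double lap = 0.0;
          if (i > 0)      lap += wN[idx] * (up[idx - 1]  - ui);
          if (i < nr - 1) lap += wS[idx] * (up[idx + 1]  - ui);
          if (j > 0)      lap += wW[idx] * (up[idx - nr] - ui);
          if (j < nc - 1) lap += wE[idx] * (up[idx + nr] - ui);
          du += lap;
        }
        unew[idx] = ui + dt * du;
      }
    }
    for (int j = 0; j < nc; ++j) {
      if (r0[j] < 0) continue;
      std::copy(unew.begin() + (j * nr + r0[j]), unew.begin() + (j * nr + r1[j] + 1),
                u.begin() + (j * nr + r0[j]));
    }

    if (s % 100 == 0 || s == n_steps) {
      bool bad = false;
      for (int idx = 0; idx < n; ++idx) {
        const double a = std::abs(u[idx]);
        if (!(a < 50.0)) { bad = true; break; }   // catches NaN too
      }
      if (bad) { diverged_step = record_offset + s; break; }
    }
    if (record_every > 0 && (record_offset + s) % record_every == 0) {
      std::copy(u.begin(), u.end(), frames.begin() + (R_xlen_t)rec_i * n);
      ++rec_i;
    }
  }

  return List::create(_["u"] = u, _["v"] = v, _["w"] = w,
                      _["frames"] = frames, _["n_rec"] = rec_i,
                      _["diverged_step"] = diverged_step);
}

// First activation time (upstroke crossing of `level`, linear sub-step
// interpolation is left to callers working on recorded frames). Used by the
// protocol driver to time the premature stimulus: returns, per node, the first
// recorded step index at which u crossed `level` upward, or -1.
// [[Rcpp::export]]
IntegerVector first_crossing(NumericVector frames, int n, int n_frames,
                             double level) {
  IntegerVector out(n, -1);
  for (int t = 1; t < n_frames; ++t) {
    const double *prev = frames.begin() + (R_xlen_t)(t - 1) * n;
    const double *cur  = frames.begin() + (R_xlen_t)t * n;
    for (int i = 0; i < n; ++i) {
      if (out[i] < 0 && prev[i] < level && cur[i] >= level) out[i] = t;
    }
  }
  return out;
}
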