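#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Four-population rate model: fixed-step RK4 integration.
// State f = (e, p, s, v); df/dt = (-f + g(net(f))) / tau_m with
// g(u) = coeff * sqrt(u - theta) above threshold, 0 otherwise.
// par layout: S_ee S_ep S_es S_ev S_pe S_pp S_ps S_se S_sv S_ve S_vp S_vs
//             I_e I_p I_s I_v theta tau_m ce cp cs cv
// ---------------------------------------------------------------------------

static inline void rate_deriv(const double *p, const double *f, double *d) {
  const double th = p[16], tau = p[17];
  double u[4];
  u[0] = p[12] + p[0] * f[0] - p[1] * f[1] - p[2] * f[2] - p[3] * f[3];
  u[1] = p[13] + p[4] * f[0] - p[5] * f[1] - p[6] * f[2];
  u[2] = p[14] + p[7] * f[0] - p[8] * f[3];
  u[3] = p[15] + p[9] * f[0] - p[10] * f[1] - p[11] * f[2];
  for (int i = 0; i < 4; ++i) {
    double ex = u[i] - th;
    double g = ex > 0 ? p[18 + i] * std::sqrt(ex) : 0.0;
    d[i] = (-f[i] + g) / tau;
  }
}

// [[Rcpp::export(name = ".rate_rk4_cpp")]]
NumericMatrix rate_rk4_cpp(NumericVector par, NumericVector initial,
                           double duration, double dt, int record) {
  int n = (int)std::lround(duration / dt);
  int nkeep = n / record + 1;
  NumericMatrix out(nkeep, 5);
  double f[4], k1[4], k2[4], k3[4], k4[4], tmp[4];
  for (int i = 0; i < 4; ++i) f[i] = std::max(initial[i], 0.0);
  const double *p = par.begin();
  out(0, 0) = 0.0;
  for (int i = 0; i < 4; ++i) out(0, i + 1) = f[i];
  int k = 1;
  for (int s = 1; s <= n; ++s) {
    rate_deriv(p, f, k1);
    for (int i = 0; i < 4; ++i) tmp[i] = std::max(f[i] + dt / 2 * k1[i], 0.0);
    rate_deriv(p, tmp, k2);
    for (int i = 0; i < 4; ++i) tmp[i] = std::max(f[i] + dt / 2 * k2[i], 0.0);
    rate_deriv(p, tmp, k3);
    for (int i = 0; i < 4; ++i) tmp[i] = std::max(f[i] + dt * k3[i], 0.0);
    rate_deriv(p, tmp, k4);
    for (int i = 0; i < 4; ++i) {
      f[i] = std::max(f[i] + dt / 6 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]), 0.0);
      if (!R_finite(f[i]))
        stop("non-finite rate-model state at t = %f ms", s * dt);
    }
    if (s % record == 0 && k < nkeep) {
      out(k, 0) = s * dt;
      for (int i = 0; i < 4; ++i) out(k, i + 1) = f[i];
      ++k;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Multi-start fixed-point solver over the 16 active sets of the rate model.
// For each subset A of {e,p,s,v} solves f_A = g(net_A(f_A)) with the other
// populations pinned at zero, by damped Newton iteration from deterministic
// low-discrepancy (van der Corput) starts placed log-uniformly in
// [f_lo, f_hi] Hz. A root is accepted when the residual is below tol, all
// active rates are strictly positive and every inactive population has net
// drive at or below threshold. Returns the accepted, deduplicated roots.
// ---------------------------------------------------------------------------

static double vdc1(int i, int base) {
  double x = 0.0, denom = 1.0;
  while (i > 0) {
    denom *= base;
    x += (i % base) / denom;
    i /= base;
  }
  return x;
}

static void net4(const double *p, const double *f, double *u) {
  u[0] = p[12] + p[0] * f[0] - p[1] * f[1] - p[2] * f[2] - p[3] * f[3];
  u[1] = p[13] + p[4] * f[0] - p[5] * f[1] - p[6] * f[2];
  u[2] = p[14] + p[7] * f[0] - p[8] * f[3];
  u[3] = p[15] + p[9] * f[0] - p[10] * f[1] - p[11] * f[2];
}

// solve J x = b for k<=4 by Gaussian elimination with partial pivoting
static bool solve_small(int k, double J[4][4], double *b, double *x) {
  int piv[4] = {0, 1, 2, 3};
  for (int c = 0; c < k; ++c) {
    int best = c;
    for (int r = c + 1; r < k; ++r)
      if (std::fabs(J[piv[r]][c]) > std::fabs(J[piv[best]][c])) best = r;
    int tmp = piv[c]; piv[c] = piv[best]; piv[best] = tmp;
    double d = J[piv[c]][c];
    if (std::fabs(d) < 1e-14) return false;
    for (int r = c + 1; r < k; ++r) {
      double m = J[piv[r]][c] / d;
      for (int cc = c; cc < k; ++cc) J[piv[r]][cc] -= m * J[piv[c]][cc];
      b[piv[r]] -= m * b[piv[c]];
    }
  }
  for (int c = k - 1; c >= 0; --c) {
    double s = b[piv[c]];
    for (int cc = c + 1; cc < k; ++cc) s -= J[piv[c]][cc] * x[cc];
    x[c] = s / J[piv[c]][c];
  }
  return true;
}

// [[Rcpp::export(name = ".solve_active_sets_cpp")]]
List solve_active_sets_cpp(NumericVector par, int n_starts,
                           double f_lo, double f_hi,
                           double tol, double dedup_tol, int maxit,
                           NumericMatrix extra_starts) {
  const double *p = par.begin();
  const double th = p[16];
  // signed coupling matrix a[x][y] = d net_x / d f_y
  double a[4][4] = {{p[0], -p[1], -p[2], -p[3]},
                    {p[4], -p[5], -p[6], 0.0},
                    {p[7], 0.0, 0.0, -p[8]},
                    {p[9], -p[10], -p[11], 0.0}};
  const int bases[4] = {2, 3, 5, 7};
  const double llo = std::log(f_lo), lhi = std::log(f_hi);
  std::vector<double> roots;  // flattened rows of 4
  int n_failed = 0;

  // Newton from one start restricted to an active set; returns success
  // and leaves the root in f
  struct Solver {
    const double *p; double (*a)[4]; double th; double tol; int maxit;

    // residual max-norm of f_A - g(net_A); +inf when an active population
    // is at or below threshold (outside the solvable region)
    double resid(int k, const int *idx, const double *f) {
      double u[4];
      net4(p, f, u);
      double rmax = 0.0;
      for (int j = 0; j < k; ++j) {
        double ex = u[idx[j]] - th;
        if (ex <= 0) return R_PosInf;
        double r = f[idx[j]] - p[18 + idx[j]] * std::sqrt(ex);
        if (std::fabs(r) > rmax) rmax = std::fabs(r);
      }
      return rmax;
    }

    bool run(int set, double *f) {
      int idx[4], k = 0;
      for (int x = 0; x < 4; ++x) if (set & (1 << x)) idx[k++] = x;
      double u[4];
      // if the start is outside the suprathreshold region, pull active
      // components up via damped fixed-point steps until inside (or fail)
      for (int it = 0; it < 50; ++it) {
        net4(p, f, u);
        bool sub = false;
        for (int j = 0; j < k; ++j) if (u[idx[j]] - th <= 0) sub = true;
        if (!sub) break;
        for (int j = 0; j < k; ++j) {
          double ex = u[idx[j]] - th;
          double g = ex > 0 ? p[18 + idx[j]] * std::sqrt(ex) : 0.0;
          f[idx[j]] = std::max(0.5 * f[idx[j]] + 0.5 * g, 1e-9);
        }
      }
      double rcur = resid(k, idx, f);
      if (!R_finite(rcur)) return false;
      for (int it = 0; it < maxit; ++it) {
        if (rcur < tol) return true;
        net4(p, f, u);
        double r[4], gp[4], J[4][4], step[4];
        for (int j = 0; j < k; ++j) {
          double ex = u[idx[j]] - th;
          r[j] = f[idx[j]] - p[18 + idx[j]] * std::sqrt(ex);
          gp[j] = p[18 + idx[j]] / (2.0 * std::sqrt(ex));
        }
        for (int j = 0; j < k; ++j)
          for (int j2 = 0; j2 < k; ++j2)
            J[j][j2] = (j == j2 ? 1.0 : 0.0) - gp[j] * a[idx[j]][idx[j2]];
        double b[4];
        for (int j = 0; j < k; ++j) b[j] = r[j];
        if (!solve_small(k, J, b, step)) return false;
        // backtracking line search: accept a step only if it stays
        // positive, stays suprathreshold, and shrinks the residual
        double lam = 1.0;
        bool moved = false;
        while (lam > 1e-8) {
          double fn[4];
          for (int x = 0; x < 4; ++x) fn[x] = f[x];
          bool pos = true;
          for (int j = 0; j < k; ++j) {
            fn[idx[j]] = f[idx[j]] - lam * step[j];
            if (fn[idx[j]] <= 0) pos = false;
          }
          if (pos) {
            double rn = resid(k, idx, fn);
            if (rn < rcur) {
              for (int x = 0; x < 4; ++x) f[x] = fn[x];
              rcur = rn;
              moved = true;
              break;
            }
          }
          lam /= 2.0;
        }
        if (!moved) return false;
      }
      return rcur < tol;
    }
  } solver;
  solver.p = p; solver.a = a; solver.th = th; solver.tol = tol;
  solver.maxit = maxit;

  // accept a converged root if active rates are positive and inactive
  // populations are at or below threshold; dedup against earlier roots
  auto accept = [&](int set, double *f) {
    double u[4];
    net4(p, f, u);
    for (int x = 0; x < 4; ++x) {
      bool active = (set & (1 << x)) != 0;
      if (active && f[x] <= 1e-8) return;
      if (!active && u[x] > th + 1e-7) return;
    }
    for (size_t q = 0; q + 3 < roots.size(); q += 4) {
      double dmax = 0.0;
      for (int x = 0; x < 4; ++x)
        dmax = std::max(dmax, std::fabs(roots[q + x] - f[x]));
      if (dmax < dedup_tol) return;
    }
    for (int x = 0; x < 4; ++x) roots.push_back(f[x]);
  };

  for (int set = 0; set < 16; ++set) {
    int idx[4], k = 0;
    for (int x = 0; x < 4; ++x) if (set & (1 << x)) idx[k++] = x;
    if (k == 0) {
      double f0[4] = {0, 0, 0, 0}, u[4];
      net4(p, f0, u);
      bool ok = true;
      for (int x = 0; x < 4; ++x) if (u[x] > th + 1e-7) ok = false;
      if (ok) for (int x = 0; x < 4; ++x) roots.push_back(0.0);
      continue;
    }
    for (int st = 1; st <= n_starts; ++st) {
      double f[4] = {0, 0, 0, 0};
      for (int j = 0; j < k; ++j)
        f[idx[j]] = std::exp(llo + (lhi - llo) * vdc1(st, bases[j]));
      if (solver.run(set, f)) accept(set, f); else ++n_failed;
    }
  }

  // extra user-supplied starts (e.g. endpoints of integrated trajectories);
  // the active set is inferred from the start's sign pattern
  for (int r0 = 0; r0 < extra_starts.nrow(); ++r0) {
    double f[4];
    int set = 0;
    for (int x = 0; x < 4; ++x) {
      f[x] = extra_starts(r0, x);
      if (f[x] > 1e-6) set |= (1 << x);
      else f[x] = 0.0;
    }
    if (set == 0) continue;
    if (solver.run(set, f)) accept(set, f); else ++n_failed;
  }
  int n_sol = (int)(roots.size() / 4);
  NumericMatrix out(n_sol, 4);
  for (int i = 0; i < n_sol; ++i)
    for (int x = 0; x < 4; ++x) out(i, x) = roots[4 * i + x];
  return List::create(_["roots"] = out, _["n_failed"] = n_failed);
}

// ---------------------------------------------------------------------------
// Clock-driven LIF network simulation with exponentially decaying
// postsynaptic-current channels and delayed spike delivery.
//
// Subthreshold dynamics per step (exact propagators of the linear cascade):
//   V(t+dt) = Vrest + (V - Vrest) e^{-dt/tau_m}
//           + sum_ch I_ch * vc_ch  +  I_const * R (1 - e^{-dt/tau_m})
//   I_ch(t+dt) = I_ch(t) e^{-dt/tau_ch}
// with vc_ch = (tau_m tau_ch / (C (tau_ch - tau_m))) (e^{-dt/tau_ch} -
// e^{-dt/tau_m}); spike arrivals add their weight to the channel at the
// start of the arrival step (PSC peak equals the synaptic weight).
// Threshold crossing emits a spike on the step boundary, resets V and
// clamps it for the refractory period; channels keep integrating.
// All randomness is drawn from the R RNG stream (set.seed upstream).
// ---------------------------------------------------------------------------

// Delivery is range-based: each neuron's synapses are pre-sorted by delay,
// so a spike pushes one (start, end) index range per distinct delay value
// into the ring buffer instead of one event per synapse; the weight adds
// stream through the contiguous synapse arrays at the arrival step.
struct Rng { int start; int end; };

// Poisson sampler by inversion for small rates (the per-step background
// lambdas are ~1), with the pre-computed exp(-lambda); falls back to
// R::rpois for large lambda. Draws from the R RNG stream.
static inline int pois_small(double lam, double explam) {
  if (lam >= 15.0) return (int)R::rpois(lam);
  double p = unif_rand();
  int k = 0;
  while (p > explam) {
    p *= unif_rand();
    ++k;
  }
  return k;
}

// [[Rcpp::export(name = ".simulate_lif_cpp")]]
List simulate_lif_cpp(int n_neur, int n_steps, double dt,
                      IntegerVector chan_offset,
                      NumericVector chan_tau,
                      double tau_m, double C, double V_th, double V_reset,
                      double V_rest, double tau_ref,
                      IntegerVector syn_offset,
                      IntegerVector syn_chan,
                      NumericVector syn_w,
                      IntegerVector syn_delay,
                      NumericVector bg_lambda,
                      NumericVector bg_w, NumericVector bg_dw,
                      IntegerVector bg_chan,
                      NumericVector i_const,
                      NumericVector src_lambda_base,
                      NumericVector src_lambda_stim,
                      IntegerVector src_on, IntegerVector src_off,
                      bool threshold_on,
                      IntegerVector probe_ids,
                      bool probe_current,
                      NumericVector v_init) {
  const int n_chan = chan_tau.size();
  const int n_src = src_lambda_base.size();
  const double dm = std::exp(-dt / tau_m);
  const double Rm = tau_m / C;                     // GOhm when pF/ms, V in mV
  const int ref_steps = (int)std::lround(tau_ref / dt);

  // channel propagator coefficients
  std::vector<double> cdec(n_chan), cvc(n_chan);
  for (int c = 0; c < n_chan; ++c) {
    double ts = chan_tau[c];
    double ds = std::exp(-dt / ts);
    cdec[c] = ds;
    if (std::fabs(ts - tau_m) < 1e-9) {
      cvc[c] = dt * dm / C;
    } else {
      cvc[c] = (tau_m * ts / (C * (ts - tau_m))) * (ds - dm);
    }
  }

  int max_delay = 1;
  for (int i = 0; i < syn_delay.size(); ++i)
    if (syn_delay[i] > max_delay) max_delay = syn_delay[i];
  const int L = max_delay + 1;
  std::vector<std::vector<Rng> > ring(L);

  std::vector<double> V(n_neur, V_rest), I(n_chan, 0.0);
  if (v_init.size() == n_neur)
    for (int i = 0; i < n_neur; ++i) V[i] = v_init[i];
  std::vector<double> bg_explam(bg_lambda.size());
  for (int i = 0; i < bg_lambda.size(); ++i)
    bg_explam[i] = std::exp(-bg_lambda[i]);
  std::vector<double> src_explam_base(n_src), src_explam_stim(n_src);
  for (int i = 0; i < n_src; ++i) {
    src_explam_base[i] = std::exp(-src_lambda_base[i]);
    src_explam_stim[i] = std::exp(-src_lambda_stim[i]);
  }
  std::vector<int> refr(n_neur, 0);
  const bool has_const = i_const.size() == n_neur;
  const bool has_bg = bg_lambda.size() == n_neur;

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(1 << 16);
  sp_t.reserve(1 << 16);

  const int n_probe = probe_ids.size();
  NumericMatrix probe_v(n_probe > 0 ? n_steps : 0, n_probe);
  NumericMatrix probe_i(probe_current && n_probe > 0 ? n_steps : 0,
                        probe_current ? n_probe : 0);

  for (int t = 0; t < n_steps; ++t) {
    // 1. deliver spikes arriving this step
    std::vector<Rng> &slot = ring[t % L];
    for (size_t k = 0; k < slot.size(); ++k) {
      for (int s = slot[k].start; s < slot[k].end; ++s)
        I[syn_chan[s]] += syn_w[s];
    }
    slot.clear();

    // 2. background input (aggregate Poisson per neuron)
    if (has_bg) {
      for (int i2 = 0; i2 < n_neur; ++i2) {
        double lam = bg_lambda[i2];
        if (lam <= 0) continue;
        int k = pois_small(lam, bg_explam[i2]);
        if (k > 0) {
          double amp = k * bg_w[i2] + std::sqrt((double)k) * bg_dw[i2] * R::norm_rand();
          if (bg_w[i2] > 0 && amp < 0) amp = 0;
          if (bg_w[i2] < 0 && amp > 0) amp = 0;
          I[bg_chan[i2]] += amp;
        }
      }
    }

    // 3. membrane update with exact propagators; channel decay
    for (int i2 = 0; i2 < n_neur; ++i2) {
      double dv = 0.0;
      for (int c = chan_offset[i2]; c < chan_offset[i2 + 1]; ++c)
        dv += I[c] * cvc[c];
      double v = V_rest + (V[i2] - V_rest) * dm + dv;
      if (has_const) v += i_const[i2] * Rm * (1.0 - dm);
      if (refr[i2] > 0) {
        --refr[i2];
        V[i2] = V_reset;
      } else {
        if (!R_finite(v))
          stop("non-finite membrane potential: neuron %d at t = %f ms",
               i2 + 1, t * dt);
        V[i2] = v;
      }
    }

    // 4. threshold crossing, reset, spike delivery (ascending neuron index)
    if (threshold_on) {
      for (int i2 = 0; i2 < n_neur; ++i2) {
        if (refr[i2] == 0 && V[i2] >= V_th) {
          sp_id.push_back(i2 + 1);
          sp_t.push_back((t + 1) * dt);
          V[i2] = V_reset;
          refr[i2] = ref_steps;
          // synapses sorted by delay within each neuron: push one range
          // per distinct delay
          int s = syn_offset[i2];
          const int send = syn_offset[i2 + 1];
          while (s < send) {
            int d = syn_delay[s];
            int s2 = s + 1;
            while (s2 < send && syn_delay[s2] == d) ++s2;
            Rng r; r.start = s; r.end = s2;
            ring[(t + d) % L].push_back(r);
            s = s2;
          }
        }
      }
    }

    // 5. Poisson sources (delivery delayed like any other spike)
    for (int s0 = 0; s0 < n_src; ++s0) {
      bool in_stim = (t >= src_on[s0] && t < src_off[s0]);
      double lam = in_stim ? src_lambda_stim[s0] : src_lambda_base[s0];
      if (lam <= 0) continue;
      int k = pois_small(lam, in_stim ? src_explam_stim[s0]
                                      : src_explam_base[s0]);
      if (k > 0) {
        int pre = n_neur + s0;
        int s = syn_offset[pre];
        const int send = syn_offset[pre + 1];
        while (s < send) {
          int d = syn_delay[s];
          int s2 = s + 1;
          while (s2 < send && syn_delay[s2] == d) ++s2;
          Rng r; r.start = s; r.end = s2;
          // k simultaneous source events: deliver the range k times
          for (int rep = 0; rep < k; ++rep) ring[(t + d) % L].push_back(r);
          s = s2;
        }
      }
    }

    // 6. probes (V after update, channel currents before end-of-step decay,
    // so a PSC probe peaks at exactly the synaptic weight on arrival)
    for (int pj = 0; pj < n_probe; ++pj) {
      int id = probe_ids[pj];
      probe_v(t, pj) = V[id];
      if (probe_current) {
        double tot = 0.0;
        for (int c = chan_offset[id]; c < chan_offset[id + 1]; ++c) tot += I[c];
        probe_i(t, pj) = tot;
      }
    }

    // 7. channel decay to the next step boundary
    for (int c = 0; c < n_chan; ++c) I[c] *= cdec[c];
  }

  return List::create(_["id"] = wrap(sp_id), _["time"] = wrap(sp_t),
                      _["probe_v"] = probe_v, _["probe_i"] = probe_i);
}
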