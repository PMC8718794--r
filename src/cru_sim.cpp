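// Stochastic 3D lattice of coupled Ca2+ release units (CRUs).
//
// Minimal "3R" model: each CRU carries cytosolic Ca (with an instantaneous
// fast buffer), explicitly time-resolved troponin-bound Ca, a network-SR
// and a junctional-SR compartment (the JSR with a rapid calsequestrin
// buffer).  Sparks ignite stochastically with a rate that grows as a power
// of local cytosolic Ca (recruitment), terminate on fractional JSR
// depletion, and are followed by a fixed refractory period.  Nearest
// neighbours are coupled diffusively (cytosol and network SR) with no-flux
// boundaries.
//
// Conserved-variable integration: the cytosolic and JSR pools advance in
// total-Ca variables (free + rapidly-buffered); free concentrations are
// recovered each step by inverting the rapid-buffer quadratic.  All
// internal fluxes are applied antisymmetrically, so with sarcolemmal
// fluxes disabled total cell Ca is conserved to floating-point rounding.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// counter-based per-CRU stream: independent of lattice size and step count
static inline double u01(uint64_t stream, uint64_t step) {
  return (sm64(stream ^ (step * 0xD1342543DE82EF95ULL)) >> 11) *
         (1.0 / 9007199254740992.0);
}

// free Ca from total (free + one rapid buffer): solves
//   c + B*c/(K+c) = u  =>  c^2 + (K + B - u) c - K u = 0
static inline double buf_invert(double u, double B, double K) {
  if (u <= 0.0) return 0.0;
  double b2 = K + B - u;
  return 0.5 * (-b2 + std::sqrt(b2 * b2 + 4.0 * K * u));
}

struct Params {
  int nx, ny, nz;
  double kon, koff, bt;
  double vmax, kserca, hserca;
  double gleak, grel, tau_tr;
  double dc, dn;
  double k0, gamma, c_ref, kstim, stim_dur, astim;
  double gncx, jbg;
  double term_frac, refrac_tau, recover_frac;
  double lum_ref, lum_exp, leak_boost, leak_ceiling, refrac_ca_half;
  double lambda_n, lambda_j;
  double bm, km, bc, kc;
  double v_rest, v_peak, apd_clamp;
  int voltage_mode; // 0 clamped, 1 coupled minimal AP
  double dt;
};

static Params unpack(const List& p) {
  Params q;
  q.nx = p["nx"]; q.ny = p["ny"]; q.nz = p["nz"];
  q.kon = p["kon"]; q.koff = p["koff"]; q.bt = p["bt"];
  q.vmax = p["vmax"]; q.kserca = p["kserca"]; q.hserca = p["hserca"];
  q.gleak = p["gleak"]; q.grel = p["grel"]; q.tau_tr = p["tau_tr"];
  q.dc = p["dc"]; q.dn = p["dn"];
  q.k0 = p["k0"]; q.gamma = p["gamma"]; q.c_ref = p["c_ref"];
  q.kstim = p["kstim"]; q.stim_dur = p["stim_dur"]; q.astim = p["astim"];
  q.gncx = p["gncx"]; q.jbg = p["jbg"];
  q.term_frac = p["term_frac"]; q.refrac_tau = p["refrac_tau"];
  q.recover_frac = p["recover_frac"];
  q.lum_ref = p["lum_ref"]; q.lum_exp = p["lum_exp"];
  q.leak_boost = p["leak_boost"]; q.leak_ceiling = p["leak_ceiling"];
  q.refrac_ca_half = p["refrac_ca_half"];
  q.lambda_n = p["lambda_n"]; q.lambda_j = p["lambda_j"];
  q.bm = p["bm"]; q.km = p["km"]; q.bc = p["bc"]; q.kc = p["kc"];
  q.v_rest = p["v_rest"]; q.v_peak = p["v_peak"]; q.apd_clamp = p["apd_clamp"];
  q.voltage_mode = p["voltage_mode"];
  q.dt = p["dt"];
  return q;
}

// [[Rcpp::export]]
List cru_run_cpp(List par, NumericVector stim_times, double t_end,
                 int seed, bool closed_cell, double record_dt,
                 List init_state, bool stochastic) {
  const Params q = unpack(par);
  const int N = q.nx * q.ny * q.nz;
  const double dt = q.dt;
  const long nt = (long)std::llround(t_end / dt);
  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt));

  NumericVector u = clone(as<NumericVector>(init_state["u"]));
  NumericVector b = clone(as<NumericVector>(init_state["b"]));
  NumericVector nsr = clone(as<NumericVector>(init_state["nsr"]));
  NumericVector w = clone(as<NumericVector>(init_state["w"]));
  IntegerVector active = clone(as<IntegerVector>(init_state["active"]));
  NumericVector refrac = clone(as<NumericVector>(init_state["refrac"]));
  NumericVector jstart = clone(as<NumericVector>(init_state["jstart"]));
  double vm = as<double>(init_state["v"]);
  double t0 = as<double>(init_state["time"]);
  if (u.size() != N) stop("state size does not match lattice");

  std::vector<double> c(N), j(N), du(N), dn_(N);
  double* pu = REAL(u); double* pb = REAL(b); double* pn = REAL(nsr);
  double* pw = REAL(w); int* pact = INTEGER(active);
  double* pref = REAL(refrac); double* pjs = REAL(jstart);
  const double kserca_h = std::pow(q.kserca, q.hserca);
  const bool hserca_sq = std::fabs(q.hserca - 2.0) < 1e-12;
  const int gamma_i = (std::fabs(q.gamma - std::round(q.gamma)) < 1e-12 &&
                       q.gamma >= 1.0 && q.gamma <= 8.0)
                          ? (int)std::lround(q.gamma) : 0;
  const int sxy = q.nx * q.ny;
  std::vector<uint64_t> stream(N);
  for (int i = 0; i < N; ++i)
    stream[i] = sm64((uint64_t)seed * 0x9E3779B97F4A7C15ULL ^ sm64((uint64_t)i + 1));

  const long nrec = nt / rec_every + 1;
  NumericVector rec_t(nrec), rec_c(nrec), rec_sr(nrec), rec_v(nrec),
      rec_tot(nrec), rec_nsr(nrec), rec_jsr(nrec);
  long ir = 0;

  const int nbeats = stim_times.size();
  NumericVector beat_peak(nbeats);
  std::fill(beat_peak.begin(), beat_peak.end(), R_NegInf);
  NumericVector beat_diast_sr(nbeats);
  std::fill(beat_diast_sr.begin(), beat_diast_sr.end(), R_PosInf);
  IntegerVector beat_fires(nbeats);   // spark ignitions per beat window

  int next_stim = 0;      // first stimulus not yet past
  int cur_beat = -1;      // index of the beat window containing t
  const double inv_cref = 1.0 / q.c_ref;
  const double lam_jn = q.lambda_j / q.lambda_n;
  const uint64_t step0 = (uint64_t)std::llround(t0 / dt);

  for (long step = 0; step <= nt; ++step) {
    const double t = t0 + step * dt;

    while (next_stim < nbeats && stim_times[next_stim] <= t + 1e-9) {
      cur_beat = next_stim;
      ++next_stim;
    }
    const bool stim_on = !closed_cell && cur_beat >= 0 &&
        (t - stim_times[cur_beat]) < q.stim_dur;

    // free concentrations
    double mean_c = 0.0, mean_n = 0.0, mean_j = 0.0, tot = 0.0;
    for (int i = 0; i < N; ++i) {
      c[i] = buf_invert(pu[i], q.bm, q.km);
      j[i] = buf_invert(pw[i], q.bc, q.kc);
      mean_c += c[i]; mean_n += pn[i]; mean_j += j[i];
      tot += pu[i] + pb[i] + q.lambda_n * pn[i] + q.lambda_j * pw[i];
    }
    mean_c /= N; mean_n /= N; mean_j /= N; tot /= N;
    const double mean_sr = (q.lambda_n * mean_n + q.lambda_j * mean_j) /
                           (q.lambda_n + q.lambda_j);

    if (cur_beat >= 0) {
      if (mean_c > beat_peak[cur_beat]) beat_peak[cur_beat] = mean_c;
      if (mean_sr < beat_diast_sr[cur_beat]) beat_diast_sr[cur_beat] = mean_sr;
    }

    // voltage
    if (q.voltage_mode == 0) {
      double ph = cur_beat >= 0 ? t - stim_times[cur_beat] : -1.0;
      if (ph >= 0.0 && ph < q.apd_clamp) {
        double s = ph < 2.0 ? ph / 2.0
                            : 0.5 * (1.0 + std::cos(M_PI * (ph - 2.0) / (q.apd_clamp - 2.0)));
        vm = q.v_rest + (q.v_peak - q.v_rest) * s;
      } else vm = q.v_rest;
    } else {
      // minimal coupled AP: voltage-gated repolarisation plus a
      // Ca-dependent inward (exchanger-like) current slowing decay
      double drive = stim_on ? 25.0 : 0.0;
      double tau_rep = vm > -40.0 ? q.apd_clamp / 3.0 : 10.0;
      double i_ca = 8.0 * (mean_c - 0.1);
      vm += dt * (drive * (q.v_peak - vm) - (vm - q.v_rest) / tau_rep +
                  (vm > -60.0 ? i_ca : 0.0));
    }

    if (step % rec_every == 0) {
      rec_t[ir] = t; rec_c[ir] = mean_c; rec_sr[ir] = mean_sr;
      rec_nsr[ir] = mean_n; rec_jsr[ir] = mean_j;
      rec_v[ir] = vm; rec_tot[ir] = tot;
      if (!R_finite(mean_c) || !R_finite(tot)) {
        stop("integration failure: non-finite cytosolic Ca at t = %f ms", t);
      }
      ++ir;
    }
    if (step == nt) break;

    // spark bookkeeping (uses pre-step c, j)
    const uint64_t gstep = step0 + (uint64_t)step;
    for (int i = 0; i < N; ++i) {
      if (pact[i]) {
        if (j[i] < q.term_frac * pjs[i]) {
          pact[i] = 0;
          pref[i] = q.refrac_tau;
        }
      } else if (pref[i] > 0.0) {
        // recovery from release refractoriness is slowed by local
        // cytosolic Ca (Ca-dependent RyR inactivation), so a prolonged
        // Ca transient tail lengthens the effective refractory period
        if (q.refrac_ca_half > 0.0) {
          const double cc = c[i] / q.refrac_ca_half;
          const double c2 = cc * cc;
          pref[i] -= dt / (1.0 + c2 * c2 * c2);
        } else {
          pref[i] -= dt;
        }
      } else if (stochastic && j[i] >= q.recover_frac * q.lum_ref) {
        // release refractoriness follows JSR refilling: a CRU is eligible
        // again only once its local JSR recovers past a luminal threshold
        // (fraction of the reference load), after the channel-level timer
        const double cr = c[i] * inv_cref;
        double crg;
        switch (gamma_i) {
          case 1: crg = cr; break;
          case 2: crg = cr * cr; break;
          case 3: crg = cr * cr * cr; break;
          case 4: { const double c2 = cr * cr; crg = c2 * c2; } break;
          case 5: { const double c2 = cr * cr; crg = c2 * c2 * cr; } break;
          case 6: { const double c2 = cr * cr; crg = c2 * c2 * c2; } break;
          case 7: { const double c2 = cr * cr; crg = c2 * c2 * c2 * cr; } break;
          case 8: { const double c2 = cr * cr; const double c4 = c2 * c2; crg = c4 * c4; } break;
          default: crg = std::pow(cr, q.gamma);
        }
        double rate = q.k0 * crg;
        if (stim_on) rate += q.kstim;
        if (q.lum_exp > 0.0) {
          // luminal RyR regulation: open probability falls steeply while
          // the local JSR is below its reference load
          double lr = j[i] / q.lum_ref;
          if (lr < 1.0) {
            double lf;
            if (q.lum_exp == 2.0) lf = lr * lr;
            else if (q.lum_exp == 4.0) { lf = lr * lr; lf *= lf; }
            else if (q.lum_exp == 8.0) { lf = lr * lr; lf *= lf; lf *= lf; }
            else lf = std::pow(lr, q.lum_exp);
            rate *= lf;
          }
        }
        if (rate > 0.0 && u01(stream[i], gstep) < rate * dt) {
          pact[i] = 1;
          pjs[i] = j[i];
          if (cur_beat >= 0) ++beat_fires[cur_beat];
        }
      }
    }

    // deterministic fluxes
    for (int i = 0; i < N; ++i) {
      const double ci = c[i];
      const double jtrpn = q.kon * (q.bt - pb[i]) * ci - q.koff * pb[i];
      const double ch = hserca_sq ? ci * ci : std::pow(ci, q.hserca);
      const double jup = q.vmax * ch / (ch + kserca_h);
      double gl = q.gleak;
      if (q.leak_boost > 0.0) {
        // store-overload leak: steeply increasing RyR leak near the
        // luminal ceiling caps the attainable SR load
        double nr = pn[i] / q.leak_ceiling;
        double n2 = nr * nr; double n6 = n2 * n2 * n2;
        gl *= 1.0 + q.leak_boost * n6;
      }
      const double jleak = gl * (pn[i] - ci);
      const double jrel = pact[i] ? q.grel * (j[i] - ci) : 0.0;
      const double jtr = (pn[i] - j[i]) / q.tau_tr;   // JSR-concentration units

      // nearest-neighbour diffusion, no-flux boundaries
      const int x = i % q.nx, y = (i / q.nx) % q.ny, z = i / sxy;
      double lc = 0.0, ln = 0.0;
      if (x > 0)        { lc += c[i - 1] - ci;    ln += pn[i - 1] - pn[i]; }
      if (x < q.nx - 1) { lc += c[i + 1] - ci;    ln += pn[i + 1] - pn[i]; }
      if (y > 0)        { lc += c[i - q.nx] - ci; ln += pn[i - q.nx] - pn[i]; }
      if (y < q.ny - 1) { lc += c[i + q.nx] - ci; ln += pn[i + q.nx] - pn[i]; }
      if (z > 0)        { lc += c[i - sxy] - ci;  ln += pn[i - sxy] - pn[i]; }
      if (z < q.nz - 1) { lc += c[i + sxy] - ci;  ln += pn[i + sxy] - pn[i]; }

      double sarco = 0.0;
      if (!closed_cell) {
        sarco = q.jbg - q.gncx * ci + (stim_on ? q.astim : 0.0);
      }
      du[i] = jrel + jleak - jup - jtrpn + sarco + q.dc * lc;
      pb[i] += dt * jtrpn;
      dn_[i] = (jup - jleak) / q.lambda_n - jtr * lam_jn + q.dn * ln;
      pw[i] += dt * (jtr - jrel / q.lambda_j);
    }
    for (int i = 0; i < N; ++i) {
      pu[i] += dt * du[i];
      pn[i] += dt * dn_[i];
      if (pu[i] < 0.0) pu[i] = 0.0;     // guarded; unreachable with stable dt
      if (pw[i] < 0.0) pw[i] = 0.0;
      if (pn[i] < 0.0) pn[i] = 0.0;
    }
  }

  List out_state = List::create(
      _["u"] = u, _["b"] = b, _["nsr"] = nsr, _["w"] = w,
      _["active"] = active, _["refrac"] = refrac, _["jstart"] = jstart,
      _["v"] = vm, _["time"] = t0 + nt * dt);

  return List::create(
      _["time"] = rec_t, _["ca"] = rec_c, _["ca_sr"] = rec_sr,
      _["ca_nsr"] = rec_nsr, _["ca_jsr"] = rec_jsr,
      _["v"] = rec_v, _["total_ca"] = rec_tot,
      _["beat_peak"] = beat_peak, _["beat_diast_sr"] = beat_diast_sr,
      _["beat_fires"] = beat_fires,
      _["state"] = out_state);
}
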