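// Implicit (backward-Euler) integrator for a population of unbranched
// multicompartment cables coupled by gap junctions.
//
// Scheme: staggered first-order update. Gating variables advance by the
// exact exponential solution for voltage frozen over the step; the voltage
// step is implicit in every linear term (leak, open-channel ohmic
// conductances, axial coupling and the self term of each gap junction),
// with the partner-side gap-junction voltage and the nonlinear GHK calcium
// flux taken from the previous step. Each neuron is an unbranched chain, so
// the implicit system is tridiagonal and solved by the Thomas algorithm;
// chains are concatenated with zero coupling between neurons.
//
// Units: mV, ms, uS, nF, nA. (uS * mV = nA; nF * mV / ms = nA.)
//
// Rate-function rows (A,B,C,D,E), fixed order:
//   0 ca alpha_m, 1 ca beta_m (V < split), 2 ca beta_m (V >= split),
//   3 kf alpha_n, 4 kf beta_n, 5 ks alpha_n, 6 ks beta_n,
//   7 na alpha_m, 8 na beta_m, 9 na alpha_h, 10 na beta_h
// Gates, fixed order: 0 m_na, 1 h_na, 2 n_kf, 3 n_ks, 4 m_ca.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double rate_eval(const double *p, double v) {
  double r = (p[0] + p[1] * v) / (p[2] + std::exp((p[3] + v) / p[4]));
  return r > 0.0 ? r : 0.0;
}

// Interleaved lookup table: for each voltage grid point, 11 contiguous
// doubles — xinf/decay pairs for the five gates (m_na, h_na, n_kf, n_ks,
// m_ca) followed by the GHK flux factor — so one index computation serves
// every per-compartment lookup and the row fits in a cache line pair.
#define TBL_STRIDE 11
struct GateTables {
  double vmin, dv, inv_dv;
  int n;
  std::vector<double> t; // n * TBL_STRIDE
};

static GateTables build_tables(const NumericMatrix &rp, double dt,
                               double ca_split, double Fc, double Rc,
                               double Tc, double ci, double co) {
  GateTables tb;
  tb.vmin = -120.0;
  tb.dv = 0.025;
  tb.inv_dv = 1.0 / tb.dv;
  tb.n = (int)std::floor((80.0 - tb.vmin) / tb.dv) + 1;
  tb.t.assign((size_t)tb.n * TBL_STRIDE, 0.0);
  double prm[11][5];
  for (int r = 0; r < 11; ++r)
    for (int c = 0; c < 5; ++c) prm[r][c] = rp(r, c);
  const int arow[5] = {7, 9, 3, 5, 0}; // alpha row per gate
  const int brow[5] = {8, 10, 4, 6, 1};
  for (int i = 0; i < tb.n; ++i) {
    double v = tb.vmin + i * tb.dv;
    double *row = &tb.t[(size_t)i * TBL_STRIDE];
    for (int g = 0; g < 5; ++g) {
      double a = rate_eval(prm[arow[g]], v);
      double b;
      if (g == 4) // calcium: piecewise closing rate
        b = (v < ca_split) ? rate_eval(prm[1], v) : rate_eval(prm[2], v);
      else
        b = rate_eval(prm[brow[g]], v);
      double s = a + b;
      row[2 * g] = (s > 0.0) ? a / s : 0.0;
      row[2 * g + 1] = std::exp(-dt * s);
    }
    // GHK flux factor at this voltage (concentrations in mol/L; the result,
    // multiplied by P [cm/s] and m^2, is read in uA/cm^2 — see vignette)
    double u = 2.0 * (v / 1000.0) * Fc / (Rc * Tc);
    double gflux;
    if (std::fabs(u) < 1e-5)
      gflux = (ci - co) * (1.0 + u / 2.0 + u * u / 12.0) + co * u;
    else
      gflux = u * (ci - co * std::exp(-u)) / (1.0 - std::exp(-u));
    row[10] = -2.0 * Fc * gflux;
  }
  return tb;
}

// interpolated row lookup: fills out[0..10] for voltage v
static inline void tbl_row(const GateTables &tb, double v, double *out) {
  double x = (v - tb.vmin) * tb.inv_dv;
  if (x < 0.0) x = 0.0;
  if (x > tb.n - 1.001) x = tb.n - 1.001;
  int i = (int)x;
  double f = x - i;
  const double *r0 = &tb.t[(size_t)i * TBL_STRIDE];
  const double *r1 = r0 + TBL_STRIDE;
  for (int k = 0; k < TBL_STRIDE; ++k)
    out[k] = r0[k] + (r1[k] - r0[k]) * f;
}

static inline double tbl_one(const GateTables &tb, double v, int k) {
  double row[TBL_STRIDE];
  tbl_row(tb, v, row);
  return row[k];
}

// [[Rcpp::export]]
List cpp_integrate(List sys, NumericMatrix rate_params_mat,
                   NumericVector ghk_consts, double ca_split,
                   List stim, List syn,
                   double dt, int nsteps, double v0,
                   IntegerVector probes, int record_every, bool active) {
  const int n = as<int>(sys["ncomp"]);
  NumericVector cap = sys["cap"], gax = sys["gax"];
  NumericVector glk = sys["glk"], gna = sys["gna"], gkf = sys["gkf"],
                gks = sys["gks"], pfca = sys["pfca"];
  IntegerVector gja = sys["gja"], gjb = sys["gjb"];
  NumericVector gjg = sys["gjg"];
  const double e_na = as<double>(sys["e_na"]);
  const double e_k = as<double>(sys["e_k"]);
  const double e_lk = as<double>(sys["e_lk"]);

  IntegerVector st_comp = stim["comp"];
  NumericVector st_amp = stim["amp"], st_on = stim["onset"],
                st_dur = stim["dur"];

  bool has_syn = syn.size() > 0;
  IntegerVector syn_comp;
  NumericMatrix syn_g; // rows: targets, cols: steps
  double e_syn = 0.0;
  if (has_syn) {
    syn_comp = as<IntegerVector>(syn["comp"]);
    syn_g = as<NumericMatrix>(syn["g"]);
    e_syn = as<double>(syn["e_rev"]);
  }

  GateTables tb = build_tables(rate_params_mat, dt, ca_split,
                               ghk_consts[0], ghk_consts[1], ghk_consts[2],
                               ghk_consts[3], ghk_consts[4]);

  std::vector<double> v(n, v0);
  std::vector<double> m_na(n), h_na(n), n_kf(n), n_ks(n), m_ca(n);
  if (active) {
    double row[TBL_STRIDE];
    tbl_row(tb, v0, row);
    for (int i = 0; i < n; ++i) {
      m_na[i] = row[0]; h_na[i] = row[2]; n_kf[i] = row[4];
      n_ks[i] = row[6]; m_ca[i] = row[8];
    }
  }

  std::vector<double> diag(n), rhs(n), cc(n), dd(n);
  std::vector<double> capdt(n);
  for (int i = 0; i < n; ++i) capdt[i] = cap[i] / dt;

  const int nrec = nsteps / record_every + 1;
  const int np = probes.size();
  NumericMatrix traces(nrec, np);
  NumericVector time(nrec);
  for (int p = 0; p < np; ++p) traces(0, p) = v[probes[p]];
  time[0] = 0.0;

  int rec = 1;
  bool blown = false;
  double blow_t = NA_REAL;

  const double *p_glk = glk.begin(), *p_gna = gna.begin(),
               *p_gkf = gkf.begin(), *p_gks = gks.begin(),
               *p_pf = pfca.begin(), *p_gax = gax.begin();

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;

    for (int i = 0; i < n; ++i) {
      diag[i] = capdt[i] + p_glk[i];
      rhs[i] = capdt[i] * v[i] + p_glk[i] * e_lk;
    }
    if (active) {
      double row[TBL_STRIDE];
      for (int i = 0; i < n; ++i) {
        double vi = v[i];
        // staggered exponential gate update at the pre-step voltage
        tbl_row(tb, vi, row);
        m_na[i] = row[0] + (m_na[i] - row[0]) * row[1];
        h_na[i] = row[2] + (h_na[i] - row[2]) * row[3];
        n_kf[i] = row[4] + (n_kf[i] - row[4]) * row[5];
        n_ks[i] = row[6] + (n_ks[i] - row[6]) * row[7];
        m_ca[i] = row[8] + (m_ca[i] - row[8]) * row[9];

        double m = m_na[i];
        double gna_open = p_gna[i] * m * m * m * h_na[i];
        double nk = n_kf[i];
        double gkf_open = p_gkf[i] * nk * nk * nk * nk;
        double ns = n_ks[i];
        double gks_open = p_gks[i] * ns * ns;
        diag[i] += gna_open + gkf_open + gks_open;
        rhs[i] += gna_open * e_na + (gkf_open + gks_open) * e_k;
        if (p_pf[i] > 0.0) {
          double mc = m_ca[i];
          rhs[i] += p_pf[i] * mc * mc * row[10]; // explicit GHK flux
        }
      }
    }
    // gap junctions: own side implicit, partner side explicit
    for (int j = 0; j < gja.size(); ++j) {
      int a = gja[j], b = gjb[j];
      double g = gjg[j];
      diag[a] += g; rhs[a] += g * v[b];
      diag[b] += g; rhs[b] += g * v[a];
    }
    // step currents
    for (int j = 0; j < st_comp.size(); ++j)
      if (t >= st_on[j] && t < st_on[j] + st_dur[j])
        rhs[st_comp[j]] += st_amp[j];
    // synaptic conductances (implicit in own voltage)
    if (has_syn)
      for (int j = 0; j < syn_comp.size(); ++j) {
        double g = syn_g(j, step);
        diag[syn_comp[j]] += g;
        rhs[syn_comp[j]] += g * e_syn;
      }
    // axial terms and Thomas solve (sub/super diagonal = -gax)
    for (int i = 0; i < n - 1; ++i) {
      diag[i] += gax[i];
      diag[i + 1] += gax[i];
    }
    // forward sweep
    cc[0] = -gax[0] / diag[0];
    dd[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      double sub = -gax[i - 1];
      double m = diag[i] - sub * cc[i - 1];
      cc[i] = (i < n - 1) ? -gax[i] / m : 0.0;
      dd[i] = (rhs[i] - sub * dd[i - 1]) / m;
    }
    v[n - 1] = dd[n - 1];
    for (int i = n - 2; i >= 0; --i) v[i] = dd[i] - cc[i] * v[i + 1];

    if ((step & 127) == 0 && !std::isfinite(v[0])) {
      blown = true; blow_t = t; break;
    }
    if ((step + 1) % record_every == 0 && rec < nrec) {
      for (int p = 0; p < np; ++p) traces(rec, p) = v[probes[p]];
      time[rec] = (step + 1) * dt;
      ++rec;
    }
  }
  if (!blown)
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(v[i])) { blown = true; blow_t = nsteps * dt; }

  return List::create(_["time"] = time, _["traces"] = traces,
                      _["v_final"] = NumericVector(v.begin(), v.end()),
                      _["diverged"] = blown, _["diverged_at"] = blow_t);
}
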