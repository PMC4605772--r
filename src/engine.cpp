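#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Slot order of the packed parameter vector shared with R (see pack_params()).
enum {
  P_W_ON_AIYL, P_W_ON_AIYR, P_W_OFF_AIYL, P_W_OFF_AIYR,
  P_W_AIYL_AIZL, P_W_AIYR_AIZR,
  P_W_AIZL_SMBDL, P_W_AIZL_SMBVL, P_W_AIZR_SMBDR, P_W_AIZR_SMBVR,
  P_W_SMBDL_SMBDL, P_W_SMBDR_SMBDR, P_W_SMBVL_SMBVL, P_W_SMBVR_SMBVR,
  P_G_AIY, P_G_AIZ,
  P_TH_AIYL, P_TH_AIYR, P_TH_AIZL, P_TH_AIZR,
  P_TH_SMBDL, P_TH_SMBDR, P_TH_SMBVL, P_TH_SMBVR,
  P_W_PG, P_W_NMJ, P_TAU, P_T, P_V, P_N, P_M, P_LEN
};

// Cell order used everywhere: AIYL AIYR AIZL AIZR SMBDL SMBDR SMBVL SMBVR
enum { AIYL, AIYR, AIZL, AIZR, SMBDL, SMBDR, SMBVL, SMBVR };

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// One explicit-Euler update of the eight membrane potentials.  `pg` is the
// ventral pattern-generator value sin(2*pi*t/T); dorsal cells get -pg.
static inline void euler_step(double *V, const double *p, double von,
                              double voff, double pg, double dt,
                              double g_aiy, double g_aiz) {
  double sig[8];
  for (int i = 0; i < 8; i++) sig[i] = sigmoid(V[i] + p[P_TH_AIYL + i]);
  double dV[8];
  dV[AIYL] = -V[AIYL] + p[P_W_ON_AIYL] * von + p[P_W_OFF_AIYL] * voff +
             g_aiy * (V[AIYR] - V[AIYL]);
  dV[AIYR] = -V[AIYR] + p[P_W_ON_AIYR] * von + p[P_W_OFF_AIYR] * voff +
             g_aiy * (V[AIYL] - V[AIYR]);
  dV[AIZL] = -V[AIZL] + p[P_W_AIYL_AIZL] * sig[AIYL] +
             g_aiz * (V[AIZR] - V[AIZL]);
  dV[AIZR] = -V[AIZR] + p[P_W_AIYR_AIZR] * sig[AIYR] +
             g_aiz * (V[AIZL] - V[AIZR]);
  dV[SMBDL] = -V[SMBDL] + p[P_W_AIZL_SMBDL] * sig[AIZL] +
              p[P_W_SMBDL_SMBDL] * sig[SMBDL] + p[P_W_PG] * (-pg);
  dV[SMBDR] = -V[SMBDR] + p[P_W_AIZR_SMBDR] * sig[AIZR] +
              p[P_W_SMBDR_SMBDR] * sig[SMBDR] + p[P_W_PG] * (-pg);
  dV[SMBVL] = -V[SMBVL] + p[P_W_AIZL_SMBVL] * sig[AIZL] +
              p[P_W_SMBVL_SMBVL] * sig[SMBVL] + p[P_W_PG] * (pg);
  dV[SMBVR] = -V[SMBVR] + p[P_W_AIZR_SMBVR] * sig[AIZR] +
              p[P_W_SMBVR_SMBVR] * sig[SMBVR] + p[P_W_PG] * (pg);
  double k = dt / p[P_TAU];
  for (int i = 0; i < 8; i++) V[i] += k * dV[i];
}

static inline double neck_phi(const double *V, const double *p) {
  return p[P_W_NMJ] *
         ((sigmoid(V[SMBDL] + p[P_TH_SMBDL]) + sigmoid(V[SMBDR] + p[P_TH_SMBDR])) -
          (sigmoid(V[SMBVL] + p[P_TH_SMBVL]) + sigmoid(V[SMBVR] + p[P_TH_SMBVR])));
}

// Open-loop integration of a trial ensemble.  All trials share one parameter
// set; the sensory drive (V_ON, V_OFF) is precomputed per trial and time step
// because the sensor stage is linear in the stimulus.  Records the synaptic
// output of every cell plus the neck angular velocity at each step, sampled
// before the state is advanced.
// [[Rcpp::export]]
List cpp_open_loop(NumericMatrix von, NumericMatrix voff, NumericVector pvec,
                   NumericVector v_init, double t0, double dt,
                   bool block_gap_aiy, bool block_gap_aiz, bool record_v) {
  int n = von.nrow(), nt = von.ncol();
  const double *p = REAL(pvec);
  double g_aiy = block_gap_aiy ? 0.0 : p[P_G_AIY];
  double g_aiz = block_gap_aiz ? 0.0 : p[P_G_AIZ];
  NumericVector sig_out(Dimension(n, nt, 8));
  NumericMatrix phi_out(n, nt);
  NumericVector v_out(record_v ? (R_xlen_t)n * nt * 8 : 0);
  NumericMatrix v_final(n, 8);
  R_xlen_t plane = (R_xlen_t)n * nt;

  for (int tr = 0; tr < n; tr++) {
    double V[8];
    for (int i = 0; i < 8; i++) V[i] = v_init[i];
    for (int k = 0; k < nt; k++) {
      double t = t0 + k * dt;
      double pg = std::sin(2.0 * M_PI * t / p[P_T]);
      for (int i = 0; i < 8; i++)
        sig_out[tr + (R_xlen_t)k * n + plane * i] =
            sigmoid(V[i] + p[P_TH_AIYL + i]);
      phi_out(tr, k) = neck_phi(V, p);
      if (record_v)
        for (int i = 0; i < 8; i++)
          v_out[tr + (R_xlen_t)k * n + plane * i] = V[i];
      euler_step(V, p, von(tr, k), voff(tr, k), pg, dt, g_aiy, g_aiz);
      for (int i = 0; i < 8; i++)
        if (!std::isfinite(V[i]))
          stop("non-finite membrane potential in cell %d at step %d", i + 1,
               k + 1);
    }
    for (int i = 0; i < 8; i++) v_final(tr, i) = V[i];
  }
  List out = List::create(_["sig"] = sig_out, _["phi"] = phi_out,
                          _["v_final"] = v_final);
  if (record_v) {
    v_out.attr("dim") = Dimension(n, nt, 8);
    out["v"] = v_out;
  }
  return out;
}

static inline double field_conc(int type, double x, double y, double px,
                                double py, double c_peak, double c_scale) {
  double d = std::sqrt((x - px) * (x - px) + (y - py) * (y - py));
  if (type == 1) {  // conical: linear decay to zero at c_scale
    double c = c_peak * (1.0 - d / c_scale);
    return c > 0.0 ? c : 0.0;
  }
  if (type == 2)  // gaussian
    return c_peak * std::exp(-d * d / (2.0 * c_scale * c_scale));
  return c_peak;  // flat
}

// Closed-loop embodied simulation, vectorised over worms so a whole GA
// population is evaluated in one call.  Each worm carries its own parameter
// row (per-worm N and M set its concentration-history window).  A worm that
// leaves the arena is frozen and flagged; its distance statistics cover only
// the steps it actually ran.
// [[Rcpp::export]]
List cpp_closed_loop(NumericMatrix P, int field_type, double peak_x,
                     double peak_y, double c_peak, double c_scale,
                     NumericVector x0, NumericVector y0, NumericVector mu0,
                     int n_steps, double dt, double arena_radius,
                     bool record_traj, bool record_dc) {
  int n = P.nrow();
  NumericVector mean_dist(n), init_dist(n);
  IntegerVector steps_used(n);
  LogicalVector truncated(n);
  NumericMatrix dc_out(record_dc ? n : 0, record_dc ? n_steps : 0);
  NumericMatrix tr_c, tr_d, tr_phi, tr_mu, tr_x, tr_y;
  NumericVector tr_v, tr_sig;
  if (record_traj) {
    tr_c = NumericMatrix(n, n_steps); tr_d = NumericMatrix(n, n_steps);
    tr_phi = NumericMatrix(n, n_steps); tr_mu = NumericMatrix(n, n_steps);
    tr_x = NumericMatrix(n, n_steps); tr_y = NumericMatrix(n, n_steps);
    tr_v = NumericVector(Dimension(n, n_steps, 8));
    tr_sig = NumericVector(Dimension(n, n_steps, 8));
  }
  R_xlen_t plane = (R_xlen_t)n * n_steps;

  for (int w = 0; w < n; w++) {
    std::vector<double> p(P_LEN);
    for (int j = 0; j < P_LEN; j++) p[j] = P(w, j);
    int N = (int)p[P_N], M = (int)p[P_M], L = N + M;
    double V[8] = {0, 0, 0, 0, 0, 0, 0, 0};
    double x = x0[w], y = y0[w], mu = mu0[w];
    double c0 = field_conc(field_type, x, y, peak_x, peak_y, c_peak, c_scale);
    std::vector<double> buf(L, c0);  // warm-up: history pre-filled, d = 0
    int head = 0;  // next write position; head-1 is newest
    double dist0 = std::sqrt((x - peak_x) * (x - peak_x) +
                             (y - peak_y) * (y - peak_y));
    init_dist[w] = dist0;
    double dist_sum = 0.0;
    int used = 0;
    double c_prev = c0;
    bool out_of_arena = false;

    double sumN = N * c0, sumM = M * c0;  // running window sums
    for (int k = 0; k < n_steps; k++) {
      double c = field_conc(field_type, x, y, peak_x, peak_y, c_peak, c_scale);
      // incremental update: c enters the N window, the sample N steps back
      // moves from the N window into the M window, the oldest one leaves
      double c_oldest = buf[head];                  // c_{t-(N+M)}
      double c_mid = buf[(head + M) % L];           // c_{t-N}
      buf[head] = c;
      head = (head + 1) % L;
      sumN += c - c_mid;
      sumM += c_mid - c_oldest;
      double d = sumN / N - sumM / M;
      double von = d > 0.0 ? d : 0.0;
      double voff = d > 0.0 ? 0.0 : -d;
      double t = k * dt;
      double pg = std::sin(2.0 * M_PI * t / p[P_T]);
      double phi = neck_phi(V, p.data());
      if (record_dc) dc_out(w, k) = (c - c_prev) / dt;
      if (record_traj) {
        tr_c(w, k) = c; tr_d(w, k) = d; tr_phi(w, k) = phi;
        tr_mu(w, k) = mu; tr_x(w, k) = x; tr_y(w, k) = y;
        for (int i = 0; i < 8; i++) {
          tr_v[w + (R_xlen_t)k * n + plane * i] = V[i];
          tr_sig[w + (R_xlen_t)k * n + plane * i] =
              sigmoid(V[i] + p[P_TH_AIYL + i]);
        }
      }
      double dist = std::sqrt((x - peak_x) * (x - peak_x) +
                              (y - peak_y) * (y - peak_y));
      dist_sum += dist;
      used++;
      c_prev = c;
      euler_step(V, p.data(), von, voff, pg, dt, p[P_G_AIY], p[P_G_AIZ]);
      x += p[P_V] * std::cos(mu) * dt;
      y += p[P_V] * std::sin(mu) * dt;
      mu += phi * dt;
      if (std::sqrt(x * x + y * y) > arena_radius) {
        out_of_arena = true;
        break;
      }
    }
    mean_dist[w] = dist_sum / used;
    steps_used[w] = used;
    truncated[w] = out_of_arena;
  }

  List out = List::create(_["mean_dist"] = mean_dist,
                          _["init_dist"] = init_dist,
                          _["steps_used"] = steps_used,
                          _["truncated"] = truncated);
  if (record_dc) out["dc"] = dc_out;
  if (record_traj) {
    out["c"] = tr_c; out["d"] = tr_d; out["phi"] = tr_phi; out["mu"] = tr_mu;
    out["x"] = tr_x; out["y"] = tr_y; out["v"] = tr_v; out["sig"] = tr_sig;
  }
  return out;
}
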