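// Core numerics: hepatocyte reaction network, adaptive RK45 integrator,
// in-vitro cell simulation, and the sinusoid transport/exchange macro step.
// Species and parameter orderings here are the single source of truth; the
// R side retrieves them through the exported helpers below.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

// ---- species ----------------------------------------------------------
enum {
  S_APAP = 0, S_APAP_B, S_NAPQI, S_NAPQI_P, S_APAPG, S_APAPS, S_APAPS_B,
  S_APAPGS, S_GSH, S_GSSG, S_H2O2, S_ROS,
  S_APAP_EXT, S_APAPG_EXT, S_APAPS_EXT, S_APAPGS_EXT, S_NAPQI_EXT
};
static const int N_SPECIES = 17;
static const int N_INTRA   = 12;

static const char *SPECIES_NAMES[N_SPECIES] = {
  "APAP_cyt", "APAP_B", "NAPQI", "NAPQI_P", "APAPG", "APAPS", "APAPS_B",
  "APAPGS", "GSH", "GSSG", "H2O2", "ROS",
  "APAP_ext", "APAPG_ext", "APAPS_ext", "APAPGS_ext", "NAPQI_ext"
};

// ---- reactions --------------------------------------------------------
enum {
  R_UPT_ACT = 0, R_UPT_PAS, R_UGT, R_SULT, R_CYP3A4, R_CYP2E1, R_CYPM,
  R_NQO1, R_GST, R_NAPQI_BIND, R_APAP_BIND, R_APAPS_BIND,
  R_MRP2_G, R_MRP2_S, R_MRP2_GS, R_MRP34_G, R_MRP34_S, R_MRP34_GS,
  R_NAPQI_DIFF, R_GSS, R_GGT, R_ROS_SYN, R_SOD, R_GPX, R_GSR, R_H2O2_CLR
};
static const int N_REACTIONS = 26;

static const char *REACTION_NAMES[N_REACTIONS] = {
  "uptake_active", "uptake_passive", "ugt", "sult", "cyp3a4", "cyp2e1",
  "cyp_minor", "nqo1", "gst", "napqi_binding", "apap_binding",
  "apaps_binding", "mrp2_apapg", "mrp2_apaps", "mrp2_apapgs",
  "mrp34_apapg", "mrp34_apaps", "mrp34_apapgs", "napqi_diffusion",
  "gss", "ggt", "ros_synthesis", "sod", "gpx", "gsr", "h2o2_clearance"
};

// 1 = carries material across the membrane, 0 = chemical transformation
static const int IS_TRANSPORT[N_REACTIONS] = {
  1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
  1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0
};

// Stoichiometric matrix, N[species][reaction]
static int STOICH[N_SPECIES][N_REACTIONS];
static bool stoich_ready = false;

static void build_stoich() {
  if (stoich_ready) return;
  std::memset(STOICH, 0, sizeof(STOICH));
  // uptake (active + passive): APAP_ext -> APAP_cyt
  STOICH[S_APAP_EXT][R_UPT_ACT] = -1; STOICH[S_APAP][R_UPT_ACT] = 1;
  STOICH[S_APAP_EXT][R_UPT_PAS] = -1; STOICH[S_APAP][R_UPT_PAS] = 1;
  // phase II conjugation
  STOICH[S_APAP][R_UGT] = -1;  STOICH[S_APAPG][R_UGT] = 1;
  STOICH[S_APAP][R_SULT] = -1; STOICH[S_APAPS][R_SULT] = 1;
  // CYP oxidation to NAPQI
  STOICH[S_APAP][R_CYP3A4] = -1; STOICH[S_NAPQI][R_CYP3A4] = 1;
  STOICH[S_APAP][R_CYP2E1] = -1; STOICH[S_NAPQI][R_CYP2E1] = 1;
  STOICH[S_APAP][R_CYPM]   = -1; STOICH[S_NAPQI][R_CYPM]   = 1;
  // NQO1 reduction back to APAP
  STOICH[S_NAPQI][R_NQO1] = -1; STOICH[S_APAP][R_NQO1] = 1;
  // GST conjugation: NAPQI + GSH -> APAPGS
  STOICH[S_NAPQI][R_GST] = -1; STOICH[S_GSH][R_GST] = -1;
  STOICH[S_APAPGS][R_GST] = 1;
  // non-specific binding (net mass-action, reversible)
  STOICH[S_NAPQI][R_NAPQI_BIND] = -1; STOICH[S_NAPQI_P][R_NAPQI_BIND] = 1;
  STOICH[S_APAP][R_APAP_BIND] = -1;   STOICH[S_APAP_B][R_APAP_BIND] = 1;
  STOICH[S_APAPS][R_APAPS_BIND] = -1; STOICH[S_APAPS_B][R_APAPS_BIND] = 1;
  // MRP2 apical export (leaves the modeled system via bile)
  STOICH[S_APAPG][R_MRP2_G] = -1;
  STOICH[S_APAPS][R_MRP2_S] = -1;
  STOICH[S_APAPGS][R_MRP2_GS] = -1;
  // MRP3/4 basolateral export to sinusoidal bulk
  STOICH[S_APAPG][R_MRP34_G] = -1;  STOICH[S_APAPG_EXT][R_MRP34_G] = 1;
  STOICH[S_APAPS][R_MRP34_S] = -1;  STOICH[S_APAPS_EXT][R_MRP34_S] = 1;
  STOICH[S_APAPGS][R_MRP34_GS] = -1; STOICH[S_APAPGS_EXT][R_MRP34_GS] = 1;
  // NAPQI passive diffusion
  STOICH[S_NAPQI_EXT][R_NAPQI_DIFF] = -1; STOICH[S_NAPQI][R_NAPQI_DIFF] = 1;
  // glutathione turnover
  STOICH[S_GSH][R_GSS] = 1;
  STOICH[S_GSH][R_GGT] = -1;
  // oxidative stress branch
  STOICH[S_ROS][R_ROS_SYN] = 1;                 // NAPQI_P acts catalytically
  STOICH[S_ROS][R_SOD] = -1; STOICH[S_H2O2][R_SOD] = 1;
  STOICH[S_H2O2][R_GPX] = -1; STOICH[S_GSH][R_GPX] = -2;
  STOICH[S_GSSG][R_GPX] = 1;
  STOICH[S_GSSG][R_GSR] = -1; STOICH[S_GSH][R_GSR] = 2;
  STOICH[S_H2O2][R_H2O2_CLR] = -1;
  stoich_ready = true;
}

// ---- parameters -------------------------------------------------------
enum {
  P_VMAX_CYP3A4 = 0, P_KM_CYP3A4, P_VMAX_CYP2E1, P_KM_CYP2E1,
  P_VMAX_CYPM, P_KM_CYPM, P_VMAX_UGT, P_KM_UGT, P_VMAX_SULT, P_KM_SULT,
  P_VMAX_GST, P_KM_GST_NAPQI, P_KM_GST_GSH, P_VMAX_NQO1, P_KM_NQO1,
  P_VMAX_GSS, P_VMAX_GGT, P_KM_GGT, P_VMAX_GPX, P_KM_GPX_H2O2,
  P_KM_GPX_GSH, P_VMAX_SOD, P_KM_SOD, P_VMAX_GSR, P_KM_GSR,
  P_VMAX_UPT, P_KM_UPT, P_P_APAP, P_P_NAPQI,
  P_KON_APAP, P_KOFF_APAP, P_KON_APAPS, P_KOFF_APAPS,
  P_KON_NAPQI, P_KOFF_NAPQI, P_K_ROS, P_K_H2O2,
  P_VMAX_MRP2, P_KM_MRP2, P_VMAX_MRP34, P_KM_MRP34
};
static const int N_PARAMS = 41;

static const char *PARAM_NAMES[N_PARAMS] = {
  "vmax_cyp3a4", "km_cyp3a4", "vmax_cyp2e1", "km_cyp2e1",
  "vmax_cyp_minor", "km_cyp_minor", "vmax_ugt", "km_ugt",
  "vmax_sult", "km_sult", "vmax_gst", "km_gst_napqi", "km_gst_gsh",
  "vmax_nqo1", "km_nqo1", "vmax_gss", "vmax_ggt", "km_ggt",
  "vmax_gpx", "km_gpx_h2o2", "km_gpx_gsh", "vmax_sod", "km_sod",
  "vmax_gsr", "km_gsr", "vmax_uptake", "km_uptake", "p_apap", "p_napqi",
  "kon_apap", "koff_apap", "kon_apaps", "koff_apaps",
  "kon_napqi", "koff_napqi", "k_ros", "k_h2o2_clear",
  "vmax_mrp2", "km_mrp2", "vmax_mrp34", "km_mrp34"
};

static inline double mm(double vmax, double km, double s) {
  if (s <= 0.0) return 0.0;
  return vmax * s / (km + s);
}

// Reaction rates; c in uM (intracellular per L_cell, extracellular per
// L_bulk), rates in umol/L_cell/min. zone multiplies CYP3A4 Vmax only.
static void reaction_rates_core(const double *c, const double *p,
                                double zone, double *v) {
  const double apap = c[S_APAP] > 0 ? c[S_APAP] : 0;
  const double napqi = c[S_NAPQI] > 0 ? c[S_NAPQI] : 0;
  const double gsh = c[S_GSH] > 0 ? c[S_GSH] : 0;
  const double h2o2 = c[S_H2O2] > 0 ? c[S_H2O2] : 0;

  v[R_UPT_ACT] = mm(p[P_VMAX_UPT], p[P_KM_UPT], c[S_APAP_EXT]);
  v[R_UPT_PAS] = p[P_P_APAP] * (c[S_APAP_EXT] - c[S_APAP]);
  v[R_UGT]  = mm(p[P_VMAX_UGT], p[P_KM_UGT], apap);
  v[R_SULT] = mm(p[P_VMAX_SULT], p[P_KM_SULT], apap);
  v[R_CYP3A4] = zone * mm(p[P_VMAX_CYP3A4], p[P_KM_CYP3A4], apap);
  v[R_CYP2E1] = mm(p[P_VMAX_CYP2E1], p[P_KM_CYP2E1], apap);
  v[R_CYPM]   = mm(p[P_VMAX_CYPM], p[P_KM_CYPM], apap);
  v[R_NQO1] = mm(p[P_VMAX_NQO1], p[P_KM_NQO1], napqi);
  v[R_GST] = p[P_VMAX_GST] * (napqi / (p[P_KM_GST_NAPQI] + napqi)) *
             (gsh / (p[P_KM_GST_GSH] + gsh));
  if (napqi <= 0 || gsh <= 0) v[R_GST] = 0.0;
  v[R_NAPQI_BIND] = p[P_KON_NAPQI] * c[S_NAPQI] -
                    p[P_KOFF_NAPQI] * c[S_NAPQI_P];
  v[R_APAP_BIND] = p[P_KON_APAP] * c[S_APAP] - p[P_KOFF_APAP] * c[S_APAP_B];
  v[R_APAPS_BIND] = p[P_KON_APAPS] * c[S_APAPS] -
                    p[P_KOFF_APAPS] * c[S_APAPS_B];
  v[R_MRP2_G]  = mm(p[P_VMAX_MRP2], p[P_KM_MRP2], c[S_APAPG]);
  v[R_MRP2_S]  = mm(p[P_VMAX_MRP2], p[P_KM_MRP2], c[S_APAPS]);
  v[R_MRP2_GS] = mm(p[P_VMAX_MRP2], p[P_KM_MRP2], c[S_APAPGS]);
  v[R_MRP34_G]  = mm(p[P_VMAX_MRP34], p[P_KM_MRP34], c[S_APAPG]);
  v[R_MRP34_S]  = mm(p[P_VMAX_MRP34], p[P_KM_MRP34], c[S_APAPS]);
  v[R_MRP34_GS] = mm(p[P_VMAX_MRP34], p[P_KM_MRP34], c[S_APAPGS]);
  v[R_NAPQI_DIFF] = p[P_P_NAPQI] * (c[S_NAPQI_EXT] - c[S_NAPQI]);
  v[R_GSS] = p[P_VMAX_GSS];
  v[R_GGT] = mm(p[P_VMAX_GGT], p[P_KM_GGT], gsh);
  v[R_ROS_SYN] = p[P_K_ROS] * (c[S_NAPQI_P] > 0 ? c[S_NAPQI_P] : 0);
  v[R_SOD] = mm(p[P_VMAX_SOD], p[P_KM_SOD], c[S_ROS]);
  v[R_GPX] = p[P_VMAX_GPX] * (h2o2 / (p[P_KM_GPX_H2O2] + h2o2)) *
             (gsh / (p[P_KM_GPX_GSH] + gsh));
  if (h2o2 <= 0 || gsh <= 0) v[R_GPX] = 0.0;
  v[R_GSR] = mm(p[P_VMAX_GSR], p[P_KM_GSR], c[S_GSSG]);
  v[R_H2O2_CLR] = p[P_K_H2O2] * (c[S_H2O2] > 0 ? c[S_H2O2] : 0);
}

// ---- adaptive Cash-Karp RK45 ------------------------------------------
typedef void (*rhs_fn)(double t, const double *y, double *dy, void *ctx);

static const double CK_A[6] = {0.0, 0.2, 0.3, 0.6, 1.0, 0.875};
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {0.2, 0, 0, 0, 0},
  {3.0/40, 9.0/40, 0, 0, 0},
  {0.3, -0.9, 1.2, 0, 0},
  {-11.0/54, 2.5, -70.0/27, 35.0/27, 0},
  {1631.0/55296, 175.0/512, 575.0/13824, 44275.0/110592, 253.0/4096}
};
static const double CK_C[6] = {37.0/378, 0, 250.0/621, 125.0/594, 0,
                               512.0/1771};
static const double CK_DC[6] = {
  37.0/378 - 2825.0/27648, 0.0, 250.0/621 - 18575.0/48384,
  125.0/594 - 13525.0/55296, -277.0/14336, 512.0/1771 - 0.25
};

struct RKResult { bool ok; double h_next; };

// Integrate y over [t0, t1]; track the running maximum of y[track_idx]
// (if track_idx >= 0) in *track_max.
static bool integrate_rkck(double *y, int n, double t0, double t1,
                           rhs_fn f, void *ctx, double rtol, double atol,
                           double h0, int track_idx, double *track_max) {
  std::vector<double> k(6 * n), ytmp(n), yerr(n), y5(n);
  double t = t0;
  double h = (h0 > 0 ? h0 : (t1 - t0));
  const double hmax = t1 - t0;
  if (h > hmax) h = hmax;
  int n_reject = 0, n_step = 0;
  while (t < t1 - 1e-12 * (t1 - t0 + 1.0)) {
    if (t + h > t1) h = t1 - t;
    // stages
    f(t, y, &k[0], ctx);
    for (int s = 1; s < 6; ++s) {
      for (int i = 0; i < n; ++i) {
        double acc = y[i];
        for (int j = 0; j < s; ++j) acc += h * CK_B[s][j] * k[j * n + i];
        ytmp[i] = acc;
      }
      f(t + CK_A[s] * h, &ytmp[0], &k[s * n], ctx);
    }
    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double dy = 0.0, de = 0.0;
      for (int s = 0; s < 6; ++s) {
        dy += CK_C[s] * k[s * n + i];
        de += CK_DC[s] * k[s * n + i];
      }
      y5[i] = y[i] + h * dy;
      yerr[i] = h * de;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = std::fabs(yerr[i]) / sc;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0) {
      t += h;
      std::memcpy(y, &y5[0], n * sizeof(double));
      if (track_idx >= 0 && y[track_idx] > *track_max)
        *track_max = y[track_idx];
      double fac = 0.9 * std::pow(errmax > 1e-12 ? errmax : 1e-12, -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
      if (h > hmax) h = hmax;
      n_reject = 0;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (++n_reject > 60) return false;
    }
    if (++n_step > 2000000) return false;
    if (h < 1e-12) return false;
  }
  return true;
}

// ---- RHS variants ------------------------------------------------------
struct CellCtx {
  const double *p;
  double zone;
  double ext_scale;      // V_cell / V_medium applied to extracellular rows
  bool clamp_apap_ext;   // exposure clamps the APAP reservoir
};

static void rhs_cell(double t, const double *y, double *dy, void *vctx) {
  (void)t;
  CellCtx *ctx = (CellCtx *)vctx;
  double v[N_REACTIONS];
  reaction_rates_core(y, ctx->p, ctx->zone, v);
  for (int i = 0; i < N_SPECIES; ++i) {
    double acc = 0.0;
    for (int r = 0; r < N_REACTIONS; ++r)
      if (STOICH[i][r]) acc += STOICH[i][r] * v[r];
    dy[i] = (i < N_INTRA) ? acc : acc * ctx->ext_scale;
  }
  if (ctx->clamp_apap_ext) dy[S_APAP_EXT] = 0.0;
}

// Sinusoid-mode cell: 12 intracellular states plus 3 quadrature states
// accumulating MRP3/4 export (umol/L_cell) of APAPG/APAPS/APAPGS.
// Membrane transport of APAP and NAPQI is handled on the bulk side and
// enters as constant source terms (umol/L_cell/min).
struct SinusCellCtx {
  const double *p;
  double zone;
  double src_apap, src_napqi;
};

static void rhs_sinus_cell(double t, const double *y, double *dy,
                           void *vctx) {
  (void)t;
  SinusCellCtx *ctx = (SinusCellCtx *)vctx;
  double c[N_SPECIES];
  for (int i = 0; i < N_INTRA; ++i) c[i] = y[i];
  for (int i = N_INTRA; i < N_SPECIES; ++i) c[i] = 0.0;
  double v[N_REACTIONS];
  reaction_rates_core(c, ctx->p, ctx->zone, v);
  // membrane exchange handled outside
  v[R_UPT_ACT] = 0.0;
  v[R_UPT_PAS] = 0.0;
  v[R_NAPQI_DIFF] = 0.0;
  for (int i = 0; i < N_INTRA; ++i) {
    double acc = 0.0;
    for (int r = 0; r < N_REACTIONS; ++r)
      if (STOICH[i][r]) acc += STOICH[i][r] * v[r];
    dy[i] = acc;
  }
  dy[S_APAP] += ctx->src_apap;
  dy[S_NAPQI] += ctx->src_napqi;
  dy[N_INTRA + 0] = v[R_MRP34_G];
  dy[N_INTRA + 1] = v[R_MRP34_S];
  dy[N_INTRA + 2] = v[R_MRP34_GS];
}

// ---- exported helpers --------------------------------------------------

// [[Rcpp::export(name = ".hepasim_species")]]
CharacterVector hepasim_species() {
  CharacterVector out(N_SPECIES);
  for (int i = 0; i < N_SPECIES; ++i) out[i] = SPECIES_NAMES[i];
  return out;
}

// [[Rcpp::export(name = ".hepasim_reactions")]]
CharacterVector hepasim_reactions() {
  CharacterVector out(N_REACTIONS);
  for (int i = 0; i < N_REACTIONS; ++i) out[i] = REACTION_NAMES[i];
  return out;
}

// [[Rcpp::export(name = ".hepasim_param_names")]]
CharacterVector hepasim_param_names() {
  CharacterVector out(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i) out[i] = PARAM_NAMES[i];
  return out;
}

// [[Rcpp::export(name = ".hepasim_stoich")]]
IntegerMatrix hepasim_stoich() {
  build_stoich();
  IntegerMatrix N(N_SPECIES, N_REACTIONS);
  for (int i = 0; i < N_SPECIES; ++i)
    for (int r = 0; r < N_REACTIONS; ++r) N(i, r) = STOICH[i][r];
  rownames(N) = hepasim_species();
  colnames(N) = hepasim_reactions();
  return N;
}

// [[Rcpp::export(name = ".hepasim_transport_flags")]]
LogicalVector hepasim_transport_flags() {
  LogicalVector out(N_REACTIONS);
  for (int r = 0; r < N_REACTIONS; ++r) out[r] = IS_TRANSPORT[r] == 1;
  out.names() = hepasim_reactions();
  return out;
}

// [[Rcpp::export(name = ".reaction_rates_cpp")]]
NumericVector reaction_rates_cpp(NumericVector conc, NumericVector params,
                                 double zone_factor) {
  build_stoich();
  if (conc.size() != N_SPECIES) stop("expected %d species", N_SPECIES);
  if (params.size() != N_PARAMS) stop("expected %d parameters", N_PARAMS);
  NumericVector v(N_REACTIONS);
  reaction_rates_core(&conc[0], &params[0], zone_factor, &v[0]);
  v.names() = hepasim_reactions();
  return v;
}

// [[Rcpp::export(name = ".cell_rhs_cpp")]]
NumericVector cell_rhs_cpp(NumericVector conc, NumericVector params,
                           double zone_factor, bool alive,
                           double ext_scale, bool clamp_apap_ext) {
  build_stoich();
  if (conc.size() != N_SPECIES) stop("expected %d species", N_SPECIES);
  NumericVector dy(N_SPECIES);
  if (!alive) { dy.names() = hepasim_species(); return dy; }
  CellCtx ctx = {&params[0], zone_factor, ext_scale, clamp_apap_ext};
  rhs_cell(0.0, &conc[0], &dy[0], &ctx);
  dy.names() = hepasim_species();
  return dy;
}

// Simulate one hepatocyte under a piecewise-constant extracellular APAP
// exposure schedule. Returns the trajectory at fixed output times plus the
// running peak of intracellular H2O2 (tracked inside the integrator).
// [[Rcpp::export(name = ".simulate_cell_cpp")]]
List simulate_cell_cpp(NumericVector c0, NumericVector params,
                       double zone_factor, NumericVector exposure_times,
                       NumericVector exposure_values, double duration,
                       double out_dt, double ext_scale, double rtol,
                       double atol) {
  build_stoich();
  if (c0.size() != N_SPECIES) stop("expected %d species", N_SPECIES);
  if (exposure_times.size() != exposure_values.size())
    stop("exposure schedule lengths differ");
  int n_out = (int)std::floor(duration / out_dt + 1e-9) + 1;
  NumericMatrix traj(n_out, N_SPECIES);
  NumericVector times(n_out);
  std::vector<double> y(N_SPECIES);
  for (int i = 0; i < N_SPECIES; ++i) { y[i] = c0[i]; traj(0, i) = c0[i]; }
  double peak_h2o2 = y[S_H2O2];
  CellCtx ctx = {&params[0], zone_factor, ext_scale, true};
  int k_exp = 0;
  double t = 0.0;
  for (int k = 1; k < n_out; ++k) {
    double t1 = k * out_dt;
    // active exposure level: last schedule point with time <= t
    while (k_exp + 1 < exposure_times.size() &&
           exposure_times[k_exp + 1] <= t + 1e-12) ++k_exp;
    y[S_APAP_EXT] = exposure_values[k_exp];
    bool ok = integrate_rkck(&y[0], N_SPECIES, t, t1, rhs_cell, &ctx, rtol,
                             atol, 0.0, S_H2O2, &peak_h2o2);
    if (!ok)
      stop("cell integration failed near t = %.2f min", t);
    t = t1;
    times[k] = t1;
    for (int i = 0; i < N_SPECIES; ++i) traj(k, i) = y[i];
  }
  colnames(traj) = hepasim_species();
  return List::create(_["time"] = times, _["states"] = traj,
                      _["peak_h2o2"] = peak_h2o2);
}

// ---- sinusoid macro step ----------------------------------------------
// Bulk species order along the sinusoid: APAP, APAPG, APAPS, APAPGS, NAPQI.
// One macro step = n_sub transport sub-steps (advect one section per
// sub-step, inject inlet, apply the diffusion kernel, exchange APAP/NAPQI
// with the resident cells), followed by one stiff-path integration of each
// section's shared live-cell state with the exchanged amounts as sources.
// [[Rcpp::export(name = ".sinusoid_step_cpp")]]
List sinusoid_step_cpp(NumericMatrix bulk, NumericMatrix cells,
                       IntegerVector n_alive, NumericVector zone,
                       NumericVector params, NumericMatrix kdiff,
                       NumericVector inlet_conc, int n_sub, double dt_sub,
                       double vol_ratio, double v_bulk, double v_cell,
                       double rtol, double atol) {
  build_stoich();
  const int NB = 5;
  const int ns = bulk.ncol();
  if (bulk.nrow() != NB) stop("bulk must have 5 rows");
  if (cells.nrow() != N_INTRA || cells.ncol() != ns)
    stop("cells must be 12 x n_sections");
  if (kdiff.nrow() != ns || kdiff.ncol() != ns)
    stop("kernel dimension mismatch");
  const double dt_macro = n_sub * dt_sub;
  const double *p = &params[0];

  NumericMatrix b = clone(bulk);
  NumericMatrix cc = clone(cells);
  NumericVector outlet(NB), inlet_amt(NB), transferred(NB), exported(NB);
  std::vector<double> t_apap(ns, 0.0), t_napqi(ns, 0.0);
  std::vector<double> amt(ns), tmp(ns);

  for (int sub = 0; sub < n_sub; ++sub) {
    for (int sp = 0; sp < NB; ++sp) {
      for (int s = 0; s < ns; ++s) amt[s] = b(sp, s) * v_bulk;
      // advection: exact one-section shift; last section exits
      outlet[sp] += amt[ns - 1];
      for (int s = ns - 1; s > 0; --s) amt[s] = amt[s - 1];
      // inlet: one section volume of fresh inflow at portal concentration
      amt[0] = inlet_conc[sp] * v_bulk;
      inlet_amt[sp] += inlet_conc[sp] * v_bulk;
      // dispersion kernel
      for (int i = 0; i < ns; ++i) {
        double acc = 0.0;
        for (int j = 0; j < ns; ++j) acc += kdiff(i, j) * amt[j];
        tmp[i] = acc;
      }
      for (int s = 0; s < ns; ++s) b(sp, s) = tmp[s] / v_bulk;
    }
    // bulk <-> cell exchange (APAP passive + carrier, NAPQI passive)
    for (int s = 0; s < ns; ++s) {
      if (n_alive[s] <= 0) continue;
      const double cell_vol = v_cell * n_alive[s];
      // APAP
      double cb = b(0, s);
      const double ccyt = cc(S_APAP, s);
      const double kap = p[P_P_APAP] * vol_ratio * n_alive[s];
      double moved = 0.0;
      if (kap > 0) {
        double cb_new = ccyt + (cb - ccyt) * std::exp(-kap * dt_sub);
        moved += (cb - cb_new) * v_bulk;
        cb = cb_new;
      }
      double act = mm(p[P_VMAX_UPT], p[P_KM_UPT], cb) * cell_vol * dt_sub;
      if (act > cb * v_bulk) act = cb * v_bulk;
      cb -= act / v_bulk;
      moved += act;
      b(0, s) = cb;
      t_apap[s] += moved;
      // NAPQI
      double nb = b(4, s);
      const double ncyt = cc(S_NAPQI, s);
      const double kan = p[P_P_NAPQI] * vol_ratio * n_alive[s];
      if (kan > 0) {
        double nb_new = ncyt + (nb - ncyt) * std::exp(-kan * dt_sub);
        t_napqi[s] += (nb - nb_new) * v_bulk;
        b(4, s) = nb_new;
      }
    }
  }
  transferred[0] = 0.0;
  for (int s = 0; s < ns; ++s) transferred[0] += t_apap[s];
  for (int s = 0; s < ns; ++s) transferred[4] += t_napqi[s];

  // integrate each section's shared live-cell state over the macro step
  for (int s = 0; s < ns; ++s) {
    if (n_alive[s] <= 0) continue;
    const double cell_vol = v_cell * n_alive[s];
    SinusCellCtx ctx;
    ctx.p = p;
    ctx.zone = zone[s];
    ctx.src_apap = t_apap[s] / cell_vol / dt_macro;
    ctx.src_napqi = t_napqi[s] / cell_vol / dt_macro;
    double y[N_INTRA + 3];
    for (int i = 0; i < N_INTRA; ++i) y[i] = cc(i, s);
    y[N_INTRA] = y[N_INTRA + 1] = y[N_INTRA + 2] = 0.0;
    double dummy = 0.0;
    bool ok = integrate_rkck(y, N_INTRA + 3, 0.0, dt_macro, rhs_sinus_cell,
                             &ctx, rtol, atol, 0.0, -1, &dummy);
    if (!ok) stop("section %d cell integration failed", s + 1);
    for (int i = 0; i < N_INTRA; ++i) cc(i, s) = y[i];
    // deliver basolateral conjugate export into this section's bulk
    for (int q = 0; q < 3; ++q) {
      double amt_exp = y[N_INTRA + q] * cell_vol;  // umol
      b(1 + q, s) += amt_exp / v_bulk;
      exported[1 + q] += amt_exp;
    }
  }

  double e_apap = 0.0;
  for (int s = 0; s < ns; ++s) e_apap += t_apap[s];

  return List::create(
      _["bulk"] = b, _["cells"] = cc, _["outlet"] = outlet,
      _["inlet_amount"] = inlet_amt, _["transferred"] = transferred,
      _["exported"] = exported, _["e_apap"] = e_apap);
}
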