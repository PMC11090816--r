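#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Transport-resistance plant growth kernel.
//
// State per cell (6 pools): shoot/root structural mass (Ms, Mr), carbon
// substrate (Cs, Cr), nitrogen substrate (Ns, Nr). Monthly explicit update:
//   C uptake  Uc = amax * trap(W; c_moist) * nsat(Ns/Ms) * Ms / (1 + B/kB)
//   N uptake  Un = sigmaN * trap(T; n_temp) * trap(W; n_moist) * Mr / (1 + B/kB)
//   transport Tc = (Cs/Ms - Cr/Mr)/rC (shoot->root),
//             Tn = (Nr/Mr - Ns/Ms)/rN (root->shoot), flux-limited by pools
//   growth    Gx = kg * trap(T; g_temp) * (Cx/Mx) * (Nx/Mx) * Mx,
//             limited so substrate consumption (fC*G, fN*G) never overdraws
//   litter    first-order loss of structural mass at rates lossS, lossR.
// The (1 + B/kB)^-1 term is self-shading/root-competition density dependence;
// without it the dynamics are scale-invariant and have no interior fixed
// point. Carbon bookkeeping is exact:
//   d(Cs + Cr + fC*(Ms+Mr)) = Uc - fC*(lossS*Ms + lossR*Mr).

struct TTRConstants {
  double sigmaN, kg, rC, rN, fC, fN, lossS, lossR, kB;
  double init_mass, init_sub, mass_min, b_floor;
};

static TTRConstants read_constants(const List& konst) {
  TTRConstants c;
  c.sigmaN = konst["sigma_n"];
  c.kg = konst["k_g"];
  c.rC = konst["r_c"];
  c.rN = konst["r_n"];
  c.fC = konst["f_c"];
  c.fN = konst["f_n"];
  c.lossS = konst["loss_shoot"];
  c.lossR = konst["loss_root"];
  c.kB = konst["k_b"];
  c.init_mass = konst["init_mass"];
  c.init_sub = konst["init_substrate"];
  c.mass_min = konst["mass_min"];
  c.b_floor = konst["b_floor"];
  return c;
}

static inline double trap(double x, double p1, double p2, double p3, double p4) {
  if (x <= p1 || x >= p4) {
    // degenerate plateaus touching the support edge behave as steps
    if (x == p1 && p1 == p2) return (p3 > p1 || x == p3) ? 1.0 : 0.0;
    if (x == p4 && p4 == p3) return 1.0;
    return 0.0;
  }
  if (x < p2) return (x - p1) / (p2 - p1);
  if (x <= p3) return 1.0;
  return (p4 - x) / (p4 - p3);
}

// saturating shoot-nitrogen dependence of carbon uptake with a floor
static inline double nsat(double nconc, double khalf, double floor_) {
  return floor_ + (1.0 - floor_) * nconc / (nconc + khalf);
}

struct TTRState {
  double Ms, Mr, Cs, Cr, Ns, Nr;
};

// One monthly step with explicit species parameters. par is length 18:
// [0..3] n_temp, [4..7] n_moist, [8..11] c_moist, [12] c_n_half,
// [13] c_n_floor, [14..17] g_temp.
static inline void step_full(TTRState& s, double T, double W, double amax,
                             const double* par, const TTRConstants& c,
                             double* uc_out, double* lit_out) {
  double Ms = std::max(s.Ms, c.mass_min);
  double Mr = std::max(s.Mr, c.mass_min);
  double B = s.Ms + s.Mr;
  double dens = 1.0 / (1.0 + B / c.kB);
  double cs = s.Cs / Ms, cr = s.Cr / Mr;
  double ns = s.Ns / Ms, nr = s.Nr / Mr;

  double modC = trap(W, par[8], par[9], par[10], par[11]);
  double modN = trap(T, par[0], par[1], par[2], par[3]) *
                trap(W, par[4], par[5], par[6], par[7]);
  double modG = trap(T, par[14], par[15], par[16], par[17]);

  double Uc = amax * modC * nsat(ns, par[12], par[13]) * Ms * dens;
  double Un = c.sigmaN * modN * Mr * dens;

  // transport: substrate flows down its concentration gradient through a
  // resistance; fluxes clamped so pools cannot go negative this month
  double Tc = (cs - cr) / c.rC * std::min(Ms, Mr);
  double Tn = (nr - ns) / c.rN * std::min(Ms, Mr);
  double csAvail = s.Cs + Uc;
  if (Tc > csAvail) Tc = csAvail;
  if (-Tc > s.Cr) Tc = -s.Cr;
  double nrAvail = s.Nr + Un;
  if (Tn > nrAvail) Tn = nrAvail;
  if (-Tn > s.Ns) Tn = -s.Ns;

  // growth, limited by available substrate after uptake and transport
  double csA = s.Cs + Uc - Tc;
  double crA = s.Cr + Tc;
  double nsA = s.Ns + Tn;
  double nrA = s.Nr + Un - Tn;
  double Gs = c.kg * modG * cs * ns * Ms;
  double Gr = c.kg * modG * cr * nr * Mr;
  if (c.fC * Gs > csA) Gs = csA / c.fC;
  if (c.fN * Gs > nsA) Gs = nsA / c.fN;
  if (c.fC * Gr > crA) Gr = crA / c.fC;
  if (c.fN * Gr > nrA) Gr = nrA / c.fN;
  if (Gs < 0) Gs = 0;
  if (Gr < 0) Gr = 0;

  double litS = c.lossS * s.Ms;
  double litR = c.lossR * s.Mr;

  s.Cs = csA - c.fC * Gs;
  s.Cr = crA - c.fC * Gr;
  s.Ns = nsA - c.fN * Gs;
  s.Nr = nrA - c.fN * Gr;
  s.Ms = s.Ms + Gs - litS;
  s.Mr = s.Mr + Gr - litR;

  if (s.Cs < 0) s.Cs = 0;
  if (s.Cr < 0) s.Cr = 0;
  if (s.Ns < 0) s.Ns = 0;
  if (s.Nr < 0) s.Nr = 0;
  if (s.Ms < 0) s.Ms = 0;
  if (s.Mr < 0) s.Mr = 0;

  if (uc_out) *uc_out = Uc;
  if (lit_out) *lit_out = c.fC * (litS + litR);
}

// [[Rcpp::export]]
NumericVector ttr_step_cpp(NumericVector state, double tmean, double moisture,
                           double amax, NumericVector par, List konst) {
  TTRConstants c = read_constants(konst);
  TTRState s = {state[0], state[1], state[2], state[3], state[4], state[5]};
  double uc = 0, lit = 0;
  step_full(s, tmean, moisture, amax, REAL(par), c, &uc, &lit);
  NumericVector out = NumericVector::create(
    _["shoot_mass"] = s.Ms, _["root_mass"] = s.Mr,
    _["shoot_c"] = s.Cs, _["root_c"] = s.Cr,
    _["shoot_n"] = s.Ns, _["root_n"] = s.Nr);
  out.attr("c_uptake") = uc;
  out.attr("c_litter") = lit;
  return out;
}

// monthly step with precomputed environmental modifiers (state-independent
// parts of the update); nitrogen saturation stays state-dependent
static inline void step_pre(TTRState& s, double ucMax, double unMax,
                            double modG, double khalf, double floor_,
                            const TTRConstants& c) {
  double Ms = std::max(s.Ms, c.mass_min);
  double Mr = std::max(s.Mr, c.mass_min);
  double B = s.Ms + s.Mr;
  double dens = 1.0 / (1.0 + B / c.kB);
  double cs = s.Cs / Ms, cr = s.Cr / Mr;
  double ns = s.Ns / Ms, nr = s.Nr / Mr;

  double Uc = ucMax * nsat(ns, khalf, floor_) * Ms * dens;
  double Un = unMax * Mr * dens;

  double Tc = (cs - cr) / c.rC * std::min(Ms, Mr);
  double Tn = (nr - ns) / c.rN * std::min(Ms, Mr);
  double csAvail = s.Cs + Uc;
  if (Tc > csAvail) Tc = csAvail;
  if (-Tc > s.Cr) Tc = -s.Cr;
  double nrAvail = s.Nr + Un;
  if (Tn > nrAvail) Tn = nrAvail;
  if (-Tn > s.Ns) Tn = -s.Ns;

  double csA = s.Cs + Uc - Tc;
  double crA = s.Cr + Tc;
  double nsA = s.Ns + Tn;
  double nrA = s.Nr + Un - Tn;
  double Gs = c.kg * modG * cs * ns * Ms;
  double Gr = c.kg * modG * cr * nr * Mr;
  if (c.fC * Gs > csA) Gs = csA / c.fC;
  if (c.fN * Gs > nsA) Gs = nsA / c.fN;
  if (c.fC * Gr > crA) Gr = crA / c.fC;
  if (c.fN * Gr > nrA) Gr = nrA / c.fN;
  if (Gs < 0) Gs = 0;
  if (Gr < 0) Gr = 0;

  s.Cs = csA - c.fC * Gs;
  s.Cr = crA - c.fC * Gr;
  s.Ns = nsA - c.fN * Gs;
  s.Nr = nrA - c.fN * Gr;
  s.Ms = s.Ms + Gs - c.lossS * s.Ms;
  s.Mr = s.Mr + Gr - c.lossR * s.Mr;

  if (s.Cs < 0) s.Cs = 0;
  if (s.Cr < 0) s.Cr = 0;
  if (s.Ns < 0) s.Ns = 0;
  if (s.Nr < 0) s.Nr = 0;
  if (s.Ms < 0) s.Ms = 0;
  if (s.Mr < 0) s.Mr = 0;
}

// equilibrium biomass for one parameter vector over many cells
// tmean, moisture, amax: ncell x 12 matrices
// [[Rcpp::export]]
NumericVector ttr_equilibrium_cpp(NumericVector par, NumericMatrix tmean,
                                  NumericMatrix moisture, NumericMatrix amax,
                                  List konst, double tol, int max_cycles) {
  TTRConstants c = read_constants(konst);
  int ncell = tmean.nrow();
  NumericVector out(ncell);
  LogicalVector conv(ncell);
  const double* p = REAL(par);
  double ucMax[12], unMax[12], modG[12];
  for (int i = 0; i < ncell; ++i) {
    conv[i] = true;
    double anyC = 0, anyN = 0, anyG = 0;
    for (int m = 0; m < 12; ++m) {
      double T = tmean(i, m), W = moisture(i, m);
      ucMax[m] = amax(i, m) * trap(W, p[8], p[9], p[10], p[11]);
      unMax[m] = c.sigmaN * trap(T, p[0], p[1], p[2], p[3]) *
                 trap(W, p[4], p[5], p[6], p[7]);
      modG[m] = trap(T, p[14], p[15], p[16], p[17]);
      anyC += ucMax[m]; anyN += unMax[m]; anyG += modG[m];
    }
    // no carbon source, no nitrogen source or no growth window in any
    // month: pools can only decay, the equilibrium is extinction
    if (anyC == 0.0 || anyN == 0.0 || anyG == 0.0) {
      out[i] = 0.0;
      continue;
    }
    TTRState s = {c.init_mass, c.init_mass, c.init_sub, c.init_sub,
                  c.init_sub, c.init_sub};
    double prevB = -1.0;
    double meanB = 0.0;
    bool settled = false;
    for (int cyc = 0; cyc < max_cycles; ++cyc) {
      double sumB = 0.0;
      for (int m = 0; m < 12; ++m) {
        step_pre(s, ucMax[m], unMax[m], modG[m], p[12], p[13], c);
        sumB += s.Ms + s.Mr;
      }
      meanB = sumB / 12.0;
      if (prevB >= 0.0) {
        double denom = std::max(prevB, c.b_floor);
        if (std::fabs(meanB - prevB) / denom < tol) { settled = true; break; }
        // dead trajectories: both cycles far below the biomass floor
        if (meanB < 0.01 * c.b_floor && prevB < 0.01 * c.b_floor) {
          settled = true; break;
        }
      }
      prevB = meanB;
    }
    conv[i] = settled;
    out[i] = (meanB < c.b_floor) ? 0.0 : meanB;
  }
  out.attr("converged") = conv;
  return out;
}

// profile cloglog Bernoulli regression of y on eta = log(B + eps):
// p = 1 - exp(-exp(b0 + b1 * eta)); returns (b0, b1, loglik)
static void cloglog_fit(const std::vector<double>& eta,
                        const std::vector<int>& y, double& b0, double& b1,
                        double& ll) {
  int n = eta.size();
  b0 = 0.0; b1 = 0.5;
  double ridge = 1e-8;
  for (int it = 0; it < 50; ++it) {
    double g0 = 0, g1 = 0, h00 = ridge, h01 = 0, h11 = ridge;
    for (int i = 0; i < n; ++i) {
      double lin = b0 + b1 * eta[i];
      if (lin > 30) lin = 30;
      double ex = std::exp(lin);
      double p = -std::expm1(-ex);
      if (p < 1e-12) p = 1e-12;
      if (p > 1 - 1e-12) p = 1 - 1e-12;
      double q = 1.0 - p;
      // d loglik / d lin
      double dldlin = y[i] ? ex * q / p : -ex;
      // expected information: ex^2 * q / p
      double w = ex * ex * q / p;
      if (w < 1e-12) w = 1e-12;
      g0 += dldlin; g1 += dldlin * eta[i];
      h00 += w; h01 += w * eta[i]; h11 += w * eta[i] * eta[i];
    }
    double det = h00 * h11 - h01 * h01;
    if (det <= 1e-14) break;
    double d0 = (h11 * g0 - h01 * g1) / det;
    double d1 = (h00 * g1 - h01 * g0) / det;
    // damp large steps
    double mx = std::max(std::fabs(d0), std::fabs(d1));
    if (mx > 5.0) { d0 *= 5.0 / mx; d1 *= 5.0 / mx; }
    b0 += d0; b1 += d1;
    if (std::fabs(d0) < 1e-8 && std::fabs(d1) < 1e-8) break;
  }
  ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double lin = b0 + b1 * eta[i];
    if (lin > 30) lin = 30;
    double ex = std::exp(lin);
    double p = -std::expm1(-ex);
    if (p < 1e-12) p = 1e-12;
    if (p > 1 - 1e-12) p = 1 - 1e-12;
    ll += y[i] ? std::log(p) : std::log1p(-p);
  }
}

// [[Rcpp::export]]
List cloglog_calibrate_cpp(NumericVector logB, IntegerVector y) {
  std::vector<double> eta(logB.begin(), logB.end());
  std::vector<int> yy(y.begin(), y.end());
  double b0, b1, ll;
  cloglog_fit(eta, yy, b0, b1, ll);
  return List::create(_["b0"] = b0, _["b1"] = b1, _["loglik"] = ll);
}

// DE objective: for each candidate row of `pop` (18 columns), simulate
// equilibrium biomass at the sample cells, profile the cloglog calibration,
// and return the negative Bernoulli log-likelihood.
// [[Rcpp::export]]
NumericVector ttr_objective_cpp(NumericMatrix pop, NumericMatrix tmean,
                                NumericMatrix moisture, NumericMatrix amax,
                                IntegerVector y, List konst, double tol,
                                int max_cycles, double eps) {
  int ncand = pop.nrow();
  int ncell = tmean.nrow();
  NumericVector nll(ncand);
  std::vector<int> yy(y.begin(), y.end());
  for (int k = 0; k < ncand; ++k) {
    NumericVector par = pop(k, _);
    NumericVector B = ttr_equilibrium_cpp(par, tmean, moisture, amax, konst,
                                          tol, max_cycles);
    std::vector<double> eta(ncell);
    for (int i = 0; i < ncell; ++i) eta[i] = std::log(B[i] + eps);
    double b0, b1, ll;
    cloglog_fit(eta, yy, b0, b1, ll);
    nll[k] = -ll;
  }
  return nll;
}
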