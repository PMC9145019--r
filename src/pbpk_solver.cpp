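// Compiled PBPK core: right-hand side of the coupled compound x compartment
// ODE system (plus enzyme turnover pools and cumulative process fluxes) and
// an adaptive Dormand-Prince 5(4) integrator with exact stepping onto the
// requested output grid. Dose events are handled by the R wrapper, which
// integrates segment-wise between event times.
//
// State vector layout (ntot = nc*9 + np + npool):
//   [0,                nc*7)   amounts A(c,k), micromol, row-major over k
//   [nc*7,             nc*8)   cumulative faeces (unabsorbed lumen exit)
//   [nc*8,             nc*9)   cumulative absorbed (lumen -> gut wall)
//   [nc*9,        nc*9 + np)   cumulative process fluxes, micromol
//   [nc*9 + np,         ntot)  relative active enzyme pools (baseline 1)
//
// Compartments: 0 venous blood, 1 arterial blood, 2 gut lumen, 3 gut wall
// (intestinal mucosa), 4 liver, 5 kidney, 6 rest-of-body.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

enum Comp { VEN = 0, ART = 1, LUMEN = 2, GUT = 3, LIV = 4, KID = 5, REST = 6 };
static const int NK = 7;

enum ProcType { P_MM = 0, P_CL = 1, P_ENZLIN = 2 };
enum Mech { M_COMP = 0, M_MBI = 1, M_IND = 2 };

struct Model {
  int nc, ne, np, ni, npool;
  std::vector<double> V;          // [7] L
  double Qgut, Qha, Qkid, Qrest, Qtot;
  std::vector<double> fu, ka, ktr;      // [nc]
  std::vector<double> Kp;               // [nc*7]
  std::vector<double> E;                // [ne*7] micromol/L tissue
  std::vector<double> kdeg, act;        // [ne]
  std::vector<int> p_type, p_sub, p_prod, p_org, p_enz;   // [np]
  std::vector<double> p_km, p_kcat, p_cl;                 // [np]
  std::vector<int> i_perp, i_enz, i_mech;                 // [ni]
  std::vector<double> i_ki, i_kinact, i_KI, i_emax, i_ec50;
  std::vector<int> pool_map;            // [ne*7] -> pool index or -1
  std::vector<int> pool_enz, pool_org;  // [npool]
  int off_fec, off_abs, off_flux, off_pool, ntot;
};

static Model build_model(const List& m) {
  Model M;
  M.nc = as<int>(m["nc"]);
  M.ne = as<int>(m["ne"]);
  NumericVector V = m["V"];
  M.V.assign(V.begin(), V.end());
  M.Qgut = as<double>(m["Q_gut"]);
  M.Qha = as<double>(m["Q_ha"]);
  M.Qkid = as<double>(m["Q_kid"]);
  M.Qrest = as<double>(m["Q_rest"]);
  M.Qtot = M.Qgut + M.Qha + M.Qkid + M.Qrest;
  NumericVector fu = m["fu"], ka = m["ka"], ktr = m["ktr"], Kp = m["Kp"];
  M.fu.assign(fu.begin(), fu.end());
  M.ka.assign(ka.begin(), ka.end());
  M.ktr.assign(ktr.begin(), ktr.end());
  M.Kp.assign(Kp.begin(), Kp.end());
  NumericVector E = m["E"], kdeg = m["kdeg"], act = m["act"];
  M.E.assign(E.begin(), E.end());
  M.kdeg.assign(kdeg.begin(), kdeg.end());
  M.act.assign(act.begin(), act.end());
  IntegerVector pt = m["p_type"], ps = m["p_sub"], pp = m["p_prod"],
                po = m["p_org"], pe = m["p_enz"];
  M.np = pt.size();
  M.p_type.assign(pt.begin(), pt.end());
  M.p_sub.assign(ps.begin(), ps.end());
  M.p_prod.assign(pp.begin(), pp.end());
  M.p_org.assign(po.begin(), po.end());
  M.p_enz.assign(pe.begin(), pe.end());
  NumericVector km = m["p_km"], kc = m["p_kcat"], cl = m["p_cl"];
  M.p_km.assign(km.begin(), km.end());
  M.p_kcat.assign(kc.begin(), kc.end());
  M.p_cl.assign(cl.begin(), cl.end());
  IntegerVector ip = m["i_perp"], ie = m["i_enz"], im = m["i_mech"];
  M.ni = ip.size();
  M.i_perp.assign(ip.begin(), ip.end());
  M.i_enz.assign(ie.begin(), ie.end());
  M.i_mech.assign(im.begin(), im.end());
  NumericVector ki = m["i_ki"], kin = m["i_kinact"], KI = m["i_KI"],
                em = m["i_emax"], ec = m["i_ec50"];
  M.i_ki.assign(ki.begin(), ki.end());
  M.i_kinact.assign(kin.begin(), kin.end());
  M.i_KI.assign(KI.begin(), KI.end());
  M.i_emax.assign(em.begin(), em.end());
  M.i_ec50.assign(ec.begin(), ec.end());
  IntegerVector pm = m["pool_map"], pen = m["pool_enz"], por = m["pool_org"];
  M.pool_map.assign(pm.begin(), pm.end());
  M.pool_enz.assign(pen.begin(), pen.end());
  M.pool_org.assign(por.begin(), por.end());
  M.npool = pen.size();
  M.off_fec = M.nc * 7;
  M.off_abs = M.nc * 8;
  M.off_flux = M.nc * 9;
  M.off_pool = M.off_flux + M.np;
  M.ntot = M.off_pool + M.npool;
  return M;
}

// Unbound (plasma-water equivalent) concentration of compound c in organ k.
static inline double cu_organ(const Model& M, const double* y, int c, int k) {
  double a = y[c * NK + k];
  if (a <= 0.0) return 0.0;
  return M.fu[c] * a / (M.V[k] * M.Kp[c * NK + k]);
}

static void rhs(const Model& M, double t, const double* y, double* dy,
                const double* ivrate, const double* porate) {
  (void)t;
  const int nc = M.nc;
  for (int i = 0; i < M.ntot; ++i) dy[i] = 0.0;

  // physiologic transport per compound
  for (int c = 0; c < nc; ++c) {
    const double* A = y + c * NK;
    double* dA = dy + c * NK;
    double Cven = (A[VEN] > 0.0) ? A[VEN] / M.V[VEN] : 0.0;
    double Cart = (A[ART] > 0.0) ? A[ART] / M.V[ART] : 0.0;
    double Cgut = (A[GUT] > 0.0) ? A[GUT] / (M.V[GUT] * M.Kp[c * NK + GUT]) : 0.0;
    double Cliv = (A[LIV] > 0.0) ? A[LIV] / (M.V[LIV] * M.Kp[c * NK + LIV]) : 0.0;
    double Ckid = (A[KID] > 0.0) ? A[KID] / (M.V[KID] * M.Kp[c * NK + KID]) : 0.0;
    double Crest = (A[REST] > 0.0) ? A[REST] / (M.V[REST] * M.Kp[c * NK + REST]) : 0.0;

    dA[ART] += M.Qtot * (Cven - Cart);
    dA[GUT] += M.Qgut * (Cart - Cgut);
    dA[LIV] += M.Qha * Cart + M.Qgut * Cgut - (M.Qha + M.Qgut) * Cliv;
    dA[KID] += M.Qkid * (Cart - Ckid);
    dA[REST] += M.Qrest * (Cart - Crest);
    dA[VEN] += (M.Qha + M.Qgut) * Cliv + M.Qkid * Ckid + M.Qrest * Crest -
               M.Qtot * Cven + ivrate[c];

    // gut lumen: first-order absorption into gut wall, transit to faeces
    double Alum = (A[LUMEN] > 0.0) ? A[LUMEN] : 0.0;
    double abs_flux = M.ka[c] * Alum;
    double fec_flux = M.ktr[c] * Alum;
    dA[LUMEN] += porate[c] - abs_flux - fec_flux;
    dA[GUT] += abs_flux;
    dy[M.off_fec + c] = fec_flux;
    dy[M.off_abs + c] = abs_flux;
  }

  // interaction terms evaluated per (enzyme, organ) on unbound organ conc
  // cmult: apparent-KM multiplier; lam: inactivation rate; mind: synthesis mult
  std::vector<double> cmult(M.ne * NK, 1.0), lam(M.ne * NK, 0.0),
      mind(M.ne * NK, 1.0);
  for (int j = 0; j < M.ni; ++j) {
    int e = M.i_enz[j], perp = M.i_perp[j];
    for (int k = GUT; k <= KID; ++k) {  // enzymes live in gut wall/liver/kidney
      double I = cu_organ(M, y, perp, k);
      switch (M.i_mech[j]) {
        case M_COMP:
          cmult[e * NK + k] += I / M.i_ki[j];
          break;
        case M_MBI:
          lam[e * NK + k] += M.i_kinact[j] * I / (M.i_KI[j] + I);
          break;
        case M_IND:
          mind[e * NK + k] *= 1.0 + M.i_emax[j] * I / (M.i_ec50[j] + I);
          break;
      }
    }
  }

  // enzyme pool turnover: d pool/dt = kdeg*mind - (kdeg + lam)*pool
  for (int q = 0; q < M.npool; ++q) {
    int e = M.pool_enz[q], k = M.pool_org[q];
    double pool = y[M.off_pool + q];
    dy[M.off_pool + q] =
        M.kdeg[e] * mind[e * NK + k] - (M.kdeg[e] + lam[e * NK + k]) * pool;
  }

  // metabolic and clearance processes
  for (int j = 0; j < M.np; ++j) {
    int c = M.p_sub[j], k = M.p_org[j];
    double Cu = cu_organ(M, y, c, k);
    double rate = 0.0;
    if (M.p_type[j] == P_CL) {
      rate = M.p_cl[j] * Cu;
    } else {
      int e = M.p_enz[j];
      double pool = 1.0;
      int q = M.pool_map[e * NK + k];
      if (q >= 0) pool = y[M.off_pool + q];
      if (pool < 0.0) pool = 0.0;
      double act = M.act[e] * pool;
      double cm = cmult[e * NK + k];
      if (M.p_type[j] == P_MM) {
        double vmax = M.p_kcat[j] * act * M.E[e * NK + k] * M.V[k];
        double den = M.p_km[j] * cm + Cu;
        rate = (den > 0.0) ? vmax * Cu / den : 0.0;
      } else {  // enzyme-scaled linear clearance (partner stubs)
        rate = M.p_cl[j] * act * Cu / cm;
      }
    }
    dy[c * NK + k] -= rate;
    if (M.p_prod[j] >= 0) dy[M.p_prod[j] * NK + k] += rate;
    dy[M.off_flux + j] = rate;
  }
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// [[Rcpp::export]]
List pbpk_integrate_cpp(List model, NumericVector y0, double t0,
                        NumericVector times, NumericVector ivrate,
                        NumericVector porate, double rtol, double atol,
                        double hmax, int maxsteps) {
  Model M = build_model(model);
  const int n = M.ntot;
  if ((int)y0.size() != n) stop("state vector length mismatch");
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n), yt(n),
      ynew(n);
  const double* iv = ivrate.begin();
  const double* po = porate.begin();

  int nt = times.size();
  NumericMatrix out(nt, n);
  int iout = 0;
  double t = t0;
  double tend = times[nt - 1];
  double h = std::min(hmax, std::max(1e-8, (tend - t0) / 100.0));
  // initial derivative (FSAL)
  rhs(M, t, y.data(), k1.data(), iv, po);
  int steps = 0;

  while (iout < nt) {
    if (times[iout] <= t + 1e-12) {  // output point reached
      for (int i = 0; i < n; ++i) out(iout, i) = y[i];
      ++iout;
      continue;
    }
    if (++steps > maxsteps) stop("pbpk solver: maximum step count exceeded");
    double tnext = times[iout];
    bool hit = false;
    double hfull = h;
    if (t + h >= tnext) {
      h = tnext - t;
      hit = true;
    }

    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * a21 * k1[i];
    rhs(M, t + c2 * h, yt.data(), k2.data(), iv, po);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(M, t + c3 * h, yt.data(), k3.data(), iv, po);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(M, t + c4 * h, yt.data(), k4.data(), iv, po);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(M, t + c5 * h, yt.data(), k5.data(), iv, po);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    rhs(M, t + h, yt.data(), k6.data(), iv, po);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                            b6 * k6[i]);
    rhs(M, t + h, ynew.data(), k7.data(), iv, po);

    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / n);

    if (errnorm <= 1.0 || h <= 1e-12) {
      t += h;
      y.swap(ynew);
      k1.swap(k7);  // FSAL
      double fac = (errnorm > 1e-12) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      fac = std::min(5.0, std::max(0.2, fac));
      // when the step was shortened to land on an output point, resume from
      // the unshortened step so output density does not throttle the solver
      h = std::min(hmax, (hit ? hfull : h) * fac);
    } else {
      double fac = std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
      h *= fac;
      if (h < 1e-13) stop("pbpk solver: step size underflow");
    }
  }

  return List::create(_["y"] = out, _["final"] = NumericVector(y.begin(), y.end()),
                      _["steps"] = steps);
}
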