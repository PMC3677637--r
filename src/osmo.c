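/* Compiled right-hand side of the 29-state osmoadaptation model.
 *
 * Exposed two ways:
 *  - deSolve compiled-model interface (osmo_initmod / osmo_derivs) for
 *    fast stiff integration;
 *  - .Call entry points returning derivatives (and fluxes/observables)
 *    for finite-difference Jacobians and property tests against the
 *    pure-R reference implementation.
 *
 * Parameter vector layout follows hog_param_names() exactly; one extra
 * trailing entry (index NPAR) is a freeze flag that zeroes the external
 * derivatives during pre-stress equilibration.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define NSTATE 29
#define NPAR 74
#define NFLUX 20
#define NOBS 17

/* parameter indices (canonical order) */
enum {
  i_Vb, i_Vos0, i_Lp_A, i_Pi_t0, i_V_lp, i_n0, i_i_vh, i_Pi_e0,
  i_Hog1tot, i_k_ph, i_k_dp,
  i_k_b1, i_k_h1, i_k_o1, i_d_m1, i_ks1, i_kd1, i_k_dim, i_k_undim, i_kd1d,
  i_k_b2, i_k_o2, i_d2,
  i_k_s0, i_K_rep, i_k_s1, i_d_ms, i_ks_s, i_kd_s,
  i_PfkT, i_k_a26, i_k_i26, i_k_f26, i_K_f26s, i_d_f26,
  i_k_open, i_k_cT, i_k_cH, i_k_fps,
  i_kHXT, i_KHXT, i_VmHK, i_KHK, i_VmPFK, i_KPFK, i_aF, i_KF26,
  i_kALD, i_VmLG, i_KLG, i_VmPDC, i_KPDC, i_VmALD6, i_KALD6,
  i_kcatGpd1, i_kcatGpd2, i_KGPD, i_VmGPP, i_KGPP,
  i_kTPS0, i_kTPSh, i_KTPS, i_kNTH,
  i_k_tE, i_k_tA, i_k_tT,
  i_VmSTL, i_KSTL,
  i_mu0, i_theta_H, i_K_gH, i_V_gmin, i_gamma_bm, i_K_bm
};

/* state indices */
enum {
  s_Vos, s_Hog1u, s_Hog1PP,
  s_mGPD1, s_Gpd1m, s_Gpd1d, s_Gpd2,
  s_mSTL1, s_Stl1,
  s_Pfk26a, s_F26DP,
  s_Fps1o,
  s_Glci, s_HexP, s_FBP, s_TriP, s_G3P, s_Glyi, s_Pyr, s_EtOHi, s_AcOi,
  s_Trei,
  s_Glce, s_Glye, s_EtOHe, s_AcOe, s_Tree,
  s_NaCle,
  s_CD
};

static double clipd(double x, double lo, double hi) {
  if (x < lo) return lo;
  if (x > hi) return hi;
  return x;
}

/* core: fills dy (length 29); flux (length 20) and obs (length 17) are
 * optional (NULL allowed). */
static void osmo_core(double t, const double *y, const double *p,
                      double *dy, double *flux, double *obs) {
  double Vos = y[s_Vos];
  if (Vos < 1e-8) Vos = 1e-8; /* numeric guard for wild optimizer steps */

  double cGlci = y[s_Glci] / Vos, cHexP = y[s_HexP] / Vos;
  double cFBP  = y[s_FBP]  / Vos, cTriP = y[s_TriP] / Vos;
  double cG3P  = y[s_G3P]  / Vos, cGlyi = y[s_Glyi] / Vos;
  double cPyr  = y[s_Pyr]  / Vos, cEtOHi = y[s_EtOHi] / Vos;
  double cAcOi = y[s_AcOi] / Vos, cTrei = y[s_Trei] / Vos;
  double cF26  = y[s_F26DP] / Vos;

  /* observables */
  double osmo_amt = p[i_n0] + y[s_Glci] + y[s_HexP] + y[s_FBP] + y[s_TriP] +
    y[s_G3P] + y[s_Glyi] + y[s_Pyr] + y[s_EtOHi] + y[s_AcOi] + y[s_Trei];
  double Pi_i = 1e-3 * osmo_amt / Vos;
  double Pi_e = p[i_Pi_e0] + p[i_i_vh] * y[s_NaCle] +
    1e-3 * (y[s_Glce] + y[s_Glye] + y[s_EtOHe] + y[s_AcOe] + y[s_Tree]);
  double Pi_t = p[i_Pi_t0] * (Vos - p[i_V_lp]) / (p[i_Vos0] - p[i_V_lp]);
  Pi_t = clipd(Pi_t, 0.0, p[i_Pi_t0]);
  double u = (p[i_Pi_t0] - Pi_t) / p[i_Pi_t0];
  if (u < 0) u = 0;
  double volf = clipd((Vos - p[i_V_gmin]) / (p[i_Vos0] - p[i_V_gmin]),
                      0.0, 1.0);
  double hogf = 1.0 - p[i_theta_H] * y[s_Hog1PP] / (p[i_K_gH] + y[s_Hog1PP]);
  double mu = p[i_mu0] * volf * hogf;

  /* rate laws */
  double vHXT = p[i_kHXT] * y[s_Glce] / (p[i_KHXT] + y[s_Glce]);
  double vHK = p[i_VmHK] * cGlci / (p[i_KHK] + cGlci);
  double vPFK = p[i_VmPFK] * (1.0 + p[i_aF] * cF26 / (p[i_KF26] + cF26)) *
    cHexP / (p[i_KPFK] + cHexP);
  double vALD = p[i_kALD] * y[s_FBP];
  double vLG = p[i_VmLG] * cTriP / (p[i_KLG] + cTriP);
  double vPDC = p[i_VmPDC] * cPyr / (p[i_KPDC] + cPyr);
  double vALD6 = p[i_VmALD6] * cPyr / (p[i_KALD6] + cPyr);
  double vGPD1 = p[i_kcatGpd1] * y[s_Gpd1d] * cTriP / (p[i_KGPD] + cTriP);
  double vGPD2 = p[i_kcatGpd2] * y[s_Gpd2] * cTriP / (p[i_KGPD] + cTriP);
  double vGPP = p[i_VmGPP] * cG3P / (p[i_KGPP] + cG3P);
  double vTPS = (p[i_kTPS0] + p[i_kTPSh] * y[s_Hog1PP]) *
    cHexP / (p[i_KTPS] + cHexP);
  double vNTH = p[i_kNTH] * y[s_Trei];
  double vFPS = p[i_k_fps] * y[s_Fps1o] * (cGlyi - y[s_Glye]);
  double vSTL = p[i_VmSTL] * y[s_Stl1] * y[s_Glye] /
    (p[i_KSTL] + y[s_Glye]);
  double vEtOHt = p[i_k_tE] * (cEtOHi - y[s_EtOHe]);
  double vAcOt = p[i_k_tA] * (cAcOi - y[s_AcOe]);
  double vTret = p[i_k_tT] * (cTrei - y[s_Tree]);
  double vBM = p[i_gamma_bm] * mu * cHexP / (p[i_K_bm] + cHexP);
  double vPH = p[i_k_ph] * u * y[s_Hog1u];
  double vDP = p[i_k_dp] * y[s_Hog1PP];

  double hterm = (p[i_Hog1tot] > 0) ?
    p[i_k_cH] * y[s_Hog1PP] / p[i_Hog1tot] : 0.0;
  double cd = y[s_CD] * 1e-12; /* cells per fL culture */

  dy[s_Vos] = p[i_Lp_A] * (Pi_i - Pi_e - Pi_t);
  dy[s_Hog1u] = -vPH + vDP + mu * (p[i_Hog1tot] - y[s_Hog1u]);
  dy[s_Hog1PP] = vPH - vDP - mu * y[s_Hog1PP];
  dy[s_mGPD1] = p[i_k_b1] + p[i_k_h1] * y[s_Hog1PP] + p[i_k_o1] * u -
    (p[i_d_m1] + mu) * y[s_mGPD1];
  dy[s_Gpd1m] = p[i_ks1] * y[s_mGPD1] - p[i_kd1] * y[s_Gpd1m] -
    2.0 * p[i_k_dim] * y[s_Gpd1m] * y[s_Gpd1m] +
    2.0 * p[i_k_undim] * y[s_Gpd1d] - mu * y[s_Gpd1m];
  dy[s_Gpd1d] = p[i_k_dim] * y[s_Gpd1m] * y[s_Gpd1m] -
    p[i_k_undim] * y[s_Gpd1d] - p[i_kd1d] * y[s_Gpd1d] - mu * y[s_Gpd1d];
  dy[s_Gpd2] = p[i_k_b2] + p[i_k_o2] * u - (p[i_d2] + mu) * y[s_Gpd2];
  dy[s_mSTL1] = p[i_k_s0] * p[i_K_rep] / (p[i_K_rep] + y[s_Glce]) +
    p[i_k_s1] * y[s_Hog1PP] - (p[i_d_ms] + mu) * y[s_mSTL1];
  dy[s_Stl1] = p[i_ks_s] * y[s_mSTL1] - (p[i_kd_s] + mu) * y[s_Stl1];
  dy[s_Pfk26a] = p[i_k_a26] * y[s_Hog1PP] * (p[i_PfkT] - y[s_Pfk26a]) -
    p[i_k_i26] * y[s_Pfk26a];
  dy[s_F26DP] = p[i_k_f26] * y[s_Pfk26a] * cHexP / (p[i_K_f26s] + cHexP) -
    (p[i_d_f26] + mu) * y[s_F26DP];
  dy[s_Fps1o] = p[i_k_open] * (1.0 - y[s_Fps1o]) -
    (p[i_k_cT] * u + hterm) * y[s_Fps1o];

  dy[s_Glci] = vHXT - vHK + 2.0 * vNTH - mu * y[s_Glci];
  dy[s_HexP] = vHK - vPFK - 2.0 * vTPS - vBM - mu * y[s_HexP];
  dy[s_FBP] = vPFK - vALD - mu * y[s_FBP];
  dy[s_TriP] = 2.0 * vALD - vLG - vGPD1 - vGPD2 - mu * y[s_TriP];
  dy[s_G3P] = vGPD1 + vGPD2 - vGPP - mu * y[s_G3P];
  dy[s_Glyi] = vGPP - vFPS + vSTL - mu * y[s_Glyi];
  dy[s_Pyr] = vLG - vPDC - vALD6 - mu * y[s_Pyr];
  dy[s_EtOHi] = vPDC - vEtOHt - mu * y[s_EtOHi];
  dy[s_AcOi] = vALD6 - vAcOt - mu * y[s_AcOi];
  dy[s_Trei] = vTPS - vNTH - vTret - mu * y[s_Trei];

  dy[s_Glce] = -cd * vHXT;
  dy[s_Glye] = cd * (vFPS - vSTL);
  dy[s_EtOHe] = cd * vEtOHt;
  dy[s_AcOe] = cd * vAcOt;
  dy[s_Tree] = cd * vTret;
  dy[s_NaCle] = 0.0;
  dy[s_CD] = mu * y[s_CD];

  if (p[NPAR] > 0.5) { /* freeze externals for equilibration */
    dy[s_Glce] = dy[s_Glye] = dy[s_EtOHe] = dy[s_AcOe] = dy[s_Tree] = 0.0;
    dy[s_NaCle] = dy[s_CD] = 0.0;
  }

  if (flux) {
    flux[0] = vHXT; flux[1] = vHK; flux[2] = vPFK; flux[3] = vALD;
    flux[4] = vLG; flux[5] = vPDC; flux[6] = vALD6; flux[7] = vGPD1;
    flux[8] = vGPD2; flux[9] = vGPP; flux[10] = vTPS; flux[11] = vNTH;
    flux[12] = vFPS; flux[13] = vSTL; flux[14] = vEtOHt; flux[15] = vAcOt;
    flux[16] = vTret; flux[17] = vBM; flux[18] = vPH; flux[19] = vDP;
  }
  if (obs) {
    obs[0] = p[i_Vb] + Vos; obs[1] = Pi_i; obs[2] = Pi_e; obs[3] = Pi_t;
    obs[4] = u; obs[5] = mu;
    obs[6] = y[s_Gpd1m] + 2.0 * y[s_Gpd1d];
    obs[7] = cGlci; obs[8] = cHexP; obs[9] = cFBP; obs[10] = cTriP;
    obs[11] = cG3P; obs[12] = cGlyi; obs[13] = cPyr; obs[14] = cEtOHi;
    obs[15] = cAcOi; obs[16] = cTrei;
  }
}

/* ---- deSolve compiled-model interface ---- */
static double parms[NPAR + 1];

void osmo_initmod(void (*odeparms)(int *, double *)) {
  int n = NPAR + 1;
  odeparms(&n, parms);
}

void osmo_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip) {
  osmo_core(*t, y, parms, ydot, NULL, NULL);
}

/* ---- .Call interface ---- */
SEXP C_hog_deriv(SEXP t, SEXP y, SEXP p) {
  if (LENGTH(y) != NSTATE) error("state vector must have 29 entries");
  if (LENGTH(p) != NPAR + 1) error("parameter vector must have %d entries",
                                   NPAR + 1);
  SEXP dy = PROTECT(allocVector(REALSXP, NSTATE));
  osmo_core(asReal(t), REAL(y), REAL(p), REAL(dy), NULL, NULL);
  UNPROTECT(1);
  return dy;
}

SEXP C_hog_rhs_full(SEXP t, SEXP y, SEXP p) {
  if (LENGTH(y) != NSTATE) error("state vector must have 29 entries");
  if (LENGTH(p) != NPAR + 1) error("parameter vector must have %d entries",
                                   NPAR + 1);
  SEXP dy = PROTECT(allocVector(REALSXP, NSTATE));
  SEXP fl = PROTECT(allocVector(REALSXP, NFLUX));
  SEXP ob = PROTECT(allocVector(REALSXP, NOBS));
  osmo_core(asReal(t), REAL(y), REAL(p), REAL(dy), REAL(fl), REAL(ob));
  SEXP out = PROTECT(allocVector(VECSXP, 3));
  SET_VECTOR_ELT(out, 0, dy);
  SET_VECTOR_ELT(out, 1, fl);
  SET_VECTOR_ELT(out, 2, ob);
  SEXP nms = PROTECT(allocVector(STRSXP, 3));
  SET_STRING_ELT(nms, 0, mkChar("deriv"));
  SET_STRING_ELT(nms, 1, mkChar("flux"));
  SET_STRING_ELT(nms, 2, mkChar("obs"));
  setAttrib(out, R_NamesSymbol, nms);
  UNPROTECT(5);
  return out;
}

static const R_CallMethodDef callMethods[] = {
  {"C_hog_deriv", (DL_FUNC) &C_hog_deriv, 3},
  {"C_hog_rhs_full", (DL_FUNC) &C_hog_rhs_full, 3},
  {NULL, NULL, 0}
};

void R_init_hogadapt(DllInfo *info) {
  R_registerRoutines(info, NULL, callMethods, NULL, NULL);
  /* deSolve locates osmo_derivs/osmo_initmod by name in this DLL */
  R_useDynamicSymbols(info, TRUE);
}
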