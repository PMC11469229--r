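// Element kernels for the vessel FEA: linear tetrahedra, Mooney-Rivlin-5
// (isochoric split + volumetric penalty, optional nodal-patch pressure
// averaging against volumetric locking) and Saint Venant-Kirchhoff
// materials, plus the explicit central-difference time integrator.
//
// Units: um - us - MPa; density in 1e6 kg/m^3.
//
// The force evaluation is the hot path of the explicit loop, so it is
// written on raw arrays with hand-coded 3x3 algebra; the (rarely called)
// stress reporting and finite-difference tangent use Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int MAT_MR5 = 0;

struct MatRow {
  int type;
  double p0, p1, p2, p3, p4, p5, rho;
};

static inline MatRow mat_row(const IntegerVector &mtype,
                             const NumericMatrix &mpar, int e) {
  MatRow m;
  m.type = mtype[e];
  m.p0 = mpar(e, 0); m.p1 = mpar(e, 1); m.p2 = mpar(e, 2);
  m.p3 = mpar(e, 3); m.p4 = mpar(e, 4); m.p5 = mpar(e, 5);
  m.rho = mpar(e, 6);
  return m;
}

// ---- fast raw-array force kernel -------------------------------------------

// Static model view: all pointers borrowed from R objects (column-major
// Rcpp matrices), node coordinates node-major (x,y,z per node).
struct FastModel {
  int N, M;
  const int *t1, *t2, *t3, *t4;     // 1-based node ids, columns of tets
  const double *G;                  // M x 12 column-major: G[c*M + e]
  const double *V0;
  const int *type;
  const double *par;                // M x 7 column-major
  const bool *proj;                 // projection flag per element (as int)
  std::vector<int> projv;
};

static FastModel make_model(const NumericMatrix &X, const IntegerMatrix &tets,
                            const NumericMatrix &G, const NumericVector &V0,
                            const IntegerVector &mtype, const NumericMatrix &mpar,
                            const LogicalVector &proj) {
  FastModel fm;
  fm.N = X.nrow(); fm.M = tets.nrow();
  fm.t1 = &tets(0, 0); fm.t2 = &tets(0, 1);
  fm.t3 = &tets(0, 2); fm.t4 = &tets(0, 3);
  fm.G = &G(0, 0);
  fm.V0 = &V0[0];
  fm.type = &mtype[0];
  fm.par = &mpar(0, 0);
  fm.projv.resize(fm.M);
  for (int e = 0; e < fm.M; ++e) fm.projv[e] = proj[e] ? 1 : 0;
  fm.proj = nullptr;
  return fm;
}

static inline double det3(const double *f) {
  return f[0] * (f[4] * f[8] - f[5] * f[7]) -
         f[1] * (f[3] * f[8] - f[5] * f[6]) +
         f[2] * (f[3] * f[7] - f[4] * f[6]);
}

static inline void inv3(const double *f, double J, double *g) {
  double id = 1.0 / J;
  g[0] = (f[4] * f[8] - f[5] * f[7]) * id;
  g[1] = (f[2] * f[7] - f[1] * f[8]) * id;
  g[2] = (f[1] * f[5] - f[2] * f[4]) * id;
  g[3] = (f[5] * f[6] - f[3] * f[8]) * id;
  g[4] = (f[0] * f[8] - f[2] * f[6]) * id;
  g[5] = (f[2] * f[3] - f[0] * f[5]) * id;
  g[6] = (f[3] * f[7] - f[4] * f[6]) * id;
  g[7] = (f[1] * f[6] - f[0] * f[7]) * id;
  g[8] = (f[0] * f[4] - f[1] * f[3]) * id;
}

// deformation gradient (row-major 9) of element e from node-major
// displacements: F = I + sum_a u_a (x) g_a, exactly the identity at rest
static inline void def_grad_fast(const FastModel &fm, const double *uc,
                                 int e, int *nd, double *F) {
  nd[0] = fm.t1[e] - 1; nd[1] = fm.t2[e] - 1;
  nd[2] = fm.t3[e] - 1; nd[3] = fm.t4[e] - 1;
  for (int k = 0; k < 9; ++k) F[k] = 0.0;
  F[0] = F[4] = F[8] = 1.0;
  for (int a = 0; a < 4; ++a) {
    const double *x = uc + 3 * nd[a];
    const double g0 = fm.G[(3 * a + 0) * fm.M + e];
    const double g1 = fm.G[(3 * a + 1) * fm.M + e];
    const double g2 = fm.G[(3 * a + 2) * fm.M + e];
    F[0] += x[0] * g0; F[1] += x[0] * g1; F[2] += x[0] * g2;
    F[3] += x[1] * g0; F[4] += x[1] * g1; F[5] += x[1] * g2;
    F[6] += x[2] * g0; F[7] += x[2] * g1; F[8] += x[2] * g2;
  }
}

// Kirchhoff stress tau (sym, row-major full 9) + isochoric energy density.
// Returns false on J <= 0. `p_over` used for MR when use_p.
static inline bool tau_fast(const double *F, const double *par_e, int type,
                            bool use_p, double p_over, double &J,
                            double *tau, double &Wi, double &Wvol_local) {
  J = det3(F);
  if (!(J > 0.0)) return false;
  Wvol_local = 0.0;
  if (type == MAT_MR5) {
    const double C10 = par_e[0], C01 = par_e[1], C20 = par_e[2],
                 C11 = par_e[3], C02 = par_e[4], D1 = par_e[5];
    // b = F F^T (sym: xx yy zz xy yz xz)
    double bxx = F[0]*F[0] + F[1]*F[1] + F[2]*F[2];
    double byy = F[3]*F[3] + F[4]*F[4] + F[5]*F[5];
    double bzz = F[6]*F[6] + F[7]*F[7] + F[8]*F[8];
    double bxy = F[0]*F[3] + F[1]*F[4] + F[2]*F[5];
    double byz = F[3]*F[6] + F[4]*F[7] + F[5]*F[8];
    double bxz = F[0]*F[6] + F[1]*F[7] + F[2]*F[8];
    double s = std::pow(J, -2.0 / 3.0);
    bxx *= s; byy *= s; bzz *= s; bxy *= s; byz *= s; bxz *= s;
    double I1 = bxx + byy + bzz;
    // bbar^2 (sym)
    double cxx = bxx*bxx + bxy*bxy + bxz*bxz;
    double cyy = bxy*bxy + byy*byy + byz*byz;
    double czz = bxz*bxz + byz*byz + bzz*bzz;
    double cxy = bxx*bxy + bxy*byy + bxz*byz;
    double cyz = bxy*bxz + byy*byz + byz*bzz;
    double cxz = bxx*bxz + bxy*byz + bxz*bzz;
    double I2 = 0.5 * (I1 * I1 - (cxx + cyy + czz));
    double x = I1 - 3.0, y = I2 - 3.0;
    double W1 = C10 + 2.0 * C20 * x + C11 * y;
    double W2 = C01 + C11 * x + 2.0 * C02 * y;
    Wi = C10 * x + C01 * y + C20 * x * x + C11 * x * y + C02 * y * y;
    double a1 = 2.0 * (W1 + I1 * W2), a2 = -2.0 * W2;
    double Axx = a1 * bxx + a2 * cxx, Ayy = a1 * byy + a2 * cyy,
           Azz = a1 * bzz + a2 * czz, Axy = a1 * bxy + a2 * cxy,
           Ayz = a1 * byz + a2 * cyz, Axz = a1 * bxz + a2 * cxz;
    double trA = (Axx + Ayy + Azz) / 3.0;
    double p = use_p ? p_over : (2.0 / D1) * (J - 1.0);
    if (!use_p) Wvol_local = (J - 1.0) * (J - 1.0) / D1;
    double d = J * p - trA;
    tau[0] = Axx + d; tau[4] = Ayy + d; tau[8] = Azz + d;
    tau[1] = tau[3] = Axy; tau[5] = tau[7] = Ayz; tau[2] = tau[6] = Axz;
  } else { // SVK
    const double E = par_e[0], nu = par_e[1];
    double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
    double mu = E / (2.0 * (1.0 + nu));
    // E_green = (F^T F - I)/2 (sym)
    double Cxx = F[0]*F[0] + F[3]*F[3] + F[6]*F[6];
    double Cyy = F[1]*F[1] + F[4]*F[4] + F[7]*F[7];
    double Czz = F[2]*F[2] + F[5]*F[5] + F[8]*F[8];
    double Cxy = F[0]*F[1] + F[3]*F[4] + F[6]*F[7];
    double Cyz = F[1]*F[2] + F[4]*F[5] + F[7]*F[8];
    double Cxz = F[0]*F[2] + F[3]*F[5] + F[6]*F[8];
    double Exx = 0.5 * (Cxx - 1.0), Eyy = 0.5 * (Cyy - 1.0),
           Ezz = 0.5 * (Czz - 1.0), Exy = 0.5 * Cxy, Eyz = 0.5 * Cyz,
           Exz = 0.5 * Cxz;
    double trE = Exx + Eyy + Ezz;
    double Sxx = lam * trE + 2.0 * mu * Exx, Syy = lam * trE + 2.0 * mu * Eyy,
           Szz = lam * trE + 2.0 * mu * Ezz, Sxy = 2.0 * mu * Exy,
           Syz = 2.0 * mu * Eyz, Sxz = 2.0 * mu * Exz;
    Wi = 0.5 * lam * trE * trE +
         mu * (Exx*Exx + Eyy*Eyy + Ezz*Ezz + 2.0*(Exy*Exy + Eyz*Eyz + Exz*Exz));
    // P = F S (row-major)
    double P[9];
    P[0] = F[0]*Sxx + F[1]*Sxy + F[2]*Sxz;
    P[1] = F[0]*Sxy + F[1]*Syy + F[2]*Syz;
    P[2] = F[0]*Sxz + F[1]*Syz + F[2]*Szz;
    P[3] = F[3]*Sxx + F[4]*Sxy + F[5]*Sxz;
    P[4] = F[3]*Sxy + F[4]*Syy + F[5]*Syz;
    P[5] = F[3]*Sxz + F[4]*Syz + F[5]*Szz;
    P[6] = F[6]*Sxx + F[7]*Sxy + F[8]*Sxz;
    P[7] = F[6]*Sxy + F[7]*Syy + F[8]*Syz;
    P[8] = F[6]*Sxz + F[7]*Syz + F[8]*Szz;
    // tau = P F^T
    tau[0] = P[0]*F[0] + P[1]*F[1] + P[2]*F[2];
    tau[1] = P[0]*F[3] + P[1]*F[4] + P[2]*F[5];
    tau[2] = P[0]*F[6] + P[1]*F[7] + P[2]*F[8];
    tau[4] = P[3]*F[3] + P[4]*F[4] + P[5]*F[5];
    tau[5] = P[3]*F[6] + P[4]*F[7] + P[5]*F[8];
    tau[8] = P[6]*F[6] + P[7]*F[7] + P[8]*F[8];
    tau[3] = tau[1]; tau[6] = tau[2]; tau[7] = tau[5];
  }
  return true;
}

// Full force pass: fint (3N node-major, zeroed by caller), total strain
// energy, optional per-element von Mises. Returns 0 or 1-based bad element.
static int fast_forces(const FastModel &fm, const double *uc, double *fint,
                       double *SE, double *vm_out, double *ptilde_out) {
  int N = fm.N, M = fm.M;
  std::vector<double> ptilde;
  bool any_proj = false;
  for (int e = 0; e < M; ++e) if (fm.projv[e]) { any_proj = true; break; }
  double E_vol = 0.0, E_iso = 0.0;
  if (any_proj) {
    ptilde.assign(M, 0.0);
    std::vector<double> V0a(N, 0.0), va(N, 0.0), WDa(N, 0.0);
    int nd[4]; double F[9];
    for (int e = 0; e < M; ++e) {
      if (!fm.projv[e]) continue;
      def_grad_fast(fm, uc, e, nd, F);
      double J = det3(F);
      if (!(J > 0.0)) return e + 1;
      double D1 = fm.par[5 * M + e];
      for (int a = 0; a < 4; ++a) {
        V0a[nd[a]] += fm.V0[e] / 4.0;
        va[nd[a]] += J * fm.V0[e] / 4.0;
        WDa[nd[a]] += fm.V0[e] / (4.0 * D1);
      }
    }
    std::vector<double> qa(N, 0.0);
    for (int n = 0; n < N; ++n) {
      if (V0a[n] > 0.0) {
        double Jbar = va[n] / V0a[n];
        qa[n] = 2.0 * (WDa[n] / V0a[n]) * (Jbar - 1.0);
        E_vol += WDa[n] * (Jbar - 1.0) * (Jbar - 1.0);
      }
    }
    for (int e = 0; e < M; ++e) {
      if (!fm.projv[e]) continue;
      ptilde[e] = 0.25 * (qa[fm.t1[e] - 1] + qa[fm.t2[e] - 1] +
                          qa[fm.t3[e] - 1] + qa[fm.t4[e] - 1]);
    }
  }
  int nd[4]; double F[9], tau[9], Fi[9];
  double par_e[7];
  for (int e = 0; e < M; ++e) {
    for (int k = 0; k < 7; ++k) par_e[k] = fm.par[k * M + e];
    def_grad_fast(fm, uc, e, nd, F);
    double J, Wi, Wv;
    bool use_p = fm.projv[e] != 0;
    if (!tau_fast(F, par_e, fm.type[e], use_p, use_p ? ptilde[e] : 0.0,
                  J, tau, Wi, Wv))
      return e + 1;
    E_iso += fm.V0[e] * Wi;
    E_vol += fm.V0[e] * Wv;
    inv3(F, J, Fi);
    // P = tau * F^{-T}: P_ij = sum_k tau_ik * Fi_jk
    double P[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        P[3 * i + j] = tau[3 * i + 0] * Fi[3 * j + 0] +
                       tau[3 * i + 1] * Fi[3 * j + 1] +
                       tau[3 * i + 2] * Fi[3 * j + 2];
    for (int a = 0; a < 4; ++a) {
      const double g0 = fm.G[(3 * a + 0) * M + e];
      const double g1 = fm.G[(3 * a + 1) * M + e];
      const double g2 = fm.G[(3 * a + 2) * M + e];
      double *fn = fint + 3 * nd[a];
      fn[0] += fm.V0[e] * (P[0] * g0 + P[1] * g1 + P[2] * g2);
      fn[1] += fm.V0[e] * (P[3] * g0 + P[4] * g1 + P[5] * g2);
      fn[2] += fm.V0[e] * (P[6] * g0 + P[7] * g1 + P[8] * g2);
    }
    if (vm_out) {
      double tr = (tau[0] + tau[4] + tau[8]) / 3.0;
      double dxx = tau[0] - tr, dyy = tau[4] - tr, dzz = tau[8] - tr;
      double ss = dxx*dxx + dyy*dyy + dzz*dzz +
                  2.0 * (tau[1]*tau[1] + tau[5]*tau[5] + tau[2]*tau[2]);
      vm_out[e] = std::sqrt(1.5 * ss) / J;
    }
    if (ptilde_out) ptilde_out[e] = any_proj && fm.projv[e] ? ptilde[e] : 0.0;
  }
  *SE = E_iso + E_vol;
  return 0;
}

// ---- exported: precompute, force, tangent, projection ----------------------

// [[Rcpp::export]]
List fem_precompute(const NumericMatrix &X, const IntegerMatrix &tets) {
  int M = tets.nrow();
  NumericMatrix G(M, 12); // g1x g1y g1z g2x ... g4z
  NumericVector V0(M);
  for (int e = 0; e < M; ++e) {
    arma::mat33 D;
    int n1 = tets(e, 0) - 1;
    for (int a = 1; a < 4; ++a) {
      int na = tets(e, a) - 1;
      for (int k = 0; k < 3; ++k) D(k, a - 1) = X(na, k) - X(n1, k);
    }
    double detD = arma::det(D);
    V0[e] = detD / 6.0;
    if (!(V0[e] > 0.0)) stop("reference mesh has a non-positive tet volume");
    arma::mat33 Dinv = arma::inv(D);
    for (int k = 0; k < 3; ++k) {
      double s = 0.0;
      for (int a = 0; a < 3; ++a) {
        G(e, 3 * (a + 1) + k) = Dinv(a, k);
        s += Dinv(a, k);
      }
      G(e, k) = -s;
    }
  }
  return List::create(_["G"] = G, _["V0"] = V0);
}

// [[Rcpp::export]]
List fem_force(const NumericMatrix &Xc, const NumericMatrix &X0,
               const IntegerMatrix &tets,
               const NumericMatrix &G, const NumericVector &V0,
               const IntegerVector &mtype, const NumericMatrix &mpar,
               const LogicalVector &proj, bool want_stress = false) {
  int M = tets.nrow(), N = Xc.nrow();
  FastModel fm = make_model(Xc, tets, G, V0, mtype, mpar, proj);
  std::vector<double> uc(3 * N), fv(3 * N, 0.0);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < 3; ++k) uc[3 * n + k] = Xc(n, k) - X0(n, k);
  double SE = 0.0;
  NumericVector vm(want_stress ? M : 0);
  NumericMatrix stress(want_stress ? M : 0, 6);
  std::vector<double> vmv(want_stress ? M : 0),
      pt(want_stress ? M : 0);
  int bad = fast_forces(fm, uc.data(), fv.data(), &SE,
                        want_stress ? vmv.data() : nullptr,
                        want_stress ? pt.data() : nullptr);
  NumericMatrix force(N, 3);
  if (bad == 0) {
    for (int n = 0; n < N; ++n)
      for (int k = 0; k < 3; ++k) force(n, k) = fv[3 * n + k];
    if (want_stress) {
      int nd[4]; double F[9], tau[9];
      double par_e[7];
      for (int e = 0; e < M; ++e) {
        for (int k = 0; k < 7; ++k) par_e[k] = fm.par[k * M + e];
        def_grad_fast(fm, uc.data(), e, nd, F);
        double J, Wi, Wv;
        bool use_p = fm.projv[e] != 0;
        tau_fast(F, par_e, mtype[e], use_p, pt[e], J, tau, Wi, Wv);
        vm[e] = vmv[e];
        stress(e, 0) = tau[0] / J; stress(e, 1) = tau[4] / J;
        stress(e, 2) = tau[8] / J; stress(e, 3) = tau[1] / J;
        stress(e, 4) = tau[5] / J; stress(e, 5) = tau[2] / J;
      }
    }
  }
  return List::create(_["force"] = force, _["SE"] = SE,
                      _["vm"] = vm, _["stress"] = stress,
                      _["ok"] = bad == 0, _["bad"] = bad);
}

// local element force (12-vector) used by the FD tangent; MR elements use
// the isochoric part only (the projected volumetric stiffness is assembled
// separately), SVK elements the full force.
static bool local_force(const double *ue /*12 node-major displacements*/,
                        const MatRow &m,
                        const double *Ge /*12*/, double V0, double *f) {
  double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  for (int a = 0; a < 4; ++a) {
    const double *x = ue + 3 * a;
    const double g0 = Ge[3 * a + 0], g1 = Ge[3 * a + 1], g2 = Ge[3 * a + 2];
    F[0] += x[0] * g0; F[1] += x[0] * g1; F[2] += x[0] * g2;
    F[3] += x[1] * g0; F[4] += x[1] * g1; F[5] += x[1] * g2;
    F[6] += x[2] * g0; F[7] += x[2] * g1; F[8] += x[2] * g2;
  }
  double par_e[7] = {m.p0, m.p1, m.p2, m.p3, m.p4, m.p5, m.rho};
  double tau[9], J, Wi, Wv;
  // MR: volumetric term dropped (use_p with p = 0)
  bool use_p = (m.type == MAT_MR5);
  if (!tau_fast(F, par_e, m.type, use_p, 0.0, J, tau, Wi, Wv)) return false;
  double Fi[9];
  inv3(F, J, Fi);
  double P[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      P[3 * i + j] = tau[3 * i + 0] * Fi[3 * j + 0] +
                     tau[3 * i + 1] * Fi[3 * j + 1] +
                     tau[3 * i + 2] * Fi[3 * j + 2];
  for (int a = 0; a < 4; ++a) {
    const double g0 = Ge[3 * a + 0], g1 = Ge[3 * a + 1], g2 = Ge[3 * a + 2];
    f[3 * a + 0] = V0 * (P[0] * g0 + P[1] * g1 + P[2] * g2);
    f[3 * a + 1] = V0 * (P[3] * g0 + P[4] * g1 + P[5] * g2);
    f[3 * a + 2] = V0 * (P[6] * g0 + P[7] * g1 + P[8] * g2);
  }
  return true;
}

// Per-element 12x12 tangent by central finite differences of the local
// element force. Column-major storage (col dof * 12 + row dof), one row
// per element.
// [[Rcpp::export]]
NumericMatrix fem_tangent(const NumericMatrix &Xc, const NumericMatrix &X0,
                          const IntegerMatrix &tets,
                          const NumericMatrix &G, const NumericVector &V0,
                          const IntegerVector &mtype, const NumericMatrix &mpar) {
  int M = tets.nrow();
  NumericMatrix K(M, 144);
  double fp[12], fm_[12], xe[12], Gc[12];
  for (int e = 0; e < M; ++e) {
    MatRow m = mat_row(mtype, mpar, e);
    for (int a = 0; a < 4; ++a) {
      int n = tets(e, a) - 1;
      for (int i = 0; i < 3; ++i) xe[3 * a + i] = Xc(n, i) - X0(n, i);
    }
    double h = 1e-6 * std::cbrt(6.0 * V0[e]);
    for (int k = 0; k < 12; ++k) Gc[k] = G(e, k);
    for (int d = 0; d < 12; ++d) {
      double keep = xe[d];
      xe[d] = keep + h;
      bool ok1 = local_force(xe, m, Gc, V0[e], fp);
      xe[d] = keep - h;
      bool ok2 = local_force(xe, m, Gc, V0[e], fm_);
      xe[d] = keep;
      if (!ok1 || !ok2) stop("inverted element while forming the tangent");
      for (int r = 0; r < 12; ++r)
        K(e, d * 12 + r) = (fp[r] - fm_[r]) / (2.0 * h);
    }
  }
  return K;
}

// dv_e/dx (M x 12) and nodal patch accumulators for the projected
// volumetric stiffness  K_vol = Gv^T diag(2 WDa / V0a^2) Gv.
// [[Rcpp::export]]
List fem_vol_projection(const NumericMatrix &Xc, const NumericMatrix &X0,
                        const IntegerMatrix &tets,
                        const NumericMatrix &G, const NumericVector &V0,
                        const LogicalVector &proj, const NumericMatrix &mpar) {
  int M = tets.nrow(), N = Xc.nrow();
  NumericMatrix dv(M, 12);
  NumericVector V0a(N), va(N), WDa(N);
  for (int e = 0; e < M; ++e) {
    if (!proj[e]) continue;
    arma::mat33 F(arma::fill::eye);
    for (int a = 0; a < 4; ++a) {
      int n = tets(e, a) - 1;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          F(i, j) += (Xc(n, i) - X0(n, i)) * G(e, 3 * a + j);
    }
    double J = arma::det(F);
    arma::mat33 FinvT = arma::inv(F).t();
    for (int a = 0; a < 4; ++a) {
      int n = tets(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        double s = 0.0;
        for (int j = 0; j < 3; ++j) s += FinvT(i, j) * G(e, 3 * a + j);
        dv(e, 3 * a + i) = V0[e] * J * s;
      }
      V0a[n] += V0[e] / 4.0;
      va[n] += J * V0[e] / 4.0;
      WDa[n] += V0[e] / (4.0 * mpar(e, 5));
    }
  }
  return List::create(_["dv"] = dv, _["V0a"] = V0a, _["va"] = va,
                      _["WDa"] = WDa);
}

// follower pressure nodal forces on oriented facets (outward normals of the
// solid): traction -p n.
static void pressure_force_vec(const double *xc, const int *f1, const int *f2,
                               const int *f3, int Fn, double p, double *force) {
  for (int f = 0; f < Fn; ++f) {
    const double *a = xc + 3 * (f1[f] - 1);
    const double *b = xc + 3 * (f2[f] - 1);
    const double *c = xc + 3 * (f3[f] - 1);
    double e1x = b[0] - a[0], e1y = b[1] - a[1], e1z = b[2] - a[2];
    double e2x = c[0] - a[0], e2y = c[1] - a[1], e2z = c[2] - a[2];
    double anx = 0.5 * (e1y * e2z - e1z * e2y);
    double any_ = 0.5 * (e1z * e2x - e1x * e2z);
    double anz = 0.5 * (e1x * e2y - e1y * e2x);
    double fx = -p * anx / 3.0, fy = -p * any_ / 3.0, fz = -p * anz / 3.0;
    force[3 * (f1[f] - 1) + 0] += fx; force[3 * (f1[f] - 1) + 1] += fy;
    force[3 * (f1[f] - 1) + 2] += fz;
    force[3 * (f2[f] - 1) + 0] += fx; force[3 * (f2[f] - 1) + 1] += fy;
    force[3 * (f2[f] - 1) + 2] += fz;
    force[3 * (f3[f] - 1) + 0] += fx; force[3 * (f3[f] - 1) + 1] += fy;
    force[3 * (f3[f] - 1) + 2] += fz;
  }
}

// [[Rcpp::export]]
NumericMatrix fem_pressure_force(const NumericMatrix &Xc,
                                 const IntegerMatrix &fac, double p) {
  int N = Xc.nrow();
  std::vector<double> xc(3 * N), fv(3 * N, 0.0);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < 3; ++k) xc[3 * n + k] = Xc(n, k);
  if (fac.nrow() > 0)
    pressure_force_vec(xc.data(), &fac(0, 0), &fac(0, 1), &fac(0, 2),
                       fac.nrow(), p, fv.data());
  NumericMatrix force(N, 3);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < 3; ++k) force(n, k) = fv[3 * n + k];
  return force;
}

static inline double pulse_scale(double t, double rise, int profile) {
  if (t <= 0.0) return 0.0;
  if (t >= rise) return 1.0;
  if (profile == 1) return t / rise;
  return 0.5 * (1.0 - std::cos(M_PI * t / rise));
}

// Explicit central-difference integration with lumped mass.
// fixed: 0-based dof indices (dof = 3*(node-1) + comp) held at their initial
// value. presc_nodes get an added displacement amp*s(t) along presc_dir on
// top of u0.
// [[Rcpp::export]]
List explicit_run(const NumericMatrix &X0, const IntegerMatrix &tets,
                  const NumericMatrix &G, const NumericVector &V0,
                  const IntegerVector &mtype, const NumericMatrix &mpar,
                  const LogicalVector &proj, const NumericVector &mass,
                  double dt, int nsteps,
                  const IntegerVector &fixed,
                  const IntegerVector &presc_nodes, int presc_dir,
                  double presc_amp, double presc_rise, int presc_profile,
                  const IntegerMatrix &pres_facets, double pres_p,
                  const NumericMatrix &u0, const NumericMatrix &v0,
                  const IntegerVector &out_steps, double alpha,
                  int ledger_stride) {
  int N = X0.nrow(), M = tets.nrow();
  FastModel fmdl = make_model(X0, tets, G, V0, mtype, mpar, proj);
  std::vector<double> xc(3 * N), fint(3 * N), fpres(3 * N);
  std::vector<double> u(3 * N), v(3 * N), uprev(3 * N), x0(3 * N);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < 3; ++k) {
      x0[3 * n + k] = X0(n, k);
      u[3 * n + k] = u0(n, k);
      v[3 * n + k] = v0(n, k);
      xc[3 * n + k] = X0(n, k) + u0(n, k);
    }
  std::vector<char> is_fixed(3 * N, 0), is_presc(3 * N, 0);
  for (int i = 0; i < fixed.size(); ++i) is_fixed[fixed[i]] = 1;
  std::vector<int> pdof(presc_nodes.size());
  std::vector<double> ubase(presc_nodes.size());
  for (int i = 0; i < presc_nodes.size(); ++i) {
    pdof[i] = 3 * (presc_nodes[i] - 1) + presc_dir;
    is_presc[pdof[i]] = 1;
    ubase[i] = u[pdof[i]];
  }
  const int *pf1 = nullptr, *pf2 = nullptr, *pf3 = nullptr;
  int nfac = pres_facets.nrow();
  if (nfac > 0) {
    pf1 = &pres_facets(0, 0); pf2 = &pres_facets(0, 1); pf3 = &pres_facets(0, 2);
  }
  int nout = out_steps.size();
  List U_out(nout), vm_out(nout);
  NumericVector t_out(nout);
  int next_out = 0;
  int nled = nsteps / ledger_stride + 2;
  NumericMatrix ledger(nled, 4);
  int iled = 0;
  double W_ext = 0.0;
  std::vector<double> fp_prev(3 * N, 0.0), du(3 * N, 0.0), vm_buf(M);
  int status = 0, bad = 0;
  bool first = true;

  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    std::fill(fint.begin(), fint.end(), 0.0);
    std::fill(fpres.begin(), fpres.end(), 0.0);
    double SE = 0.0;
    bool want_vm = (next_out < nout && out_steps[next_out] == step);
    bad = fast_forces(fmdl, u.data(), fint.data(), &SE,
                      want_vm ? vm_buf.data() : nullptr, nullptr);
    if (bad != 0) { status = 3; break; }
    if (nfac > 0)
      pressure_force_vec(xc.data(), pf1, pf2, pf3, nfac, pres_p, fpres.data());
    if (want_vm) {
      NumericMatrix Usnap(N, 3);
      for (int n = 0; n < N; ++n)
        for (int k = 0; k < 3; ++k) Usnap(n, k) = u[3 * n + k];
      U_out[next_out] = Usnap;
      vm_out[next_out] = NumericVector(vm_buf.begin(), vm_buf.end());
      t_out[next_out] = t;
      ++next_out;
    }

    // accelerations and velocity update
    double KE = 0.0;
    std::vector<double> R(3 * N, 0.0);
    double s0 = pulse_scale(t, presc_rise, presc_profile);
    double sp = pulse_scale(t + dt, presc_rise, presc_profile);
    double sm = pulse_scale(t - dt, presc_rise, presc_profile);
    for (int n = 0; n < N; ++n) {
      for (int k = 0; k < 3; ++k) {
        int d = 3 * n + k;
        double ftot = fpres[d] - fint[d] - alpha * mass[n] * v[d];
        if (is_fixed[d]) {
          R[d] = -ftot;
          v[d] = 0.0;
          continue;
        }
        if (is_presc[d]) {
          double acc = presc_amp * (sp - 2.0 * s0 + sm) / (dt * dt);
          R[d] = mass[n] * acc - ftot;
          double vel = presc_amp * (sp - sm) / (2.0 * dt);
          KE += 0.5 * mass[n] * vel * vel;
          continue; // u set below from the profile
        }
        double a = ftot / mass[n];
        double vmid = v[d] + dt * a;
        KE += 0.5 * mass[n] * 0.25 * (v[d] + vmid) * (v[d] + vmid);
        v[d] = vmid;
      }
    }
    // external work: trapezoid over the step just completed
    if (!first) {
      double dW = 0.0;
      for (int d = 0; d < 3 * N; ++d) {
        double f_now = fpres[d] + ((is_presc[d] || is_fixed[d]) ? R[d] : 0.0);
        dW += 0.5 * (f_now + fp_prev[d]) * du[d];
      }
      W_ext += dW;
    }
    for (int d = 0; d < 3 * N; ++d)
      fp_prev[d] = fpres[d] + ((is_presc[d] || is_fixed[d]) ? R[d] : 0.0);
    first = false;

    if (step % ledger_stride == 0 && iled < nled) {
      ledger(iled, 0) = t; ledger(iled, 1) = W_ext;
      ledger(iled, 2) = KE; ledger(iled, 3) = SE;
      ++iled;
      if (!std::isfinite(KE) || !std::isfinite(SE)) { status = 2; break; }
      double ref = std::max(std::abs(W_ext), 1e-9);
      if (step > 10 && KE > 10.0 * ref && KE > 1e-6) { status = 1; break; }
    }
    if (step == nsteps) break;

    // displacement update
    for (int d = 0; d < 3 * N; ++d) {
      uprev[d] = u[d];
      if (!is_fixed[d] && !is_presc[d]) u[d] += dt * v[d];
    }
    for (size_t i = 0; i < pdof.size(); ++i) {
      int d = pdof[i];
      double unew = ubase[i] + presc_amp * sp;
      v[d] = (unew - u[d]) / dt;
      u[d] = unew;
    }
    for (int d = 0; d < 3 * N; ++d) {
      du[d] = u[d] - uprev[d];
      xc[d] = x0[d] + u[d];
    }
  }

  return List::create(_["times"] = t_out, _["U"] = U_out, _["vm"] = vm_out,
                      _["ledger"] = ledger, _["n_ledger"] = iled,
                      _["status"] = status, _["bad"] = bad,
                      _["n_out"] = next_out);
}
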