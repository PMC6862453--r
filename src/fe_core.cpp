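// Matrix-free voxel FE core: 8-node trilinear hexahedra on a regular grid,
// isotropic linear elasticity, Jacobi-preconditioned conjugate gradients.
// All elements share the edge length h; per-element Young's modulus scales a
// per-Poisson-group unit stiffness matrix (K is linear in E and in h).
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// local node order: (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1)
static const double SG[8][3] = {
  {-1,-1,-1},{1,-1,-1},{1,1,-1},{-1,1,-1},{-1,-1,1},{1,-1,1},{1,1,1},{-1,1,1}};

static void shape_grad(double xi, double eta, double zeta, double h,
                       double dN[8][3]) {
  const double j = 2.0 / h;  // d(xi)/dx for a cube of edge h
  for (int i = 0; i < 8; ++i) {
    const double xs = SG[i][0], ys = SG[i][1], zs = SG[i][2];
    dN[i][0] = 0.125 * xs * (1.0 + eta * ys) * (1.0 + zeta * zs) * j;
    dN[i][1] = 0.125 * ys * (1.0 + xi * xs) * (1.0 + zeta * zs) * j;
    dN[i][2] = 0.125 * zs * (1.0 + xi * xs) * (1.0 + eta * ys) * j;
  }
}

// strain-displacement matrix at (xi,eta,zeta); rows exx eyy ezz gxy gyz gxz
static void bmat(double xi, double eta, double zeta, double h, double B[6][24]) {
  double dN[8][3];
  shape_grad(xi, eta, zeta, h, dN);
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 24; ++c) B[r][c] = 0.0;
  for (int i = 0; i < 8; ++i) {
    const int cx = 3 * i, cy = 3 * i + 1, cz = 3 * i + 2;
    B[0][cx] = dN[i][0];
    B[1][cy] = dN[i][1];
    B[2][cz] = dN[i][2];
    B[3][cx] = dN[i][1]; B[3][cy] = dN[i][0];
    B[4][cy] = dN[i][2]; B[4][cz] = dN[i][1];
    B[5][cx] = dN[i][2]; B[5][cz] = dN[i][0];
  }
}

static void dmat(double E, double nu, double D[6][6]) {
  const double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  const double mu = E / (2.0 * (1.0 + nu));
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 6; ++c) D[r][c] = 0.0;
  for (int r = 0; r < 3; ++r) {
    for (int c = 0; c < 3; ++c) D[r][c] = lam;
    D[r][r] = lam + 2.0 * mu;
  }
  D[3][3] = D[4][4] = D[5][5] = mu;
}

// [[Rcpp::export]]
NumericMatrix hex_khat_cpp(double nu, double h) {
  NumericMatrix K(24, 24);
  const double g = 1.0 / std::sqrt(3.0);
  double B[6][24], D[6][6], DB[6][24];
  dmat(1.0, nu, D);
  const double detw = (h / 2.0) * (h / 2.0) * (h / 2.0);  // detJ * weight(=1)
  for (int gx = 0; gx < 2; ++gx)
    for (int gy = 0; gy < 2; ++gy)
      for (int gz = 0; gz < 2; ++gz) {
        const double xi = (gx ? g : -g), eta = (gy ? g : -g), zeta = (gz ? g : -g);
        bmat(xi, eta, zeta, h, B);
        for (int r = 0; r < 6; ++r)
          for (int c = 0; c < 24; ++c) {
            double s = 0.0;
            for (int k = 0; k < 6; ++k) s += D[r][k] * B[k][c];
            DB[r][c] = s;
          }
        for (int r = 0; r < 24; ++r)
          for (int c = 0; c < 24; ++c) {
            double s = 0.0;
            for (int k = 0; k < 6; ++k) s += B[k][r] * DB[k][c];
            K(r, c) += s * detw;
          }
      }
  return K;
}

struct KOp {
  const int nelem, nnodes;
  const int* grp;           // per-element Poisson-group index, 0-based
  const double* escale;     // per-element Young's modulus (multiplies unit-E K)
  std::vector<int> connT;   // element-major 8-node lists for contiguous access
  std::vector<std::vector<double> > khat;  // per-group 24x24 row-major

  KOp(const IntegerMatrix& conn_, const IntegerVector& grp_,
      const NumericVector& escale_, const List& khats_, int nnodes_)
      : nelem(conn_.nrow()), nnodes(nnodes_), grp(&grp_[0]),
        escale(&escale_[0]) {
    connT.resize((size_t)nelem * 8);
    for (int e = 0; e < nelem; ++e)
      for (int i = 0; i < 8; ++i) connT[(size_t)e * 8 + i] = conn_(e, i);
    for (int g = 0; g < khats_.size(); ++g) {
      NumericMatrix K = khats_[g];
      std::vector<double> flat(576);
      for (int r = 0; r < 24; ++r)
        for (int c = 0; c < 24; ++c) flat[r * 24 + c] = K(r, c);
      khat.push_back(flat);
    }
  }

  // y += K x   (y must be zeroed by caller)
  void apply(const double* x, double* y) const {
    double ue[24], fe[24];
    for (int e = 0; e < nelem; ++e) {
      const double Ee = escale[e];
      const double* K = &khat[grp[e]][0];
      const int* cn = &connT[(size_t)e * 8];
      for (int i = 0; i < 8; ++i) {
        const int n3 = 3 * cn[i];
        ue[3 * i] = x[n3]; ue[3 * i + 1] = x[n3 + 1]; ue[3 * i + 2] = x[n3 + 2];
      }
      for (int r = 0; r < 24; ++r) {
        double s = 0.0;
        const double* Kr = K + r * 24;
        for (int c = 0; c < 24; ++c) s += Kr[c] * ue[c];
        fe[r] = Ee * s;
      }
      for (int i = 0; i < 8; ++i) {
        const int n3 = 3 * cn[i];
        y[n3] += fe[3 * i]; y[n3 + 1] += fe[3 * i + 1]; y[n3 + 2] += fe[3 * i + 2];
      }
    }
  }

  void diagonal(double* d) const {
    for (int i = 0; i < 3 * nnodes; ++i) d[i] = 0.0;
    for (int e = 0; e < nelem; ++e) {
      const double Ee = escale[e];
      const double* K = &khat[grp[e]][0];
      const int* cn = &connT[(size_t)e * 8];
      for (int i = 0; i < 8; ++i) {
        const int n = cn[i];
        for (int a = 0; a < 3; ++a) {
          const int l = 3 * i + a;
          d[3 * n + a] += Ee * K[l * 24 + l];
        }
      }
    }
  }
};

// [[Rcpp::export]]
NumericVector fe_apply_k_cpp(const IntegerMatrix& conn, const IntegerVector& grp,
                             const NumericVector& escale, const List& khats,
                             int nnodes, const NumericVector& u) {
  KOp op(conn, grp, escale, khats, nnodes);
  NumericVector f(3 * nnodes);
  op.apply(&u[0], &f[0]);
  return f;
}

// Solve K u = 0 subject to Dirichlet values on `fixed` dofs (so the free part
// feels b = -K u_fixed). x0 optionally warm-starts the free dofs.
// [[Rcpp::export]]
List fe_cg_solve_cpp(const IntegerMatrix& conn, const IntegerVector& grp,
                     const NumericVector& escale, const List& khats, int nnodes,
                     const LogicalVector& fixed, const NumericVector& fixedval,
                     Nullable<NumericVector> x0, double tol, int maxit) {
  const int ndof = 3 * nnodes;
  KOp op(conn, grp, escale, khats, nnodes);

  std::vector<double> uc(ndof, 0.0), b(ndof, 0.0);
  for (int i = 0; i < ndof; ++i)
    if (fixed[i]) uc[i] = fixedval[i];
  op.apply(&uc[0], &b[0]);
  double bnorm = 0.0;
  for (int i = 0; i < ndof; ++i) {
    b[i] = fixed[i] ? 0.0 : -b[i];
    bnorm += b[i] * b[i];
  }
  bnorm = std::sqrt(bnorm);

  NumericVector u(ndof);
  if (bnorm == 0.0) {  // no load: solution is the prescribed field only
    for (int i = 0; i < ndof; ++i) u[i] = uc[i];
    return List::create(_["u"] = u, _["iterations"] = 0, _["relres"] = 0.0,
                        _["converged"] = true);
  }

  std::vector<double> diag(ndof);
  op.diagonal(&diag[0]);
  for (int i = 0; i < ndof; ++i)
    if (fixed[i] || diag[i] <= 0.0) diag[i] = 1.0;

  std::vector<double> x(ndof, 0.0), r(ndof), z(ndof), p(ndof), q(ndof);
  if (x0.isNotNull()) {
    NumericVector xx(x0);
    for (int i = 0; i < ndof; ++i) x[i] = fixed[i] ? 0.0 : xx[i];
  }
  // r = b - A x
  std::fill(q.begin(), q.end(), 0.0);
  op.apply(&x[0], &q[0]);
  for (int i = 0; i < ndof; ++i) r[i] = fixed[i] ? 0.0 : b[i] - q[i];

  double rz = 0.0;
  for (int i = 0; i < ndof; ++i) {
    z[i] = r[i] / diag[i];
    rz += r[i] * z[i];
  }
  p = z;
  double relres = 0.0;
  {
    double rn = 0.0;
    for (int i = 0; i < ndof; ++i) rn += r[i] * r[i];
    relres = std::sqrt(rn) / bnorm;
  }
  int it = 0;
  bool conv = relres <= tol;
  while (!conv && it < maxit) {
    std::fill(q.begin(), q.end(), 0.0);
    op.apply(&p[0], &q[0]);
    double pq = 0.0;
    for (int i = 0; i < ndof; ++i) {
      if (fixed[i]) q[i] = 0.0;
      pq += p[i] * q[i];
    }
    const double alpha = rz / pq;
    double rn = 0.0;
    for (int i = 0; i < ndof; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * q[i];
      rn += r[i] * r[i];
    }
    ++it;
    relres = std::sqrt(rn) / bnorm;
    if (relres <= tol) { conv = true; break; }
    double rznew = 0.0;
    for (int i = 0; i < ndof; ++i) {
      z[i] = r[i] / diag[i];
      rznew += r[i] * z[i];
    }
    const double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < ndof; ++i) p[i] = z[i] + beta * p[i];
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < ndof; ++i) u[i] = fixed[i] ? uc[i] : x[i];
  return List::create(_["u"] = u, _["iterations"] = it, _["relres"] = relres,
                      _["converged"] = conv);
}

// Per-element centroid strain/stress summaries plus the exact (2x2x2 Gauss)
// element strain energy 0.5 u_e' K_e u_e.
// Columns: exx eyy ezz gxy gyz gxz sxx syy szz sxy syz sxz vm sed ees energy
// [[Rcpp::export]]
NumericMatrix element_fields_cpp(const IntegerMatrix& conn, const IntegerVector& grp,
                                 const NumericVector& escale, const NumericVector& nus,
                                 const List& khats, double h, const NumericVector& u) {
  const int nelem = conn.nrow();
  NumericMatrix out(nelem, 16);
  std::vector<std::vector<double> > Ks;
  for (int g = 0; g < khats.size(); ++g) {
    NumericMatrix K = khats[g];
    std::vector<double> flat(576);
    for (int r = 0; r < 24; ++r)
      for (int c = 0; c < 24; ++c) flat[r * 24 + c] = K(r, c);
    Ks.push_back(flat);
  }
  double B[6][24];
  bmat(0.0, 0.0, 0.0, h, B);
  std::vector<std::vector<double> > Ds;
  for (int g = 0; g < nus.size(); ++g) {
    double D[6][6];
    dmat(1.0, nus[g], D);
    std::vector<double> flat(36);
    for (int r = 0; r < 6; ++r)
      for (int c = 0; c < 6; ++c) flat[r * 6 + c] = D[r][c];
    Ds.push_back(flat);
  }
  double ue[24], eps[6], sig[6];
  for (int e = 0; e < nelem; ++e) {
    const double Ee = escale[e];
    const double* D = &Ds[grp[e]][0];
    for (int i = 0; i < 8; ++i) {
      const int n = conn(e, i);
      ue[3 * i] = u[3 * n]; ue[3 * i + 1] = u[3 * n + 1]; ue[3 * i + 2] = u[3 * n + 2];
    }
    for (int r = 0; r < 6; ++r) {
      double s = 0.0;
      for (int c = 0; c < 24; ++c) s += B[r][c] * ue[c];
      eps[r] = s;
    }
    for (int r = 0; r < 6; ++r) {
      double s = 0.0;
      for (int c = 0; c < 6; ++c) s += D[r * 6 + c] * eps[c];
      sig[r] = Ee * s;
    }
    const double vm = std::sqrt(0.5 * ((sig[0] - sig[1]) * (sig[0] - sig[1]) +
                                       (sig[1] - sig[2]) * (sig[1] - sig[2]) +
                                       (sig[2] - sig[0]) * (sig[2] - sig[0])) +
                                3.0 * (sig[3] * sig[3] + sig[4] * sig[4] +
                                       sig[5] * sig[5]));
    double sed = 0.0;
    for (int r = 0; r < 6; ++r) sed += 0.5 * sig[r] * eps[r];
    if (sed < 0.0) sed = 0.0;  // guard round-off
    const double ees = std::sqrt(2.0 * sed / Ee);
    for (int r = 0; r < 6; ++r) out(e, r) = eps[r];
    for (int r = 0; r < 6; ++r) out(e, 6 + r) = sig[r];
    out(e, 12) = vm;
    out(e, 13) = sed;
    out(e, 14) = ees;
    const double* K = &Ks[grp[e]][0];
    double en = 0.0;
    for (int r = 0; r < 24; ++r) {
      double s = 0.0;
      const double* Kr = K + r * 24;
      for (int c = 0; c < 24; ++c) s += Kr[c] * ue[c];
      en += ue[r] * s;
    }
    out(e, 15) = 0.5 * Ee * en;
  }
  return out;
}

// Axial (z) internal-force contribution of each element phase to a node set
// (a constrained plane). Returns per-phase sums, phases 0..nphase-1.
// [[Rcpp::export]]
NumericVector plane_phase_axial_cpp(const IntegerMatrix& conn, const IntegerVector& grp,
                                    const NumericVector& escale, const List& khats,
                                    int nnodes, const NumericVector& u,
                                    const IntegerVector& phase, int nphase,
                                    const LogicalVector& inplane) {
  KOp op(conn, grp, escale, khats, nnodes);
  NumericVector out(nphase);
  double ue[24], fe[24];
  const int nelem = conn.nrow();
  for (int e = 0; e < nelem; ++e) {
    bool touches = false;
    for (int i = 0; i < 8; ++i)
      if (inplane[conn(e, i)]) { touches = true; break; }
    if (!touches) continue;
    const double Ee = op.escale[e];
    const double* K = &op.khat[op.grp[e]][0];
    for (int i = 0; i < 8; ++i) {
      const int n = conn(e, i);
      ue[3 * i] = u[3 * n]; ue[3 * i + 1] = u[3 * n + 1]; ue[3 * i + 2] = u[3 * n + 2];
    }
    for (int r = 0; r < 24; ++r) {
      double s = 0.0;
      const double* Kr = K + r * 24;
      for (int c = 0; c < 24; ++c) s += Kr[c] * ue[c];
      fe[r] = Ee * s;
    }
    for (int i = 0; i < 8; ++i)
      if (inplane[conn(e, i)]) out[phase[e]] += fe[3 * i + 2];
  }
  return out;
}

// 6-connected component labels on a voxel grid; 0 where mask is FALSE.
// [[Rcpp::export]]
IntegerVector label_components6_cpp(const LogicalVector& mask, int nx, int ny, int nz) {
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<int> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.push_back((int)s);
    lab[s] = cur;
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        const int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        const int w = ii + nx * (jj + ny * kk);
        if (mask[w] && lab[w] == 0) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}
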