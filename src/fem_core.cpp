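// Plane-strain hyperelastic element assembly.
//
// Quadratic (P2) displacement triangles with affine geometry (midside nodes
// at edge midpoints), linear continuous (P1) pressure on corner nodes for
// incompressible regions (Taylor-Hood), and a displacement-only compressible
// Neo-Hookean law for the buffer / penalty paths. Moduli in kPa, lengths in
// mm, so stresses are kPa and forces kPa*mm (per unit out-of-plane depth).
//
// Strain energy conventions (paper form W = C (I1 - 3) => mu = 2C):
//   incompressible: P = mu (F - J F^{-T}) - p J F^{-T},  constraint J = 1.
//     The mu J F^{-T} part (a pure hydrostatic term on the constraint
//     manifold) is absorbed into the stress rather than the multiplier, so
//     p is the hydrostatic perturbation: zero at rest and continuous
//     across material interfaces, which a continuous pressure
//     interpolation can represent. (With P = mu F - p J F^{-T} the rest
//     state needs p = mu, which jumps at interfaces and pollutes the
//     displacement field near them by O(h) at any load.)
//   compressible:   W = mu/2 (I1 - 3) - mu ln Jb + lambda/2 (ln Jb)^2 with
//     Jb the element-mean dilatation (B-bar / mean-dilatation treatment:
//     pointwise volumetric terms lock quadratic triangles to a saturated
//     ~2% error at near-incompressible penalty moduli)

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

// 6-point degree-4 Dunavant rule, weights sum to 1
const double QA1 = 0.445948490915965, QB1 = 0.108103018168070, QW1 = 0.223381589678011;
const double QA2 = 0.091576213509771, QB2 = 0.816847572980459, QW2 = 0.109951743655322;

struct QP { double L1, L2, L3, w; };

static const QP qps[6] = {
  {QB1, QA1, QA1, QW1}, {QA1, QB1, QA1, QW1}, {QA1, QA1, QB1, QW1},
  {QB2, QA2, QA2, QW2}, {QA2, QB2, QA2, QW2}, {QA2, QA2, QB2, QW2}
};

inline void shape_deriv(double L1, double L2, double L3, double dN[6][2]) {
  dN[0][0] = 4 * L1 - 1;      dN[0][1] = 0;
  dN[1][0] = 0;               dN[1][1] = 4 * L2 - 1;
  dN[2][0] = -(4 * L3 - 1);   dN[2][1] = -(4 * L3 - 1);
  dN[3][0] = 4 * L2;          dN[3][1] = 4 * L1;
  dN[4][0] = -4 * L2;         dN[4][1] = 4 * (L3 - L2);
  dN[5][0] = 4 * (L3 - L1);   dN[5][1] = -4 * L1;
}

} // namespace

// [[Rcpp::export(name = ".fem_assemble")]]
List fem_assemble(const arma::mat& nodes, const arma::mat& U,
                  const arma::imat& tri, const arma::vec& mu,
                  const arma::vec& lam, const arma::ivec& incomp,
                  const arma::ivec& pidx, const arma::vec& pvals,
                  int n_pdof) {
  const int n = nodes.n_rows, m = tri.n_rows;
  const int ndof = 2 * n + n_pdof;

  // worst case per element: 12x12 + 2 * 12x3
  const size_t cap = (size_t)m * (144 + 72);
  std::vector<int> ti; ti.reserve(cap);
  std::vector<int> tj; tj.reserve(cap);
  std::vector<double> tv; tv.reserve(cap);
  arma::vec resid(ndof, arma::fill::zeros);
  bool bad = false;

  for (int e = 0; e < m && !bad; ++e) {
    int id[6];
    for (int a = 0; a < 6; ++a) id[a] = tri(e, a) - 1;
    const double x1 = nodes(id[0], 0), y1 = nodes(id[0], 1);
    const double x2 = nodes(id[1], 0), y2 = nodes(id[1], 1);
    const double x3 = nodes(id[2], 0), y3 = nodes(id[2], 1);
    arma::mat22 J;
    J(0, 0) = x1 - x3; J(0, 1) = x2 - x3;
    J(1, 0) = y1 - y3; J(1, 1) = y2 - y3;
    const double detJ = J(0, 0) * J(1, 1) - J(0, 1) * J(1, 0);
    if (detJ <= 0) { bad = true; break; }
    const double Ae = 0.5 * detJ;
    arma::mat22 Jit;  // inverse transpose of J
    Jit(0, 0) =  J(1, 1) / detJ; Jit(0, 1) = -J(1, 0) / detJ;
    Jit(1, 0) = -J(0, 1) / detJ; Jit(1, 1) =  J(0, 0) / detJ;

    const double mue = mu[e], lame = lam[e];
    const bool inc = incomp[e] != 0;

    double Ke[12][12] = {{0}};
    double Re[12] = {0};
    double Kup[12][3] = {{0}};
    double Rp[3] = {0};

    // per-quadrature-point state (kept for the mean-dilatation pass)
    double qw[6], qJ[6], qBdN[6][6][2];
    double Jbar = 0;        // element-mean dilatation
    double gvec[12] = {0};  // A * dJbar/du

    for (int q = 0; q < 6; ++q) {
      double dNl[6][2];
      shape_deriv(qps[q].L1, qps[q].L2, qps[q].L3, dNl);
      double dN[6][2];  // w.r.t. x
      for (int a = 0; a < 6; ++a) {
        dN[a][0] = Jit(0, 0) * dNl[a][0] + Jit(0, 1) * dNl[a][1];
        dN[a][1] = Jit(1, 0) * dNl[a][0] + Jit(1, 1) * dNl[a][1];
      }
      // deformation gradient
      double F[2][2] = {{1, 0}, {0, 1}};
      for (int a = 0; a < 6; ++a) {
        const double ux = U(id[a], 0), uy = U(id[a], 1);
        F[0][0] += ux * dN[a][0]; F[0][1] += ux * dN[a][1];
        F[1][0] += uy * dN[a][0]; F[1][1] += uy * dN[a][1];
      }
      const double Jd = F[0][0] * F[1][1] - F[0][1] * F[1][0];
      if (Jd <= 0) { bad = true; break; }
      // B = F^{-T}
      double B[2][2];
      B[0][0] =  F[1][1] / Jd; B[0][1] = -F[1][0] / Jd;
      B[1][0] = -F[0][1] / Jd; B[1][1] =  F[0][0] / Jd;

      const double w = qps[q].w * Ae;
      const double Lc[3] = {qps[q].L1, qps[q].L2, qps[q].L3};

      double BdN[6][2];
      for (int a = 0; a < 6; ++a) {
        BdN[a][0] = B[0][0] * dN[a][0] + B[0][1] * dN[a][1];
        BdN[a][1] = B[1][0] * dN[a][0] + B[1][1] * dN[a][1];
      }

      qw[q] = w; qJ[q] = Jd;
      for (int a = 0; a < 6; ++a) {
        qBdN[q][a][0] = BdN[a][0];
        qBdN[q][a][1] = BdN[a][1];
      }
      if (!inc) {
        Jbar += w * Jd / Ae;
        for (int a = 0; a < 6; ++a) {
          gvec[2 * a]     += w * Jd * BdN[a][0];
          gvec[2 * a + 1] += w * Jd * BdN[a][1];
        }
      }

      double pq = 0, c_bb = 0, c_bbT = 0;  // coefficients of Bik Bjl and Bil Bjk
      double P[2][2] = {{0, 0}, {0, 0}};
      if (inc) {
        for (int c = 0; c < 3; ++c) pq += Lc[c] * pvals[pidx[id[c]] - 1];
        const double qh = (mue + pq) * Jd;
        P[0][0] = mue * F[0][0] - qh * B[0][0];
        P[0][1] = mue * F[0][1] - qh * B[0][1];
        P[1][0] = mue * F[1][0] - qh * B[1][0];
        P[1][1] = mue * F[1][1] - qh * B[1][1];
        c_bb  = -qh;
        c_bbT = qh;
      } else {
        // isochoric part only; volumetric terms are added element-wise
        P[0][0] = mue * F[0][0];
        P[0][1] = mue * F[0][1];
        P[1][0] = mue * F[1][0];
        P[1][1] = mue * F[1][1];
      }

      for (int a = 0; a < 6; ++a) {
        Re[2 * a]     += w * (P[0][0] * dN[a][0] + P[0][1] * dN[a][1]);
        Re[2 * a + 1] += w * (P[1][0] * dN[a][0] + P[1][1] * dN[a][1]);
      }
      for (int a = 0; a < 6; ++a) {
        for (int b = 0; b < 6; ++b) {
          const double dd = dN[a][0] * dN[b][0] + dN[a][1] * dN[b][1];
          for (int i = 0; i < 2; ++i)
            for (int j = 0; j < 2; ++j) {
              double v = (i == j ? mue * dd : 0.0);
              v += c_bb  * BdN[a][i] * BdN[b][j];
              v += c_bbT * BdN[b][i] * BdN[a][j];
              Ke[2 * a + i][2 * b + j] += w * v;
            }
        }
      }
      if (inc) {
        for (int a = 0; a < 6; ++a)
          for (int i = 0; i < 2; ++i)
            for (int c = 0; c < 3; ++c)
              Kup[2 * a + i][c] += w * (-Jd * BdN[a][i] * Lc[c]);
        for (int c = 0; c < 3; ++c)
          Rp[c] += w * (-(Jd - 1.0) * Lc[c]);
      }
    }
    if (bad) break;

    if (!inc) {
      // mean-dilatation volumetric terms:
      //   W_vol = A [ -mu ln(Jbar) + lambda/2 ln(Jbar)^2 ],  g = A dJbar/du
      const double lnJb = std::log(Jbar);
      const double c1 = (lame * lnJb - mue) / Jbar;        // dW_vol/(A dJbar)
      const double c2 = (lame * (1 - lnJb) + mue) / (Jbar * Jbar);
      for (int a = 0; a < 12; ++a) Re[a] += c1 * gvec[a];
      for (int a = 0; a < 12; ++a)
        for (int b = 0; b < 12; ++b)
          Ke[a][b] += (c2 / Ae) * gvec[a] * gvec[b];
      for (int q = 0; q < 6; ++q) {
        const double wj = qw[q] * qJ[q] * c1;
        for (int a = 0; a < 6; ++a)
          for (int b = 0; b < 6; ++b)
            for (int i = 0; i < 2; ++i)
              for (int j = 0; j < 2; ++j)
                Ke[2 * a + i][2 * b + j] += wj *
                  (qBdN[q][a][i] * qBdN[q][b][j] -
                   qBdN[q][b][i] * qBdN[q][a][j]);
      }
    }

    int gd[12];
    for (int a = 0; a < 6; ++a) {
      gd[2 * a] = 2 * id[a];          // 0-based ux dof
      gd[2 * a + 1] = 2 * id[a] + 1;  // uy
    }
    for (int a = 0; a < 12; ++a) {
      resid[gd[a]] += Re[a];
      for (int b = 0; b < 12; ++b)
        if (Ke[a][b] != 0) {
          ti.push_back(gd[a] + 1); tj.push_back(gd[b] + 1); tv.push_back(Ke[a][b]);
        }
    }
    if (inc) {
      for (int c = 0; c < 3; ++c) {
        const int pc = 2 * n + pidx[id[c]] - 1;  // 0-based
        resid[pc] += Rp[c];
        for (int a = 0; a < 12; ++a)
          if (Kup[a][c] != 0) {
            ti.push_back(gd[a] + 1); tj.push_back(pc + 1); tv.push_back(Kup[a][c]);
            ti.push_back(pc + 1); tj.push_back(gd[a] + 1); tv.push_back(Kup[a][c]);
          }
      }
    }
  }

  return List::create(_["i"] = ti, _["j"] = tj, _["v"] = tv,
                      _["resid"] = resid, _["ok"] = !bad);
}

// Follower pressure on quadratic lumen boundary edges (a, mid, b ordered
// counter-clockwise around the lumen). Returns the external force vector f
// (to be subtracted from the residual) and load-stiffness triplets (to be
// added to the tangent).
// [[Rcpp::export(name = ".follower_load")]]
List follower_load(const arma::mat& nodes, const arma::mat& U,
                   const arma::imat& edges, double pressure, int ndof) {
  const int ne = edges.n_rows;
  const double gx[3] = {-std::sqrt(3.0 / 5.0), 0.0, std::sqrt(3.0 / 5.0)};
  const double gw[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};

  std::vector<int> ti, tj; std::vector<double> tv;
  ti.reserve((size_t)ne * 36); tj.reserve((size_t)ne * 36); tv.reserve((size_t)ne * 36);
  arma::vec f(ndof, arma::fill::zeros);

  for (int e = 0; e < ne; ++e) {
    const int id[3] = {(int)edges(e, 0) - 1, (int)edges(e, 1) - 1, (int)edges(e, 2) - 1};
    double X[3], Y[3];
    for (int a = 0; a < 3; ++a) {
      X[a] = nodes(id[a], 0) + U(id[a], 0);
      Y[a] = nodes(id[a], 1) + U(id[a], 1);
    }
    for (int q = 0; q < 3; ++q) {
      const double xi = gx[q];
      // shape order along the edge: a (xi=-1), mid (0), b (+1)
      const double N[3]  = {0.5 * xi * (xi - 1), 1 - xi * xi, 0.5 * xi * (xi + 1)};
      const double dN[3] = {xi - 0.5, -2 * xi, xi + 0.5};
      double tx = 0, ty = 0;
      for (int a = 0; a < 3; ++a) { tx += dN[a] * X[a]; ty += dN[a] * Y[a]; }
      const double w = gw[q] * pressure;
      for (int a = 0; a < 3; ++a) {
        // outward-from-lumen normal is to the right of the CCW tangent
        f[2 * id[a]]     += w * N[a] * ty;
        f[2 * id[a] + 1] += w * N[a] * (-tx);
        for (int b = 0; b < 3; ++b) {
          // K += -df/du
          ti.push_back(2 * id[a] + 1); tj.push_back(2 * id[b] + 2);
          tv.push_back(-w * N[a] * dN[b]);
          ti.push_back(2 * id[a] + 2); tj.push_back(2 * id[b] + 1);
          tv.push_back(w * N[a] * dN[b]);
        }
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["v"] = tv, _["f"] = f);
}

// Quadratic interpolation of a nodal field at barycentric coordinates.
// [[Rcpp::export(name = ".p2_interp")]]
arma::mat p2_interp(const arma::mat& vals, const arma::imat& tri,
                    const arma::ivec& elem, const arma::mat& bary) {
  const int np = elem.n_elem, nc = vals.n_cols;
  arma::mat out(np, nc, arma::fill::zeros);
  for (int p = 0; p < np; ++p) {
    const int e = elem[p] - 1;
    const double L1 = bary(p, 0), L2 = bary(p, 1), L3 = bary(p, 2);
    const double N[6] = {L1 * (2 * L1 - 1), L2 * (2 * L2 - 1), L3 * (2 * L3 - 1),
                         4 * L1 * L2, 4 * L2 * L3, 4 * L3 * L1};
    for (int a = 0; a < 6; ++a) {
      const int nd = tri(e, a) - 1;
      for (int c = 0; c < nc; ++c) out(p, c) += N[a] * vals(nd, c);
    }
  }
  return out;
}
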