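// Plane-strain Neo-Hookean assembly on 6-node (quadratic) triangles.
// Units: lengths mm, moduli kPa (= mN/mm^2), body force mN/mm^3,
// pressure kPa.  Out-of-plane stretch is 1, so J = det(F2x2) and
// I1 = tr(F^T F) + 1.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// quadrature: 3 interior points, weights 1/6 on the reference triangle
static const double QP[3][2] = {{1.0 / 6, 1.0 / 6}, {2.0 / 3, 1.0 / 6}, {1.0 / 6, 2.0 / 3}};
static const double QW = 1.0 / 6;

static void shape_p2(double xi, double eta, double N[6], double dN[6][2]) {
  double l1 = 1.0 - xi - eta, l2 = xi, l3 = eta;
  N[0] = l1 * (2 * l1 - 1); N[1] = l2 * (2 * l2 - 1); N[2] = l3 * (2 * l3 - 1);
  N[3] = 4 * l1 * l2; N[4] = 4 * l2 * l3; N[5] = 4 * l3 * l1;
  dN[0][0] = -(4 * l1 - 1); dN[0][1] = -(4 * l1 - 1);
  dN[1][0] = 4 * l2 - 1;    dN[1][1] = 0.0;
  dN[2][0] = 0.0;           dN[2][1] = 4 * l3 - 1;
  dN[3][0] = 4 * (l1 - l2); dN[3][1] = -4 * l2;
  dN[4][0] = 4 * l3;        dN[4][1] = 4 * l2;
  dN[5][0] = -4 * l3;       dN[5][1] = 4 * (l1 - l3);
}

// first Piola stress and (optionally) material tangent A[i][J][k][L]
static void nh_stress(const arma::mat22& F, double mu, double Kb,
                      arma::mat22& P, double A[2][2][2][2], bool want_A,
                      double* Wout) {
  double J = F(0, 0) * F(1, 1) - F(0, 1) * F(1, 0);
  if (J <= 0) { *Wout = -1.0; return; }  // caller treats as failure
  arma::mat22 Finv = arma::inv(F);
  arma::mat22 G = Finv.t();              // F^{-T}
  double I1 = arma::accu(F % F) + 1.0;
  double Jm23 = std::pow(J, -2.0 / 3.0);
  *Wout = 0.5 * mu * (Jm23 * I1 - 3.0) + 0.5 * Kb * (J - 1.0) * (J - 1.0);
  P = mu * Jm23 * F - (mu / 3.0) * Jm23 * I1 * G + Kb * J * (J - 1.0) * G;
  if (!want_A) return;
  for (int i = 0; i < 2; ++i)
    for (int Jj = 0; Jj < 2; ++Jj)
      for (int k = 0; k < 2; ++k)
        for (int L = 0; L < 2; ++L) {
          double v = 0.0;
          if (i == k && Jj == L) v += mu * Jm23;
          v += -(2.0 * mu / 3.0) * Jm23 * (F(i, Jj) * G(k, L) + F(k, L) * G(i, Jj));
          v += (2.0 * mu / 9.0) * Jm23 * I1 * G(i, Jj) * G(k, L);
          v += (mu / 3.0) * Jm23 * I1 * G(i, L) * G(k, Jj);
          v += Kb * J * (2.0 * J - 1.0) * G(i, Jj) * G(k, L);
          v += -Kb * J * (J - 1.0) * G(i, L) * G(k, Jj);
          A[i][Jj][k][L] = v;
        }
}

// [[Rcpp::export]]
List nh_assemble(const arma::mat& nodes, const arma::imat& tri,
                 const arma::vec& u, const arma::vec& mu, const arma::vec& Kb,
                 const arma::mat& bodyf, const arma::imat& pedges,
                 double pmag, const arma::ivec& slot_el,
                 const arma::ivec& slot_pe, int nnz, bool want_tangent) {
  const int nel = tri.n_rows;
  const int ndof = 2 * nodes.n_rows;
  arma::vec res(ndof, arma::fill::zeros);
  arma::vec xvals(std::max(nnz, 1), arma::fill::zeros);
  double energy = 0.0;
  bool ok = true;

  double N[6], dN[6][2], A[2][2][2][2];
  arma::mat22 P;
  for (int e = 0; e < nel && ok; ++e) {
    arma::mat X(6, 2), ue(6, 2);
    int gdof[12];
    for (int a = 0; a < 6; ++a) {
      int n = tri(e, a) - 1;
      X(a, 0) = nodes(n, 0); X(a, 1) = nodes(n, 1);
      ue(a, 0) = u[2 * n]; ue(a, 1) = u[2 * n + 1];
      gdof[2 * a] = 2 * n; gdof[2 * a + 1] = 2 * n + 1;
    }
    double Ke[12][12] = {{0}};
    double re[12] = {0};
    for (int q = 0; q < 3; ++q) {
      shape_p2(QP[q][0], QP[q][1], N, dN);
      arma::mat22 Jm(arma::fill::zeros);           // dX/dxi
      for (int a = 0; a < 6; ++a) {
        Jm(0, 0) += X(a, 0) * dN[a][0]; Jm(0, 1) += X(a, 0) * dN[a][1];
        Jm(1, 0) += X(a, 1) * dN[a][0]; Jm(1, 1) += X(a, 1) * dN[a][1];
      }
      double detJ = Jm(0, 0) * Jm(1, 1) - Jm(0, 1) * Jm(1, 0);
      if (detJ <= 0) { ok = false; break; }
      arma::mat22 Jinv = arma::inv(Jm);
      double dNX[6][2];
      for (int a = 0; a < 6; ++a) {
        dNX[a][0] = dN[a][0] * Jinv(0, 0) + dN[a][1] * Jinv(1, 0);
        dNX[a][1] = dN[a][0] * Jinv(0, 1) + dN[a][1] * Jinv(1, 1);
      }
      arma::mat22 F(arma::fill::eye);
      for (int a = 0; a < 6; ++a) {
        F(0, 0) += ue(a, 0) * dNX[a][0]; F(0, 1) += ue(a, 0) * dNX[a][1];
        F(1, 0) += ue(a, 1) * dNX[a][0]; F(1, 1) += ue(a, 1) * dNX[a][1];
      }
      double W;
      nh_stress(F, mu[e], Kb[e], P, A, want_tangent, &W);
      if (W < 0) { ok = false; break; }
      double wv = QW * detJ;
      energy += wv * W;
      for (int a = 0; a < 6; ++a)
        for (int i = 0; i < 2; ++i) {
          re[2 * a + i] += wv * (P(i, 0) * dNX[a][0] + P(i, 1) * dNX[a][1]);
          re[2 * a + i] -= wv * bodyf(e, i) * N[a];
        }
      if (want_tangent) {
        for (int a = 0; a < 6; ++a)
          for (int b = 0; b < 6; ++b)
            for (int i = 0; i < 2; ++i)
              for (int k = 0; k < 2; ++k) {
                double v = 0.0;
                for (int Jj = 0; Jj < 2; ++Jj)
                  for (int L = 0; L < 2; ++L)
                    v += A[i][Jj][k][L] * dNX[a][Jj] * dNX[b][L];
                Ke[2 * a + i][2 * b + k] += wv * v;
              }
      }
    }
    if (!ok) break;
    for (int p = 0; p < 12; ++p) res[gdof[p]] += re[p];
    if (want_tangent) {
      const arma::sword* sl = slot_el.memptr() + (arma::uword)e * 144;
      for (int p = 0; p < 12; ++p)
        for (int qd = 0; qd < 12; ++qd) {
          arma::sword s = sl[p * 12 + qd];
          if (s >= 0) xvals[s] += Ke[p][qd];
        }
    }
  }

  // follower pressure on cavity-wall edges (tissue on the left of the
  // edge direction; the load pushes toward the tissue side)
  if (ok && pedges.n_rows > 0 && pmag != 0.0) {
    const double gt[3] = {0.5 - std::sqrt(3.0 / 5.0) / 2, 0.5,
                          0.5 + std::sqrt(3.0 / 5.0) / 2};
    const double gw[3] = {5.0 / 18, 8.0 / 18, 5.0 / 18};
    for (arma::uword e = 0; e < pedges.n_rows; ++e) {
      int nid[3] = {(int)pedges(e, 0) - 1, (int)pedges(e, 1) - 1,
                    (int)pedges(e, 2) - 1};
      double xv[3], yv[3];
      for (int a = 0; a < 3; ++a) {
        xv[a] = nodes(nid[a], 0) + u[2 * nid[a]];
        yv[a] = nodes(nid[a], 1) + u[2 * nid[a] + 1];
      }
      double fe[6] = {0};
      double Te[6][6] = {{0}};
      for (int q = 0; q < 3; ++q) {
        double t = gt[q];
        double Ne[3] = {(1 - t) * (1 - 2 * t), 4 * t * (1 - t), t * (2 * t - 1)};
        double dNe[3] = {4 * t - 3, 4 - 8 * t, 4 * t - 1};
        // node order along edge: end1, mid, end2
        double tx = dNe[0] * xv[0] + dNe[1] * xv[1] + dNe[2] * xv[2];
        double ty = dNe[0] * yv[0] + dNe[1] * yv[1] + dNe[2] * yv[2];
        // rotate tangent +90 deg: force direction into the tissue
        double nx = -ty, ny = tx;
        for (int a = 0; a < 3; ++a) {
          fe[2 * a]     += gw[q] * pmag * Ne[a] * nx;
          fe[2 * a + 1] += gw[q] * pmag * Ne[a] * ny;
          for (int b = 0; b < 3; ++b) {
            // d f_a / d x_b: fax = -p Na ty -> d/dyb = -p Na dNb ; etc.
            Te[2 * a][2 * b + 1]     += -gw[q] * pmag * Ne[a] * dNe[b];
            Te[2 * a + 1][2 * b]     +=  gw[q] * pmag * Ne[a] * dNe[b];
          }
        }
      }
      for (int a = 0; a < 3; ++a) {
        res[2 * nid[a]]     -= fe[2 * a];
        res[2 * nid[a] + 1] -= fe[2 * a + 1];
      }
      if (want_tangent) {
        // residual = internal - external, so K -= dfext/du; store the
        // symmetric part (the factorisation assumes symmetry)
        const arma::sword* sl = slot_pe.memptr() + (arma::uword)e * 36;
        for (int p = 0; p < 6; ++p)
          for (int qd = 0; qd < 6; ++qd) {
            arma::sword s = sl[p * 6 + qd];
            if (s >= 0) xvals[s] += -0.5 * (Te[p][qd] + Te[qd][p]);
          }
      }
    }
  }

  return List::create(_["ok"] = ok, _["res"] = res, _["xvals"] = xvals,
                      _["energy"] = energy);
}

// per-element mean deformation summaries: W, J, I1 and reference area
// [[Rcpp::export]]
arma::mat nh_fields(const arma::mat& nodes, const arma::imat& tri,
                    const arma::vec& u, const arma::vec& mu,
                    const arma::vec& Kb) {
  const int nel = tri.n_rows;
  arma::mat out(nel, 4, arma::fill::zeros);
  double N[6], dN[6][2], A[2][2][2][2];
  arma::mat22 P;
  for (int e = 0; e < nel; ++e) {
    arma::mat X(6, 2), ue(6, 2);
    for (int a = 0; a < 6; ++a) {
      int n = tri(e, a) - 1;
      X(a, 0) = nodes(n, 0); X(a, 1) = nodes(n, 1);
      ue(a, 0) = u[2 * n]; ue(a, 1) = u[2 * n + 1];
    }
    double Wsum = 0, Jsum = 0, I1sum = 0, area = 0;
    for (int q = 0; q < 3; ++q) {
      shape_p2(QP[q][0], QP[q][1], N, dN);
      arma::mat22 Jm(arma::fill::zeros);
      for (int a = 0; a < 6; ++a) {
        Jm(0, 0) += X(a, 0) * dN[a][0]; Jm(0, 1) += X(a, 0) * dN[a][1];
        Jm(1, 0) += X(a, 1) * dN[a][0]; Jm(1, 1) += X(a, 1) * dN[a][1];
      }
      double detJ = Jm(0, 0) * Jm(1, 1) - Jm(0, 1) * Jm(1, 0);
      arma::mat22 Jinv = arma::inv(Jm);
      arma::mat22 F(arma::fill::eye);
      for (int a = 0; a < 6; ++a) {
        double dx = dN[a][0] * Jinv(0, 0) + dN[a][1] * Jinv(1, 0);
        double dy = dN[a][0] * Jinv(0, 1) + dN[a][1] * Jinv(1, 1);
        F(0, 0) += ue(a, 0) * dx; F(0, 1) += ue(a, 0) * dy;
        F(1, 0) += ue(a, 1) * dx; F(1, 1) += ue(a, 1) * dy;
      }
      double W;
      nh_stress(F, mu[e], Kb[e], P, A, false, &W);
      double wv = QW * detJ;
      double Jdet = F(0, 0) * F(1, 1) - F(0, 1) * F(1, 0);
      Wsum += wv * std::max(W, 0.0);
      Jsum += wv * Jdet;
      I1sum += wv * (arma::accu(F % F) + 1.0);
      area += wv;
    }
    out(e, 0) = Wsum / area; out(e, 1) = Jsum / area;
    out(e, 2) = I1sum / area; out(e, 3) = area;
  }
  return out;
}
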