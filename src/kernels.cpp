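#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Regularized-Stokeslet kernels (Cortez-type blob), mu = 1 internally.
// Velocity:  u_a(x) = [ d_ab (r^2 + 2 e^2) + r_a r_b ] / (8 pi (r^2+e^2)^{3/2}) g_b
// Pressure:  p(x)   = (g . r) (2 r^2 + 5 e^2) / (8 pi (r^2+e^2)^{5/2})
// The blob length e is that of the *source* point throughout.

static const double PI8 = 8.0 * M_PI;

// [[Rcpp::export]]
NumericMatrix cp_stokeslet_matrix(NumericMatrix pts, NumericVector eps) {
  int n = pts.nrow();
  NumericMatrix A(3 * n, 3 * n);
  for (int j = 0; j < n; ++j) {
    double e2 = eps[j] * eps[j];
    for (int i = 0; i < n; ++i) {
      double rx = pts(i, 0) - pts(j, 0);
      double ry = pts(i, 1) - pts(j, 1);
      double rz = pts(i, 2) - pts(j, 2);
      double r2 = rx * rx + ry * ry + rz * rz;
      double d  = std::sqrt(r2 + e2);
      double d3 = d * d * d;
      double c1 = (r2 + 2.0 * e2) / (PI8 * d3);
      double c2 = 1.0 / (PI8 * d3);
      A(3 * i,     3 * j)     = c1 + c2 * rx * rx;
      A(3 * i,     3 * j + 1) = c2 * rx * ry;
      A(3 * i,     3 * j + 2) = c2 * rx * rz;
      A(3 * i + 1, 3 * j)     = c2 * ry * rx;
      A(3 * i + 1, 3 * j + 1) = c1 + c2 * ry * ry;
      A(3 * i + 1, 3 * j + 2) = c2 * ry * rz;
      A(3 * i + 2, 3 * j)     = c2 * rz * rx;
      A(3 * i + 2, 3 * j + 1) = c2 * rz * ry;
      A(3 * i + 2, 3 * j + 2) = c1 + c2 * rz * rz;
    }
  }
  return A;
}

// [[Rcpp::export]]
NumericMatrix cp_stokeslet_velocity(NumericMatrix src, NumericVector eps,
                                    NumericMatrix forces, NumericMatrix field) {
  int n = src.nrow(), m = field.nrow();
  NumericMatrix U(m, 3);
  for (int i = 0; i < m; ++i) {
    double ux = 0, uy = 0, uz = 0;
    for (int j = 0; j < n; ++j) {
      double e2 = eps[j] * eps[j];
      double rx = field(i, 0) - src(j, 0);
      double ry = field(i, 1) - src(j, 1);
      double rz = field(i, 2) - src(j, 2);
      double r2 = rx * rx + ry * ry + rz * rz;
      double d  = std::sqrt(r2 + e2);
      double d3 = d * d * d;
      double c1 = (r2 + 2.0 * e2) / (PI8 * d3);
      double fr = forces(j, 0) * rx + forces(j, 1) * ry + forces(j, 2) * rz;
      double c2 = fr / (PI8 * d3);
      ux += c1 * forces(j, 0) + c2 * rx;
      uy += c1 * forces(j, 1) + c2 * ry;
      uz += c1 * forces(j, 2) + c2 * rz;
    }
    U(i, 0) = ux; U(i, 1) = uy; U(i, 2) = uz;
  }
  return U;
}

// [[Rcpp::export]]
NumericVector cp_stokeslet_pressure(NumericMatrix src, NumericVector eps,
                                    NumericMatrix forces, NumericMatrix field) {
  int n = src.nrow(), m = field.nrow();
  NumericVector P(m);
  for (int i = 0; i < m; ++i) {
    double p = 0;
    for (int j = 0; j < n; ++j) {
      double e2 = eps[j] * eps[j];
      double rx = field(i, 0) - src(j, 0);
      double ry = field(i, 1) - src(j, 1);
      double rz = field(i, 2) - src(j, 2);
      double r2 = rx * rx + ry * ry + rz * rz;
      double d  = std::sqrt(r2 + e2);
      double d5 = d * d * d * d * d;
      double fr = forces(j, 0) * rx + forces(j, 1) * ry + forces(j, 2) * rz;
      p += fr * (2.0 * r2 + 5.0 * e2) / (PI8 * d5);
    }
    P[i] = p;
  }
  return P;
}

// [[Rcpp::export]]
NumericVector cp_min_dist(NumericMatrix src, NumericMatrix field) {
  int n = src.nrow(), m = field.nrow();
  NumericVector D(m);
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      double rx = field(i, 0) - src(j, 0);
      double ry = field(i, 1) - src(j, 1);
      double rz = field(i, 2) - src(j, 2);
      double d2 = rx * rx + ry * ry + rz * rz;
      if (d2 < best) best = d2;
    }
    D[i] = std::sqrt(best);
  }
  return D;
}

// Image-system correction for a Stokeslet above a no-slip plane z = 0
// (classical image triplet: mirror Stokeslet, potential dipole, Stokeslet
// doublet), singular form; added to the regularized primary Stokeslet it
// enforces no-slip on the wall up to O(eps) near the source.
// R = x - y*, y* the mirror of the source, h = source height, beta=(1,1,-1).
static inline void blake_image(const double Rv[3], double h, double IM[3][3]) {
  double R2 = Rv[0] * Rv[0] + Rv[1] * Rv[1] + Rv[2] * Rv[2];
  double R1 = std::sqrt(R2);
  double R3 = R1 * R2, R5 = R3 * R2;
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) {
      double dij = (i == j) ? 1.0 : 0.0;
      double bj  = (j == 2) ? -1.0 : 1.0;
      double im  = -(dij / R1 + Rv[i] * Rv[j] / R3);
      double t   = h * (dij / R3 - 3.0 * Rv[i] * Rv[j] / R5);
      if (i == 2) t += Rv[j] / R3;
      t -= (dij * Rv[2] + ((j == 2) ? Rv[i] : 0.0)) / R3;
      t += 3.0 * Rv[i] * Rv[2] * Rv[j] / R5;
      IM[i][j] = im + 2.0 * h * bj * t;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cp_blake_matrix(NumericMatrix pts, NumericVector eps) {
  int n = pts.nrow();
  NumericMatrix A = cp_stokeslet_matrix(pts, eps);
  double IM[3][3];
  for (int j = 0; j < n; ++j) {
    double h = pts(j, 2);
    for (int i = 0; i < n; ++i) {
      double Rv[3] = { pts(i, 0) - pts(j, 0),
                       pts(i, 1) - pts(j, 1),
                       pts(i, 2) + pts(j, 2) };
      blake_image(Rv, h, IM);
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          A(3 * i + a, 3 * j + b) += IM[a][b] / PI8;
    }
  }
  return A;
}

// [[Rcpp::export]]
NumericMatrix cp_blake_velocity(NumericMatrix src, NumericVector eps,
                                NumericMatrix forces, NumericMatrix field) {
  int m = field.nrow(), n = src.nrow();
  NumericMatrix U = cp_stokeslet_velocity(src, eps, forces, field);
  double IM[3][3];
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double h = src(j, 2);
      double Rv[3] = { field(i, 0) - src(j, 0),
                       field(i, 1) - src(j, 1),
                       field(i, 2) + src(j, 2) };
      blake_image(Rv, h, IM);
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          U(i, a) += IM[a][b] * forces(j, b) / PI8;
    }
  }
  return U;
}
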