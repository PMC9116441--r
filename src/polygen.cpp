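// Crankshaft Markov chain on closed equilateral polygons, plus the exact
// re-equilateralization projection used to control floating-point drift.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using Rcpp::NumericMatrix;

namespace {

// alternate unit-normalization of edge vectors with removal of the closure
// defect; converges rapidly for small perturbations
void equilateralize_inplace(std::vector<double>& x, std::vector<double>& y,
                            std::vector<double>& z, double tol, int max_iter) {
  const int n = static_cast<int>(x.size());
  std::vector<double> ex(n), ey(n), ez(n);
  for (int iter = 0; iter < max_iter; ++iter) {
    double worst_len = 0.0;
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      worst_len = std::max(worst_len, std::fabs(len - 1.0));
      ex[i] = dx / len;
      ey[i] = dy / len;
      ez[i] = dz / len;
    }
    double mx = 0.0, my = 0.0, mz = 0.0;
    for (int i = 0; i < n; ++i) {
      mx += ex[i];
      my += ey[i];
      mz += ez[i];
    }
    mx /= n;
    my /= n;
    mz /= n;
    double defect = std::sqrt(mx * mx + my * my + mz * mz) * n;
    if (worst_len < tol && defect < tol) return;
    for (int i = 0; i < n; ++i) {
      ex[i] -= mx;
      ey[i] -= my;
      ez[i] -= mz;
    }
    // rebuild vertices from the closed edge set
    for (int i = 1; i < n; ++i) {
      x[i] = x[i - 1] + ex[i - 1];
      y[i] = y[i - 1] + ey[i - 1];
      z[i] = z[i - 1] + ez[i - 1];
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix equilateralize_cpp(NumericMatrix v, double tol = 1e-12,
                                 int max_iter = 1000) {
  const int n = v.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = v(i, 0);
    y[i] = v(i, 1);
    z[i] = v(i, 2);
  }
  equilateralize_inplace(x, y, z, tol, max_iter);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i];
    out(i, 1) = y[i];
    out(i, 2) = z[i];
  }
  return out;
}

// deterministic single crankshaft rotation (0-based indices), no projection
// [[Rcpp::export]]
NumericMatrix rotate_subchain_cpp(NumericMatrix v, int i, int j, double theta) {
  const int n = v.nrow();
  NumericMatrix out = Rcpp::clone(v);
  double ax = v(j, 0) - v(i, 0);
  double ay = v(j, 1) - v(i, 1);
  double az = v(j, 2) - v(i, 2);
  double norm = std::sqrt(ax * ax + ay * ay + az * az);
  if (norm < 1e-12) Rcpp::stop("degenerate chord");
  if (theta == 0.0) return out;  // identity move, bit-exact
  ax /= norm;
  ay /= norm;
  az /= norm;
  const double c = std::cos(theta), s = std::sin(theta);
  for (int k = (i + 1) % n; k != j; k = (k + 1) % n) {
    double px = v(k, 0) - v(i, 0), py = v(k, 1) - v(i, 1), pz = v(k, 2) - v(i, 2);
    double dot = px * ax + py * ay + pz * az;
    double cx = ay * pz - az * py;
    double cy = az * px - ax * pz;
    double cz = ax * py - ay * px;
    out(k, 0) = v(i, 0) + px * c + cx * s + ax * dot * (1.0 - c);
    out(k, 1) = v(i, 1) + py * c + cy * s + ay * dot * (1.0 - c);
    out(k, 2) = v(i, 2) + pz * c + cz * s + az * dot * (1.0 - c);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix crankshaft_chain_cpp(NumericMatrix v, int n_steps,
                                   int reproject_every = 1000,
                                   double tol = 1e-12) {
  const int n = v.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = v(i, 0);
    y[i] = v(i, 1);
    z[i] = v(i, 2);
  }
  Rcpp::RNGScope scope;
  for (int step = 0; step < n_steps; ++step) {
    int i, j;
    double ax, ay, az, norm;
    do {
      i = static_cast<int>(R::unif_rand() * n);
      j = static_cast<int>(R::unif_rand() * n);
      if (i >= n) i = n - 1;
      if (j >= n) j = n - 1;
      ax = x[j] - x[i];
      ay = y[j] - y[i];
      az = z[j] - z[i];
      norm = std::sqrt(ax * ax + ay * ay + az * az);
    } while (i == j || norm < 1e-12);
    ax /= norm;
    ay /= norm;
    az /= norm;
    const double theta = R::unif_rand() * 2.0 * M_PI;
    const double c = std::cos(theta), s = std::sin(theta);
    // rotate the sub-chain strictly between i and j (walking forward from i)
    for (int k = (i + 1) % n; k != j; k = (k + 1) % n) {
      double px = x[k] - x[i], py = y[k] - y[i], pz = z[k] - z[i];
      double dot = px * ax + py * ay + pz * az;
      double cx = ay * pz - az * py;
      double cy = az * px - ax * pz;
      double cz = ax * py - ay * px;
      // Rodrigues rotation about the chord direction
      x[k] = x[i] + px * c + cx * s + ax * dot * (1.0 - c);
      y[k] = y[i] + py * c + cy * s + ay * dot * (1.0 - c);
      z[k] = z[i] + pz * c + cz * s + az * dot * (1.0 - c);
    }
    if ((step + 1) % reproject_every == 0)
      equilateralize_inplace(x, y, z, tol, 1000);
  }
  equilateralize_inplace(x, y, z, tol, 1000);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i];
    out(i, 1) = y[i];
    out(i, 2) = z[i];
  }
  return out;
}
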