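// Geometric kernels: exact minimal enclosing ball (Welzl), incremental 3D
// convex hull volume, and planar crossing detection for knot diagrams.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

namespace {

struct P3 {
  double x, y, z;
};

inline P3 operator-(const P3& a, const P3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline double dot(const P3& a, const P3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline P3 cross(const P3& a, const P3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm2(const P3& a) { return dot(a, a); }

struct Ball {
  P3 c;
  double r2;  // squared radius; r2 < 0 marks the empty ball
  bool contains(const P3& p, double slack) const {
    return r2 >= 0 && norm2(p - c) <= r2 + slack;
  }
};

Ball ball2(const P3& a, const P3& b) {
  P3 c{(a.x + b.x) / 2, (a.y + b.y) / 2, (a.z + b.z) / 2};
  return {c, norm2(a - c)};
}

// circumsphere of 3 points with centre in their plane
Ball ball3(const P3& a, const P3& b, const P3& c) {
  P3 u = b - a, v = c - a;
  P3 n = cross(u, v);
  double nn = norm2(n);
  if (nn < 1e-24) return {P3{0, 0, 0}, -1.0};
  double uu = norm2(u), vv = norm2(v);
  P3 t = cross(P3{u.x * vv - v.x * uu, u.y * vv - v.y * uu, u.z * vv - v.z * uu}, n);
  P3 ctr{a.x - t.x / (2 * nn), a.y - t.y / (2 * nn), a.z - t.z / (2 * nn)};
  return {ctr, norm2(a - ctr)};
}

Ball ball4(const P3& a, const P3& b, const P3& c, const P3& d) {
  // solve 2 (p_i - a) . x = |p_i|^2 - |a|^2
  double m[3][3], rhs[3];
  const P3 pts[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    P3 u = pts[i] - a;
    m[i][0] = 2 * u.x;
    m[i][1] = 2 * u.y;
    m[i][2] = 2 * u.z;
    rhs[i] = norm2(pts[i]) - norm2(a);
  }
  double det = m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
               m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
               m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  if (std::fabs(det) < 1e-18) return {P3{0, 0, 0}, -1.0};
  auto solve = [&](int col) {
    double mm[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) mm[i][j] = (j == col) ? rhs[i] : m[i][j];
    return (mm[0][0] * (mm[1][1] * mm[2][2] - mm[1][2] * mm[2][1]) -
            mm[0][1] * (mm[1][0] * mm[2][2] - mm[1][2] * mm[2][0]) +
            mm[0][2] * (mm[1][0] * mm[2][1] - mm[1][1] * mm[2][0])) /
           det;
  };
  P3 ctr{solve(0), solve(1), solve(2)};
  return {ctr, norm2(a - ctr)};
}

Ball ball_of_support(const std::vector<P3>& s) {
  switch (s.size()) {
    case 0: return {P3{0, 0, 0}, -1.0};
    case 1: return {s[0], 0.0};
    case 2: return ball2(s[0], s[1]);
    case 3: {
      Ball b = ball3(s[0], s[1], s[2]);
      if (b.r2 < 0) {  // collinear support: widest pair
        Ball best = ball2(s[0], s[1]);
        Ball b2 = ball2(s[0], s[2]);
        if (b2.r2 > best.r2) best = b2;
        Ball b3 = ball2(s[1], s[2]);
        if (b3.r2 > best.r2) best = b3;
        return best;
      }
      return b;
    }
    default: {
      Ball b = ball4(s[0], s[1], s[2], s[3]);
      if (b.r2 < 0) return ball3(s[0], s[1], s[2]);
      return b;
    }
  }
}

Ball welzl(std::vector<P3>& pts, size_t end, std::vector<P3>& support, double slack) {
  if (end == 0 || support.size() == 4) return ball_of_support(support);
  Ball b = welzl(pts, end - 1, support, slack);
  const P3& p = pts[end - 1];
  if (b.contains(p, slack)) return b;
  support.push_back(p);
  b = welzl(pts, end - 1, support, slack);
  support.pop_back();
  // move-to-front
  std::rotate(pts.begin(), pts.begin() + (end - 1), pts.begin() + end);
  return b;
}

}  // namespace

// [[Rcpp::export]]
NumericVector miniball_cpp(NumericMatrix m) {
  const int n = m.nrow();
  std::vector<P3> pts(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    pts[i] = {m(i, 0), m(i, 1), m(i, 2)};
    scale = std::max(scale, std::fabs(m(i, 0)) + std::fabs(m(i, 1)) + std::fabs(m(i, 2)));
  }
  const double slack = 1e-13 * std::max(1.0, scale * scale);
  std::mt19937 gen(88172645u);  // deterministic shuffle, independent of R's RNG
  std::shuffle(pts.begin(), pts.end(), gen);
  std::vector<P3> support;
  Ball b = welzl(pts, pts.size(), support, slack);
  return NumericVector::create(b.c.x, b.c.y, b.c.z, std::sqrt(std::max(0.0, b.r2)));
}

// [[Rcpp::export]]
double hull_volume_cpp(NumericMatrix m) {
  const int n = m.nrow();
  if (n < 4) return 0.0;
  std::vector<P3> p(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    p[i] = {m(i, 0), m(i, 1), m(i, 2)};
    scale = std::max(scale,
                     std::max(std::fabs(p[i].x), std::max(std::fabs(p[i].y), std::fabs(p[i].z))));
  }
  const double eps = 1e-10 * std::max(1.0, scale);
  // initial simplex: extremal in x, farthest from line, farthest from plane
  int i0 = 0, i1 = 0;
  for (int i = 0; i < n; ++i) {
    if (p[i].x < p[i0].x) i0 = i;
    if (p[i].x > p[i1].x) i1 = i;
  }
  if (i0 == i1) i1 = (i0 + 1) % n;
  int i2 = -1;
  double best = eps * eps;
  for (int i = 0; i < n; ++i) {
    P3 d = cross(p[i1] - p[i0], p[i] - p[i0]);
    double v = norm2(d) / std::max(norm2(p[i1] - p[i0]), 1e-300);
    if (v > best) {
      best = v;
      i2 = i;
    }
  }
  if (i2 < 0) return 0.0;  // all collinear
  int i3 = -1;
  P3 nrm = cross(p[i1] - p[i0], p[i2] - p[i0]);
  best = eps * std::sqrt(norm2(nrm));
  for (int i = 0; i < n; ++i) {
    double v = std::fabs(dot(nrm, p[i] - p[i0]));
    if (v > best) {
      best = v;
      i3 = i;
    }
  }
  if (i3 < 0) return 0.0;  // coplanar
  struct Face {
    int a, b, c;
    P3 n;
    double off;
    bool alive;
  };
  std::vector<Face> faces;
  P3 inner{(p[i0].x + p[i1].x + p[i2].x + p[i3].x) / 4,
           (p[i0].y + p[i1].y + p[i2].y + p[i3].y) / 4,
           (p[i0].z + p[i1].z + p[i2].z + p[i3].z) / 4};
  auto add_face = [&](int a, int b, int c) {
    P3 fn = cross(p[b] - p[a], p[c] - p[a]);
    if (dot(fn, inner - p[a]) > 0) {  // orient outward
      std::swap(b, c);
      fn = cross(p[b] - p[a], p[c] - p[a]);
    }
    faces.push_back({a, b, c, fn, dot(fn, p[a]), true});
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    std::vector<int> visible;
    for (int f = 0; f < static_cast<int>(faces.size()); ++f) {
      if (!faces[f].alive) continue;
      double nn = std::sqrt(std::max(norm2(faces[f].n), 1e-300));
      if (dot(faces[f].n, p[i]) - faces[f].off > eps * nn) visible.push_back(f);
    }
    if (visible.empty()) continue;
    // horizon = directed edges of visible faces whose twin is not visible
    std::vector<std::pair<int, int>> edges;
    for (int f : visible) {
      edges.push_back({faces[f].a, faces[f].b});
      edges.push_back({faces[f].b, faces[f].c});
      edges.push_back({faces[f].c, faces[f].a});
    }
    for (int f : visible) faces[f].alive = false;
    for (auto& e : edges) {
      bool twin = false;
      for (auto& e2 : edges)
        if (e2.first == e.second && e2.second == e.first) {
          twin = true;
          break;
        }
      if (!twin) add_face(e.first, e.second, i);
    }
  }
  double vol6 = 0.0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    P3 a = p[f.a], b = p[f.b], c = p[f.c];
    vol6 += dot(P3{a.x - inner.x, a.y - inner.y, a.z - inner.z},
                cross(P3{b.x - inner.x, b.y - inner.y, b.z - inner.z},
                      P3{c.x - inner.x, c.y - inner.y, c.z - inner.z}));
  }
  return std::fabs(vol6) / 6.0;
}

// Project the polygon along `direction` and find all transverse crossings.
// Returns a list of crossing records, or a degeneracy flag for the caller to
// retry with a fresh direction.  Positions along the curve are (edge, param).
// [[Rcpp::export]]
List project_diagram_cpp(NumericMatrix v, NumericVector direction, double tol) {
  const int n = v.nrow();
  P3 w{direction[0], direction[1], direction[2]};
  double wn = std::sqrt(norm2(w));
  w = {w.x / wn, w.y / wn, w.z / wn};
  // orthonormal frame (u1, u2, w), right-handed
  P3 axis = std::fabs(w.x) < 0.9 ? P3{1, 0, 0} : P3{0, 1, 0};
  P3 u1 = cross(axis, w);
  double u1n = std::sqrt(norm2(u1));
  u1 = {u1.x / u1n, u1.y / u1n, u1.z / u1n};
  P3 u2 = cross(w, u1);
  std::vector<double> px(n), py(n), pz(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P3 q{v(i, 0), v(i, 1), v(i, 2)};
    px[i] = dot(q, u1);
    py[i] = dot(q, u2);
    pz[i] = dot(q, w);
    scale = std::max(scale, std::fabs(px[i]) + std::fabs(py[i]));
  }
  scale = std::max(scale, 1.0);
  for (int a = 0; a < n; ++a) {
    int a2 = (a + 1) % n;
    double Ax = px[a2] - px[a], Ay = py[a2] - py[a];
    if (Ax * Ax + Ay * Ay < tol * tol * scale * scale)
      return List::create(Rcpp::Named("degenerate") = true);  // edge along direction
  }
  std::vector<int> ea, eb;
  std::vector<double> sa, sb;
  std::vector<int> over_first, sign;
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      // skip edge pairs sharing a vertex (cyclically adjacent)
      if (b == a + 1 || (a == 0 && b == n - 1)) continue;
      int a2 = (a + 1) % n, b2 = (b + 1) % n;
      double Ax = px[a2] - px[a], Ay = py[a2] - py[a];
      double Bx = px[b2] - px[b], By = py[b2] - py[b];
      double Dx = px[b] - px[a], Dy = py[b] - py[a];
      double den = Ax * By - Ay * Bx;
      if (std::fabs(den) < 1e-12 * scale * scale) {
        // near-parallel projected edges: degenerate only if the segments
        // actually come close in projection
        double t0 = ((Dx) *Ax + (Dy) *Ay) / std::max(Ax * Ax + Ay * Ay, 1e-300);
        t0 = std::min(1.0, std::max(0.0, t0));
        double cxp = px[a] + t0 * Ax - px[b], cyp = py[a] + t0 * Ay - py[b];
        double t1 = (cxp * Bx + cyp * By) / std::max(Bx * Bx + By * By, 1e-300);
        t1 = std::min(1.0, std::max(0.0, t1));
        double gx = px[a] + t0 * Ax - (px[b] + t1 * Bx);
        double gy = py[a] + t0 * Ay - (py[b] + t1 * By);
        if (gx * gx + gy * gy < tol * tol * scale * scale)
          return List::create(Rcpp::Named("degenerate") = true);
        continue;
      }
      // solve p_a + s A = p_b + t B (Cramer)
      double s = (Dx * By - Dy * Bx) / den;
      double t = (Ay * Dx - Ax * Dy) / den;
      if (s <= -tol || s >= 1 + tol || t <= -tol || t >= 1 + tol) continue;
      if (s < tol || s > 1 - tol || t < tol || t > 1 - tol)
        return List::create(Rcpp::Named("degenerate") = true);  // crossing at a vertex image
      double za = pz[a] + s * (pz[a2] - pz[a]);
      double zb = pz[b] + t * (pz[b2] - pz[b]);
      if (std::fabs(za - zb) < tol) return List::create(Rcpp::Named("degenerate") = true);
      bool a_over = za > zb;
      // crossing sign: det of (over tangent, under tangent) in the plane
      double det = a_over ? (Ax * By - Ay * Bx) : (Bx * Ay - By * Ax);
      ea.push_back(a);
      eb.push_back(b);
      sa.push_back(s);
      sb.push_back(t);
      over_first.push_back(a_over ? 1 : 0);
      sign.push_back(det > 0 ? 1 : -1);
    }
  }
  return List::create(
      Rcpp::Named("degenerate") = false, Rcpp::Named("edge_a") = ea,
      Rcpp::Named("edge_b") = eb, Rcpp::Named("s_a") = sa, Rcpp::Named("s_b") = sb,
      Rcpp::Named("a_over") = over_first, Rcpp::Named("sign") = sign);
}

// crossing count only (for the Monte-Carlo average crossing number);
// returns -1 on a degenerate projection
// [[Rcpp::export]]
int count_crossings_cpp(NumericMatrix v, NumericVector direction, double tol) {
  List res = project_diagram_cpp(v, direction, tol);
  if (Rcpp::as<bool>(res["degenerate"])) return -1;
  return Rcpp::as<std::vector<int>>(res["edge_a"]).size();
}
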