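// Alexander polynomial from a Gauss code via the Wirtinger presentation.
//
// Each crossing contributes a Fox-calculus relation row over the arcs:
//   positive crossing:  (1-t) over + t in  -   out
//   negative crossing:  (t-1) over +   in  - t out   (row scaled by t)
// The Alexander polynomial is the determinant of the matrix with one row and
// one column deleted, up to units.  The determinant is computed over the
// prime field Z_p (p = 2^31 - 1) by evaluation at distinct points and
// Lagrange interpolation; coefficients are lifted to the symmetric range.
// Alexander coefficients of knots realizable here are far below p/2, so the
// lift is exact.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using Rcpp::IntegerVector;

namespace {

const int64_t P = 2147483647LL;  // 2^31 - 1, prime

inline int64_t mulp(int64_t a, int64_t b) { return (a * b) % P; }
inline int64_t addp(int64_t a, int64_t b) {
  int64_t s = a + b;
  return s >= P ? s - P : s;
}
inline int64_t subp(int64_t a, int64_t b) {
  int64_t s = a - b;
  return s < 0 ? s + P : s;
}

int64_t powp(int64_t b, int64_t e) {
  int64_t r = 1;
  b %= P;
  while (e > 0) {
    if (e & 1) r = mulp(r, b);
    b = mulp(b, b);
    e >>= 1;
  }
  return r;
}

inline int64_t invp(int64_t a) { return powp(a, P - 2); }

// determinant of a dense matrix over Z_p by Gaussian elimination
int64_t detp(std::vector<std::vector<int64_t>>& m) {
  const int n = static_cast<int>(m.size());
  int64_t det = 1;
  for (int c = 0; c < n; ++c) {
    int piv = -1;
    for (int r = c; r < n; ++r)
      if (m[r][c] != 0) {
        piv = r;
        break;
      }
    if (piv < 0) return 0;
    if (piv != c) {
      std::swap(m[piv], m[c]);
      det = subp(0, det);
    }
    det = mulp(det, m[c][c]);
    int64_t inv = invp(m[c][c]);
    for (int r = c + 1; r < n; ++r) {
      if (m[r][c] == 0) continue;
      int64_t f = mulp(m[r][c], inv);
      for (int k = c; k < n; ++k) m[r][k] = subp(m[r][k], mulp(f, m[c][k]));
    }
  }
  return det;
}

}  // namespace

// gauss: 2C rows in traversal order; columns: crossing id (1..C),
// over flag (1/0), sign (+1/-1).  Returns the normalized Alexander
// coefficient vector (lowest degree first, value +1 at t = 1), or an empty
// vector if normalization fails (non-unit value at t = 1).
// [[Rcpp::export]]
IntegerVector alexander_coeffs_cpp(IntegerVector crossing_id, IntegerVector over,
                                   IntegerVector sign) {
  const int len = crossing_id.size();
  const int C = len / 2;
  if (C == 0) return IntegerVector::create(1);
  // arcs: maximal runs between under-passages along the traversal
  std::vector<int> under_pos;
  for (int i = 0; i < len; ++i)
    if (!over[i]) under_pos.push_back(i);
  // Arc j is the run that starts just after the j-th under-passage; a
  // non-under position p with u_j < p < u_{j+1} therefore lies on arc j,
  // and positions before the first under-passage wrap onto arc C-1.
  auto arc_at = [&](int p) {
    int cnt = 0;
    for (int u : under_pos)
      if (u < p) ++cnt;
    return (cnt - 1 + C) % C;
  };
  // per crossing: over arc, incoming under arc, outgoing under arc, sign
  std::vector<int> over_arc(C + 1, -1), in_arc(C + 1, -1), out_arc(C + 1, -1),
      csign(C + 1, 0);
  for (int i = 0; i < len; ++i) {
    int id = crossing_id[i];
    csign[id] = sign[i];
    if (over[i]) {
      over_arc[id] = arc_at(i);
    } else {
      int j = 0;
      while (under_pos[j] != i) ++j;
      in_arc[id] = ((j - 1) % C + C) % C;  // arc ending at this under-passage
      out_arc[id] = j % C;
    }
  }
  if (C == 1) return IntegerVector::create(1);  // reduced by R1; unknotted kink
  // evaluate det of the (C-1)x(C-1) minor at C distinct points, interpolate
  const int D = C;  // degree bound of the (C-1)-minor determinant
  std::vector<int64_t> ts(D), vals(D);
  for (int q = 0; q < D; ++q) {
    int64_t t = 2 + q;
    std::vector<std::vector<int64_t>> mat(C - 1, std::vector<int64_t>(C - 1, 0));
    auto add_entry = [&](int row, int arc, int64_t coef) {
      if (row >= C - 1 || arc >= C - 1) return;  // delete last row and column
      mat[row][arc] = addp(mat[row][arc], (coef % P + P) % P);
    };
    for (int id = 1; id <= C; ++id) {
      int row = id - 1;
      if (csign[id] > 0) {
        add_entry(row, over_arc[id], subp(1, t));  // 1 - t
        add_entry(row, in_arc[id], t);
        add_entry(row, out_arc[id], P - 1);  // -1
      } else {
        add_entry(row, over_arc[id], subp(t, 1));  // t - 1
        add_entry(row, in_arc[id], 1);
        add_entry(row, out_arc[id], P - t);  // -t
      }
    }
    ts[q] = t;
    vals[q] = detp(mat);
  }
  // Lagrange interpolation of the degree <= D-1 polynomial
  std::vector<int64_t> coef(D, 0);
  for (int q = 0; q < D; ++q) {
    // basis polynomial prod_{r != q} (x - t_r) / (t_q - t_r)
    std::vector<int64_t> num(1, 1);
    int64_t den = 1;
    for (int r = 0; r < D; ++r) {
      if (r == q) continue;
      std::vector<int64_t> next(num.size() + 1, 0);
      for (size_t k = 0; k < num.size(); ++k) {
        next[k + 1] = addp(next[k + 1], num[k]);
        next[k] = subp(next[k], mulp(num[k], ts[r]));
      }
      num.swap(next);
      den = mulp(den, subp(ts[q], ts[r]));
    }
    int64_t f = mulp(vals[q], invp(den));
    for (size_t k = 0; k < num.size(); ++k) coef[k] = addp(coef[k], mulp(num[k], f));
  }
  // strip powers of t and trailing zeros
  int lo = 0, hi = D - 1;
  while (hi >= 0 && coef[hi] == 0) --hi;
  if (hi < 0) return IntegerVector(0);  // zero determinant: presentation defect
  while (coef[lo] == 0) ++lo;
  // normalize so the value at t = 1 is +1
  int64_t at1 = 0;
  for (int k = lo; k <= hi; ++k) at1 = addp(at1, coef[k]);
  if (at1 == P - 1) {
    for (int k = lo; k <= hi; ++k) coef[k] = subp(0, coef[k]);
  } else if (at1 != 1) {
    return IntegerVector(0);  // |Delta(1)| != 1: not a valid knot diagram
  }
  IntegerVector out(hi - lo + 1);
  for (int k = lo; k <= hi; ++k) {
    int64_t c = coef[k];
    out[k - lo] = static_cast<int>(c > P / 2 ? c - P : c);  // symmetric lift
  }
  return out;
}
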