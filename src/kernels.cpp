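#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Score every window of an integer-encoded sequence against one PWM.
//
// seq: 1=A, 2=C, 3=G, 4=T, 0=ambiguous.  W is the 4 x L matrix of
// information-weighted frequencies info[i] * f(i, b); wN[i] is the
// ambiguous-base contribution at position i (info[i] * mean_b f(i, b)).
// minS/maxS are the per-position minimum/maximum weighted sums, so the
// returned score is the normalized similarity in [0, 1].  A degenerate
// matrix (maxS == minS) scores every window 1.
// [[Rcpp::export]]
NumericVector scan_scores_cpp(IntegerVector seq, NumericMatrix W,
                              NumericVector wN, double minS, double maxS) {
  const int L = W.ncol();
  const int n = seq.size();
  const int noff = n - L + 1;
  if (noff < 1) return NumericVector(0);
  NumericVector out(noff);
  const double denom = maxS - minS;
  for (int o = 0; o < noff; ++o) {
    double s = 0.0;
    for (int i = 0; i < L; ++i) {
      const int b = seq[o + i];
      s += (b >= 1 && b <= 4) ? W(b - 1, i) : wN[i];
    }
    out[o] = denom > 0.0 ? (s - minS) / denom : 1.0;
  }
  return out;
}

// One step of the MARS forward pass: find the (parent term, column, knot)
// whose reflected hinge pair gives the largest exact RSS decrease when the
// whole model is refitted by least squares.
//
// Q:       n x m orthonormal basis of the current model (includes the
//          normalized intercept), r: current residual (orthogonal to Q).
// B:       n x P raw parent basis columns (column 1 is the intercept).
// X:       n x p predictor matrix; ord: n x p, 1-based ascending order
//          permutation of each column of X.
// knotpos: per column, 1-based positions into the sorted column marking the
//          last occurrence of each candidate knot value (ascending).
// allowed: P x p 0/1, whether a parent may be multiplied by a hinge on a
//          column (degree limit, no repeated column within a term).
//
// For a parent b, column x and knot c the pair is u = b * (x - c)+ and
// v = b * (c - x)+.  u and v have disjoint supports so u.v = 0, and every
// inner product needed is a prefix/suffix sum that is linear in c:
//   <u, w> = sum_{x_i > c} b_i w_i (x_i - c),  <v, w> = sum_{x_i < c} b_i w_i (c - x_i).
// The RSS decrease after Gram-Schmidt against Q (and u against v) is
//   <u~, r>^2 / |u~|^2 + <v~, r>^2 / |v~|^2.
// Ties are broken toward the lowest column index, then the lowest knot.
// [[Rcpp::export]]
List mars_best_candidate_cpp(NumericMatrix Q, NumericVector r,
                             NumericMatrix B, NumericMatrix X,
                             IntegerMatrix ord, List knotpos,
                             IntegerMatrix allowed) {
  const int n = Q.nrow();
  const int m = Q.ncol();
  const int P = B.ncol();
  const int p = X.ncol();

  double best = 0.0, bknot = NA_REAL;
  int bpar = -1, bcol = -1;

  std::vector<double> xs(n), rs(n), bs(n);
  std::vector<double> qs((size_t)n * m);   // row-major: qs[k*m + c]
  std::vector<double> T0q(m), T1q(m), A0(m), A1(m);

  for (int j = 0; j < p; ++j) {
    IntegerVector kp = knotpos[j];
    const int K = kp.size();
    if (K == 0) continue;
    bool any_allowed = false;
    for (int a = 0; a < P; ++a) if (allowed(a, j)) { any_allowed = true; break; }
    if (!any_allowed) continue;

    // reorder the column, residual and Q once per column
    for (int k = 0; k < n; ++k) {
      const int i = ord(k, j) - 1;
      xs[k] = X(i, j);
      rs[k] = r[i];
      for (int c = 0; c < m; ++c) qs[(size_t)k * m + c] = Q(i, c);
    }

    for (int a = 0; a < P; ++a) {
      if (!allowed(a, j)) continue;

      // totals over all rows (suffix sums are total - prefix)
      double bb0 = 0, bb1 = 0, bb2 = 0, tr0 = 0, tr1 = 0;
      std::fill(T0q.begin(), T0q.end(), 0.0);
      std::fill(T1q.begin(), T1q.end(), 0.0);
      for (int k = 0; k < n; ++k) {
        const int i = ord(k, j) - 1;
        const double b = B(i, a);
        bs[k] = b;
        if (b == 0.0) continue;
        const double x = xs[k], bx = b * x;
        bb0 += b * b; bb1 += b * b * x; bb2 += b * b * x * x;
        tr0 += b * rs[k]; tr1 += bx * rs[k];
        const double *qrow = &qs[(size_t)k * m];
        for (int c = 0; c < m; ++c) {
          T0q[c] += b * qrow[c]; T1q[c] += bx * qrow[c];
        }
      }

      // ascending walk; evaluate at each candidate knot (prefix covers
      // x <= c, which is exact because both hinges vanish at x == c)
      double p0r = 0, p1r = 0, pb0 = 0, pb1 = 0, pb2 = 0;
      std::fill(A0.begin(), A0.end(), 0.0);
      std::fill(A1.begin(), A1.end(), 0.0);
      int ci = 0;
      for (int k = 0; k < n && ci < K; ++k) {
        const double b = bs[k], x = xs[k];
        if (b != 0.0) {
          const double bx = b * x;
          p0r += b * rs[k]; p1r += bx * rs[k];
          pb0 += b * b; pb1 += b * b * x; pb2 += bx * bx;
          const double *qrow = &qs[(size_t)k * m];
          for (int c2 = 0; c2 < m; ++c2) {
            A0[c2] += b * qrow[c2]; A1[c2] += bx * qrow[c2];
          }
        }
        if (k + 1 == kp[ci]) {
          const double cc = x;
          ++ci;
          const double dv = cc * p0r - p1r;
          const double vv = cc * cc * pb0 - 2.0 * cc * pb1 + pb2;
          const double du = (tr1 - p1r) - cc * (tr0 - p0r);
          const double uu = (bb2 - pb2) - 2.0 * cc * (bb1 - pb1)
            + cc * cc * (bb0 - pb0);
          double squ = 0, sqv = 0, cross = 0;
          for (int c2 = 0; c2 < m; ++c2) {
            const double quj = (T1q[c2] - A1[c2]) - cc * (T0q[c2] - A0[c2]);
            const double qvj = cc * A0[c2] - A1[c2];
            squ += quj * quj; sqv += qvj * qvj; cross -= quj * qvj;
          }
          double uut = uu - squ;
          if (uut < 0) uut = 0;
          const double tolu = 1e-10 * (uu + 1.0);
          double dec = 0.0, vvt, dvt;
          if (uut > tolu) {
            dec += du * du / uut;
            vvt = vv - sqv - cross * cross / uut;
            dvt = dv - cross * du / uut;
          } else {
            vvt = vv - sqv;
            dvt = dv;
          }
          const double tolv = 1e-10 * (vv + 1.0);
          if (vvt > tolv) dec += dvt * dvt / vvt;
          if (dec > best * (1.0 + 1e-12) && dec > 0.0) {
            best = dec; bpar = a + 1; bcol = j + 1; bknot = cc;
          }
        }
      }
    }
  }
  return List::create(_["parent"] = bpar, _["col"] = bcol,
                      _["knot"] = bknot, _["decrease"] = best);
}
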