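#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

// Lattice DPs behind the exact conditional scan-statistic computation.
//
// A "run" is a maximal block of consecutive occupied width-w cells of the
// scanned region. Sliding the window across a run, the window count performs
// a walk whose steps are the run's points in mod-w order: a point of cell i
// is a departure for the walk between cells i and i+1, and an arrival for
// the walk between cells i-1 and i. Because within-cell offsets are iid
// uniform, all interleavings are equally likely, and the probability that no
// walk ever reaches k is a count of constrained lattice paths.

// Fraction of interleavings of cnt[i] copies of each of r cell labels such
// that every prefix state c satisfies v[i] - c[i] + c[i+1] < k for all
// internal walks (all cells fully departing).
// [[Rcpp::export(name = ".run_frac_cpp")]]
double run_frac_cpp(IntegerVector v, int k) {
  int r = v.size();
  for (int i = 0; i < r; ++i) if (v[i] >= k) return 0.0;
  if (r == 1) return 1.0;
  std::vector<int> dims(r);
  long V = 1;
  for (int i = 0; i < r; ++i) { dims[i] = v[i] + 1; V *= dims[i]; }
  std::vector<long> stride(r);
  stride[0] = 1;
  for (int i = 1; i < r; ++i) stride[i] = stride[i - 1] * dims[i - 1];
  std::vector<double> f(V, 0.0);
  std::vector<int> c(r, 0);
  f[0] = 1.0;  // all-zero prefix is valid because all v[i] < k
  for (long q = 1; q < V; ++q) {
    long rem = q;
    bool valid = true;
    for (int i = 0; i < r; ++i) { c[i] = (int)(rem % dims[i]); rem /= dims[i]; }
    for (int i = 0; i + 1 < r; ++i)
      if (v[i] - c[i] + c[i + 1] >= k) { valid = false; break; }
    if (!valid) continue;
    double tot = 0.0;
    for (int j = 0; j < r; ++j) if (c[j] > 0) {
      bool pv = true;
      c[j] -= 1;  // predecessor: only constraints touching j can change
      if (j + 1 < r && v[j] - c[j] + c[j + 1] >= k) pv = false;
      if (pv && j > 0 && v[j - 1] - c[j - 1] + c[j] >= k) pv = false;
      c[j] += 1;
      if (pv) tot += f[q - stride[j]];
    }
    f[q] = tot;
  }
  double lmn = R::lgammafn(1.0 + std::accumulate(v.begin(), v.end(), 0));
  for (int i = 0; i < r; ++i) lmn -= R::lgammafn(1.0 + v[i]);
  return f[V - 1] / std::exp(lmn);
}

// Stage DP for a terminal run (ends at the final, possibly truncated cell).
// Points split into segment-1 (offset < r') and segment-2 (offset >= r');
// all segment-1 events precede segment-2 events in phase order. The cell
// adjacent to the final cell only departs with its segment-1 points.
static double stage_frac(const std::vector<int>& cnt, const std::vector<int>& m1,
                         const IntegerVector& v, int k, int stage) {
  int r = (int)cnt.size();
  long V = 1;
  std::vector<int> dims(r);
  for (int i = 0; i < r; ++i) { dims[i] = cnt[i] + 1; V *= dims[i]; }
  if (V == 1) return 1.0;
  std::vector<long> stride(r);
  stride[0] = 1;
  for (int i = 1; i < r; ++i) stride[i] = stride[i - 1] * dims[i - 1];
  std::vector<double> f(V, 0.0);
  std::vector<int> c(r, 0), u1(r), u2(r);
  auto ok = [&](const std::vector<int>& cc) {
    for (int i = 0; i < r; ++i) {
      if (stage == 1) { u1[i] = cc[i]; u2[i] = 0; }
      else           { u1[i] = m1[i]; u2[i] = cc[i]; }
    }
    for (int i = 0; i + 1 < r; ++i) {
      int dep = (i <= r - 3) ? (u1[i] + u2[i]) : u1[i];
      int arr = u1[i + 1] + u2[i + 1];
      if (v[i] - dep + arr >= k) return false;
    }
    return true;
  };
  std::vector<int> zero(r, 0);
  if (!ok(zero)) return 0.0;
  f[0] = 1.0;
  for (long q = 1; q < V; ++q) {
    long rem = q;
    for (int i = 0; i < r; ++i) { c[i] = (int)(rem % dims[i]); rem /= dims[i]; }
    if (!ok(c)) continue;
    double tot = 0.0;
    for (int j = 0; j < r; ++j) if (c[j] > 0) {
      c[j] -= 1;
      bool pv = ok(c);
      c[j] += 1;
      if (pv) tot += f[q - stride[j]];
    }
    f[q] = tot;
  }
  double lmn = R::lgammafn(1.0 + std::accumulate(cnt.begin(), cnt.end(), 0));
  for (int i = 0; i < r; ++i) lmn -= R::lgammafn(1.0 + cnt[i]);
  return f[V - 1] / std::exp(lmn);
}

// No-hit fraction for a terminal run whose last cell is the truncated final
// cell (width r' = q1 * w). Full cells split binomially between segments.
// [[Rcpp::export(name = ".term_frac_cpp")]]
double term_frac_cpp(IntegerVector v, int k, double q1) {
  int r = v.size();
  for (int i = 0; i < r; ++i) if (v[i] >= k) return 0.0;
  if (r == 1) return 1.0;
  if (q1 >= 1.0 - 1e-12) return run_frac_cpp(v, k);
  int nf = r - 1;
  std::vector<int> sdims(nf);
  long NS = 1;
  for (int i = 0; i < nf; ++i) { sdims[i] = v[i] + 1; NS *= sdims[i]; }
  double tot = 0.0;
  std::vector<int> m1(r), m2(r);
  for (long s = 0; s < NS; ++s) {
    long rem = s;
    double wgt = 1.0;
    for (int i = 0; i < nf; ++i) {
      m1[i] = (int)(rem % sdims[i]); rem /= sdims[i];
      wgt *= R::dbinom(m1[i], v[i], q1, 0);
    }
    m1[r - 1] = v[r - 1];  // final-cell points all lie in segment 1
    if (wgt < 1e-16) continue;
    for (int i = 0; i < r; ++i) m2[i] = v[i] - m1[i];
    double f1 = stage_frac(m1, m1, v, k, 1);
    if (f1 <= 0.0) continue;
    double f2 = stage_frac(m2, m1, v, k, 2);
    tot += wgt * f1 * f2;
  }
  return tot;
}
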