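// Periodic-geometry kernels shared by all distance-based analyses.
// Brute-force O(N_A * N_B) pair scans: system sizes here (<= ~4e4 atoms,
// selections usually far smaller) make cell lists unnecessary.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// wrap a scalar displacement into (-L/2, L/2]
static inline double wrap1(double d, double L) {
  d -= L * std::round(d / L);
  if (d <= -0.5 * L) d += L;
  return d;
}

// [[Rcpp::export]]
NumericMatrix cpp_min_image(NumericMatrix a, NumericMatrix b, NumericVector box) {
  int n = a.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k)
      out(i, k) = wrap1(b(i, k) - a(i, k), box[k]);
  return out;
}

// All pairs (i in A, j in B) with minimum-image distance <= cutoff.
// Returns 1-based indices and the distances.
// [[Rcpp::export]]
List cpp_pairs_within(NumericMatrix A, NumericMatrix B, NumericVector box,
                      double cutoff, bool exclude_same_index = false) {
  int na = A.nrow(), nb = B.nrow();
  double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  std::vector<double> dd;
  for (int i = 0; i < na; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      if (exclude_same_index && i == j) continue;
      double dx = wrap1(B(j, 0) - ax, box[0]);
      if (std::fabs(dx) > cutoff) continue;
      double dy = wrap1(B(j, 1) - ay, box[1]);
      if (std::fabs(dy) > cutoff) continue;
      double dz = wrap1(B(j, 2) - az, box[2]);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["d"] = wrap(dd));
}

// Histogram of minimum-image pair distances below rmax (bin width rmax/nbins).
// [[Rcpp::export]]
NumericVector cpp_dist_hist(NumericMatrix A, NumericMatrix B, NumericVector box,
                            double rmax, int nbins, bool exclude_same_index = false) {
  int na = A.nrow(), nb = B.nrow();
  double r2max = rmax * rmax, dr = rmax / nbins;
  NumericVector h(nbins);
  for (int i = 0; i < na; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      if (exclude_same_index && i == j) continue;
      double dx = wrap1(B(j, 0) - ax, box[0]);
      if (std::fabs(dx) > rmax) continue;
      double dy = wrap1(B(j, 1) - ay, box[1]);
      if (std::fabs(dy) > rmax) continue;
      double dz = wrap1(B(j, 2) - az, box[2]);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < r2max) {
        int b = (int)(std::sqrt(d2) / dr);
        if (b >= 0 && b < nbins) h[b] += 1.0;
      }
    }
  }
  return h;
}

// For each row of A: index (1-based) of the nearest row of B and the distance.
// [[Rcpp::export]]
List cpp_nearest(NumericMatrix A, NumericMatrix B, NumericVector box) {
  int na = A.nrow(), nb = B.nrow();
  IntegerVector idx(na);
  NumericVector dist(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    int bj = -1;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = wrap1(B(j, 0) - ax, box[0]);
      double dy = wrap1(B(j, 1) - ay, box[1]);
      double dz = wrap1(B(j, 2) - az, box[2]);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
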