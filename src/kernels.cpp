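#include <Rcpp.h>
using namespace Rcpp;

// Row-shuffle null for the co-innervation permutation test.
// S is the pairs x neurons statistic matrix. For every shuffle each
// neuron's (column's) values are independently permuted across pairs
// (rows) and re-summed per pair. Returns, per pair, the number of
// shuffles whose null sum is >= the observed sum. Uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector null_pair_sum_counts(NumericMatrix S, int n_shuffles) {
  const int P = S.nrow(), N = S.ncol();
  std::vector<double> obs(P, 0.0);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < P; ++i) obs[i] += S(i, j);

  IntegerVector counts(P);
  std::vector<int> idx(P);
  std::vector<double> nullsum(P);

  for (int s = 0; s < n_shuffles; ++s) {
    std::fill(nullsum.begin(), nullsum.end(), 0.0);
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i < P; ++i) idx[i] = i;
      // Fisher-Yates using R's uniform stream
      for (int i = P - 1; i > 0; --i) {
        int k = (int)(unif_rand() * (i + 1));
        if (k > i) k = i;
        std::swap(idx[i], idx[k]);
      }
      for (int i = 0; i < P; ++i) nullsum[i] += S(idx[i], j);
    }
    for (int i = 0; i < P; ++i)
      if (nullsum[i] >= obs[i]) ++counts[i];
  }
  return counts;
}

// Directed raw similarity between two tangent-augmented point clouds:
// for every query point take its nearest target point and accumulate
// sqrt(|u.v|) * exp(-d^2 / (2 sigma^2)). Coordinates in microns.
// [[Rcpp::export]]
double dotprops_raw_score(NumericMatrix qp, NumericMatrix qt,
                          NumericMatrix tp, NumericMatrix tt,
                          double sigma) {
  const int nq = qp.nrow(), nt = tp.nrow();
  const double denom = 2.0 * sigma * sigma;
  double total = 0.0;
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int bj = 0;
    const double x = qp(i, 0), y = qp(i, 1), z = qp(i, 2);
    for (int j = 0; j < nt; ++j) {
      const double dx = x - tp(j, 0), dy = y - tp(j, 1), dz = z - tp(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    const double dot = qt(i, 0) * tt(bj, 0) + qt(i, 1) * tt(bj, 1) +
                       qt(i, 2) * tt(bj, 2);
    total += std::sqrt(std::fabs(dot)) * std::exp(-best / denom);
  }
  return total;
}
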