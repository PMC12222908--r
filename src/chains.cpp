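#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Markov chain for the exact Hardy-Weinberg test on a multiallelic locus.
//
// Conditional on the allele counts, the null distribution of the genotype
// table (Levene) is the one induced by a uniformly random pairing of the 2n
// gene copies. The chain therefore performs random transpositions: pick two
// individuals, pick one gene copy from each, swap. Every move is accepted
// (the target is uniform over labelled pairings) and the induced table
// distribution is the conditional null. The p-value is the chain fraction
// of tables whose conditional probability does not exceed the observed
// table's, with a batch-means standard error.
//
// The table log-probability up to an additive constant is
//   h * log(2) - sum_g log(n_g!)
// over genotype cells g with counts n_g, h = number of heterozygotes.

static inline int cellIndex(int a, int b, int k) {
  if (a > b) std::swap(a, b);
  return a * k + b;
}

// [[Rcpp::export]]
List hwe_chain_cpp(IntegerVector a1, IntegerVector a2, int k,
                   int demem, int batches, int stepsPerBatch) {
  int n = a1.size();
  std::vector<int> c1(a1.begin(), a1.end());  // 0-based allele codes
  std::vector<int> c2(a2.begin(), a2.end());
  std::vector<int> cells(k * k, 0);

  double sumLfact = 0.0;
  int het = 0;
  for (int i = 0; i < n; ++i) {
    int idx = cellIndex(c1[i], c2[i], k);
    cells[idx] += 1;
    if (c1[i] != c2[i]) ++het;
  }
  for (int g = 0; g < k * k; ++g)
    if (cells[g] > 0) sumLfact += lgamma((double)cells[g] + 1.0);

  const double log2 = std::log(2.0);
  double logProb = het * log2 - sumLfact;
  const double logProbObs = logProb;
  const double eps = 1e-9;

  long totalSteps = (long)demem + (long)batches * stepsPerBatch;
  NumericVector batchMeans(batches);
  long step = 0;
  int batch = -1;
  long hits = 0;

  for (step = 0; step < totalSteps; ++step) {
    // propose: two distinct individuals, one copy each, swap
    int u = (int)(unif_rand() * n); if (u == n) u = n - 1;
    int v = (int)(unif_rand() * (n - 1)); if (v == n - 1) v = n - 2;
    if (v >= u) ++v;
    bool pu = unif_rand() < 0.5, pv = unif_rand() < 0.5;
    int au = pu ? c1[u] : c2[u];
    int av = pv ? c1[v] : c2[v];
    if (au != av) {
      int oldU = cellIndex(c1[u], c2[u], k);
      int oldV = cellIndex(c1[v], c2[v], k);
      // remove old cells from the statistic
      sumLfact -= lgamma((double)cells[oldU] + 1.0);
      cells[oldU] -= 1;
      sumLfact += lgamma((double)cells[oldU] + 1.0);
      sumLfact -= lgamma((double)cells[oldV] + 1.0);
      cells[oldV] -= 1;
      sumLfact += lgamma((double)cells[oldV] + 1.0);
      if (c1[u] != c2[u]) --het;
      if (c1[v] != c2[v]) --het;
      // swap
      if (pu) c1[u] = av; else c2[u] = av;
      if (pv) c1[v] = au; else c2[v] = au;
      int newU = cellIndex(c1[u], c2[u], k);
      int newV = cellIndex(c1[v], c2[v], k);
      sumLfact -= lgamma((double)cells[newU] + 1.0);
      cells[newU] += 1;
      sumLfact += lgamma((double)cells[newU] + 1.0);
      sumLfact -= lgamma((double)cells[newV] + 1.0);
      cells[newV] += 1;
      sumLfact += lgamma((double)cells[newV] + 1.0);
      if (c1[u] != c2[u]) ++het;
      if (c1[v] != c2[v]) ++het;
      logProb = het * log2 - sumLfact;
    }
    if (step >= demem) {
      long rec = step - demem;
      if (rec % stepsPerBatch == 0) {
        if (batch >= 0)
          batchMeans[batch] = (double)hits / stepsPerBatch;
        ++batch;
        hits = 0;
      }
      if (logProb <= logProbObs + eps) ++hits;
    }
  }
  if (batch >= 0) batchMeans[batch] = (double)hits / stepsPerBatch;

  double p = 0.0;
  for (int b = 0; b < batches; ++b) p += batchMeans[b];
  p /= batches;
  double v = 0.0;
  for (int b = 0; b < batches; ++b)
    v += (batchMeans[b] - p) * (batchMeans[b] - p);
  double se = batches > 1 ? std::sqrt(v / (batches - 1) / batches) : NA_REAL;

  return List::create(_["p"] = p, _["se"] = se, _["batchMeans"] = batchMeans);
}

// Metropolis sampler for the Ewens sampling formula conditional on the
// number of gene copies g and the number of distinct alleles k.
//
// In the ordered allele-count representation (n_1, ..., n_k) the
// conditional null satisfies P(n) proportional to prod_i 1/n_i. The chain
// moves one copy from class i to class j (i, j uniform, move invalid when
// n_i == 1) and accepts with probability
//   min(1, n_i * n_j / ((n_i - 1) * (n_j + 1))).
// Returns homozygosity samples F = sum_i (n_i/g)^2 thinned after burn-in.

// [[Rcpp::export]]
NumericVector ew_chain_cpp(int g, int k, int nSamples, int thin, int burn) {
  std::vector<int> cnt(k, 0);
  for (int i = 0; i < k; ++i) cnt[i] = 1;
  int rest = g - k;
  for (int i = 0; rest > 0; i = (i + 1) % k) { cnt[i] += 1; --rest; }

  NumericVector F(nSamples);
  long total = (long)burn + (long)nSamples * thin;
  int got = 0;
  double sumSq = 0.0;
  for (int i = 0; i < k; ++i) sumSq += (double)cnt[i] * cnt[i];

  for (long step = 0; step < total; ++step) {
    int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
    if (j >= i) ++j;
    if (cnt[i] > 1) {
      double ratio = ((double)cnt[i] * cnt[j]) /
                     (((double)cnt[i] - 1.0) * ((double)cnt[j] + 1.0));
      if (ratio >= 1.0 || unif_rand() < ratio) {
        sumSq -= (double)cnt[i] * cnt[i] + (double)cnt[j] * cnt[j];
        cnt[i] -= 1; cnt[j] += 1;
        sumSq += (double)cnt[i] * cnt[i] + (double)cnt[j] * cnt[j];
      }
    }
    if (step >= burn && (step - burn) % thin == thin - 1) {
      F[got++] = sumSq / ((double)g * g);
      if (got == nSamples) break;
    }
  }
  return F;
}
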