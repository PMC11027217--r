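#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted sampling without replacement for many draws sharing one weight
// vector (Efraimidis-Spirakis exponential keys). Returns 1-based item
// indices, concatenated in the order of `d`. Uses the R RNG so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".sample_wor_many")]]
IntegerVector sample_wor_many(IntegerVector d, NumericVector w) {
  const int K = w.size();
  int positive = 0;
  for (int k = 0; k < K; ++k) {
    if (w[k] < 0) stop("weights must be non-negative");
    if (w[k] > 0) ++positive;
  }
  long long total = 0;
  for (int u = 0; u < d.size(); ++u) {
    if (d[u] < 0) stop("draw counts must be non-negative");
    if (d[u] > positive) stop("requested more distinct items than have positive weight");
    total += d[u];
  }
  IntegerVector out(total);
  std::vector< std::pair<double, int> > keys(K);
  long long pos = 0;
  for (int u = 0; u < d.size(); ++u) {
    const int du = d[u];
    if (du == 0) continue;
    for (int k = 0; k < K; ++k) {
      double key = (w[k] > 0) ? R::exp_rand() / w[k] : R_PosInf;
      keys[k] = std::make_pair(key, k);
    }
    std::partial_sort(keys.begin(), keys.begin() + du, keys.end());
    for (int t = 0; t < du; ++t) out[pos++] = keys[t].second + 1;
  }
  return out;
}

// One replicate of the label-shuffle null model for a single age bin.
// slots holds the observed patient-drug occurrences (0-based pool indices),
// patient u owning slots [offs[u], offs[u+1]). The drug column is permuted
// (Fisher-Yates, R RNG), within-patient duplicates are repaired by random
// swaps that keep both patients duplicate-free, then npairs[u] distinct
// pairs are drawn from the patient's shuffled drug set and checked against
// the sorted interaction keys (a * K + b, a < b). Returns one interacting
// flag per patient.
// [[Rcpp::export(name = ".null_rep_shuffle")]]
LogicalVector null_rep_shuffle(IntegerVector slots, IntegerVector offs,
                               IntegerVector npairs, NumericVector ddi_keys,
                               int K) {
  const int S = slots.size();
  const int n = offs.size() - 1;
  std::vector<int> perm(slots.begin(), slots.end());
  // Fisher-Yates
  for (int i = S - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }
  // repair within-patient duplicates
  std::vector<char> seen(K, 0);
  for (int u = 0; u < n; ++u) {
    const int lo = offs[u], hi = offs[u + 1];
    for (int tries = 0; tries < 100; ++tries) {
      int dup = -1;
      std::fill(seen.begin(), seen.end(), 0);
      for (int i = lo; i < hi; ++i) {
        if (seen[perm[i]] && dup < 0) dup = i;
        seen[perm[i]] = 1;
      }
      if (dup < 0) break;
      int j = (int)(unif_rand() * S);
      if (j >= S) j = S - 1;
      if (j >= lo && j < hi) continue;
      // candidate drug must be new to u; dup's drug must be new to j's owner
      if (seen[perm[j]]) continue;
      int v = std::upper_bound(offs.begin(), offs.end(), j) - offs.begin() - 1;
      bool other_ok = true;
      for (int i = offs[v]; i < offs[v + 1]; ++i)
        if (i != j && perm[i] == perm[dup]) { other_ok = false; break; }
      if (!other_ok) continue;
      std::swap(perm[j], perm[dup]);
    }
  }
  LogicalVector out(n);
  const double *ddi_begin = ddi_keys.begin(), *ddi_end = ddi_keys.end();
  std::vector<int> drugs;
  std::vector<long long> chosen;
  for (int u = 0; u < n; ++u) {
    drugs.assign(perm.begin() + offs[u], perm.begin() + offs[u + 1]);
    std::sort(drugs.begin(), drugs.end());
    drugs.erase(std::unique(drugs.begin(), drugs.end()), drugs.end());
    const int du = (int)drugs.size();
    const long long P = (long long)du * (du - 1) / 2;
    long long m = npairs[u];
    if (m > P) m = P;
    if (m <= 0 || du < 2) { out[u] = FALSE; continue; }
    chosen.clear();
    for (long long j = P - m; j < P; ++j) {
      long long t = (long long)(unif_rand() * (double)(j + 1));
      if (t > j) t = j;
      if (std::find(chosen.begin(), chosen.end(), t) != chosen.end())
        chosen.push_back(j);
      else
        chosen.push_back(t);
    }
    bool hit = false;
    for (size_t c = 0; c < chosen.size() && !hit; ++c) {
      long long r = chosen[c];
      int a = 0;
      while (r >= du - 1 - a) { r -= du - 1 - a; ++a; }
      int b = a + 1 + (int)r;
      double key = (double)drugs[a] * K + drugs[b];
      hit = std::binary_search(ddi_begin, ddi_end, key);
    }
    out[u] = hit;
  }
  return out;
}

// One replicate of the polypharmacy-preserving null model for a single age
// bin. Each patient u receives d[u] distinct drugs drawn from the bin pool
// (weights w), then npairs[u] distinct unordered pairs are drawn uniformly
// without replacement from the patient's sampled drug set (Floyd's
// algorithm). A patient is flagged as interacting when any drawn pair is in
// the interaction reference. ddi_keys must be sorted ascending and encode a
// pair of 0-based pool indices a < b as a * K + b (stored as double; exact
// for pools far below 2^26 drugs).
// [[Rcpp::export(name = ".null_rep_interacting")]]
LogicalVector null_rep_interacting(IntegerVector d, IntegerVector npairs,
                                   NumericVector w, NumericVector ddi_keys) {
  const int K = w.size();
  const int n = d.size();
  if (npairs.size() != n) stop("d and npairs must have equal length");
  LogicalVector out(n);
  std::vector< std::pair<double, int> > keys(K);
  std::vector<int> drugs;
  std::vector<long long> chosen;
  const double *ddi_begin = ddi_keys.begin(), *ddi_end = ddi_keys.end();
  for (int u = 0; u < n; ++u) {
    const int du = d[u];
    if (du > K) stop("patient has more distinct drugs than the bin pool");
    const long long P = (long long)du * (du - 1) / 2;
    long long m = npairs[u];
    if (m > P) m = P;  // callers log the cap
    if (m <= 0 || du < 2) { out[u] = FALSE; continue; }
    for (int k = 0; k < K; ++k) {
      double key = (w[k] > 0) ? R::exp_rand() / w[k] : R_PosInf;
      keys[k] = std::make_pair(key, k);
    }
    std::partial_sort(keys.begin(), keys.begin() + du, keys.end());
    drugs.assign(du, 0);
    for (int t = 0; t < du; ++t) drugs[t] = keys[t].second;
    // Floyd's algorithm: m distinct pair indices from [0, P)
    chosen.clear();
    for (long long j = P - m; j < P; ++j) {
      long long t = (long long)(unif_rand() * (double)(j + 1));
      if (t > j) t = j;
      if (std::find(chosen.begin(), chosen.end(), t) != chosen.end())
        chosen.push_back(j);
      else
        chosen.push_back(t);
    }
    bool hit = false;
    for (size_t c = 0; c < chosen.size() && !hit; ++c) {
      long long r = chosen[c];
      int a = 0;
      while (r >= du - 1 - a) { r -= du - 1 - a; ++a; }
      int b = a + 1 + (int)r;
      int da = drugs[a], db = drugs[b];
      if (da > db) std::swap(da, db);
      double key = (double)da * K + db;
      hit = std::binary_search(ddi_begin, ddi_end, key);
    }
    out[u] = hit;
  }
  return out;
}
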