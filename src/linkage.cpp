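#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Match keys arrive as doubles holding exact integers < 2^53
// (timestamp component * 1e5 + canonical value component).

// Nested-scan matcher: for each PAT row i and each of its keys j, scan every
// ERGO row k left to right until the key is found (early exit) or the row is
// exhausted. D[k][j] reduces to a per-row count E[k]; all rows attaining the
// maximum count are reported. Every key comparison is counted.
// pat/ergo are passed as flat key vectors plus row-offset vectors
// (offsets are 0-based, length nrow+1).
// [[Rcpp::export]]
List cpp_baseline_report(NumericVector pat_keys, IntegerVector pat_off,
                         NumericVector ergo_keys, IntegerVector ergo_off) {
  const int m = pat_off.size() - 1;
  const int p = ergo_off.size() - 1;
  double ops = 0.0;

  IntegerVector max_count(m);
  List argmax(m);
  std::vector<int> ecount(p);

  for (int i = 0; i < m; ++i) {
    const int js = pat_off[i], je = pat_off[i + 1];
    std::fill(ecount.begin(), ecount.end(), 0);
    for (int k = 0; k < p; ++k) {
      const int ls = ergo_off[k], le = ergo_off[k + 1];
      int e = 0;
      for (int j = js; j < je; ++j) {
        const double key = pat_keys[j];
        for (int l = ls; l < le; ++l) {
          ops += 1.0;
          if (ergo_keys[l] == key) { ++e; break; }
        }
      }
      ecount[k] = e;
    }
    int best = 0;
    for (int k = 0; k < p; ++k) if (ecount[k] > best) best = ecount[k];
    max_count[i] = best;
    std::vector<int> rows;
    if (best > 0)
      for (int k = 0; k < p; ++k)
        if (ecount[k] == best) rows.push_back(k + 1);
    argmax[i] = IntegerVector(rows.begin(), rows.end());
  }
  return List::create(_["max_count"] = max_count, _["argmax"] = argmax,
                      _["ops"] = ops);
}

struct TaggedPair {
  double key;
  int row;
};

static double sort_ops;  // comparisons made by std::sort (single-threaded)

static bool cmp_counted(const TaggedPair &a, const TaggedPair &b) {
  sort_ops += 1.0;
  if (a.key != b.key) return a.key < b.key;
  return a.row < b.row;
}

// Sort a tagged sequence by (key, row) with a counting comparator.
// Returns the permuted keys/rows and the number of comparisons performed.
// [[Rcpp::export]]
List cpp_sort_tagged(NumericVector keys, IntegerVector rows) {
  const R_xlen_t n = keys.size();
  std::vector<TaggedPair> v(n);
  for (R_xlen_t t = 0; t < n; ++t) v[t] = TaggedPair{keys[t], rows[t]};
  sort_ops = 0.0;
  std::sort(v.begin(), v.end(), cmp_counted);
  NumericVector ok(n);
  IntegerVector orow(n);
  for (R_xlen_t t = 0; t < n; ++t) { ok[t] = v[t].key; orow[t] = v[t].row; }
  return List::create(_["key"] = ok, _["row"] = orow, _["ops"] = sort_ops);
}

// Two-pointer merge of two (key, row)-sorted tagged sequences. For every
// equal-key block, count(i, k) is incremented for each combination of a PAT
// tag i and an ERGO tag k in the block. Returns sparse triplets.
// [[Rcpp::export]]
List cpp_merge_count(NumericVector s1_key, IntegerVector s1_row,
                     NumericVector s2_key, IntegerVector s2_row) {
  const R_xlen_t n1 = s1_key.size(), n2 = s2_key.size();
  double ops = 0.0;
  // (i,k) -> count accumulation; keys of blocks are disjoint so a given
  // (i,k) can recur across blocks — accumulate in a hash map.
  std::unordered_map<int64_t, int> acc;
  R_xlen_t a = 0, b = 0;
  while (a < n1 && b < n2) {
    ops += 1.0;
    if (s1_key[a] < s2_key[b]) { ++a; continue; }
    if (s1_key[a] > s2_key[b]) { ++b; continue; }
    const double key = s1_key[a];
    R_xlen_t ae = a, be = b;
    while (ae < n1 && s1_key[ae] == key) { ++ae; ops += 1.0; }
    while (be < n2 && s2_key[be] == key) { ++be; ops += 1.0; }
    for (R_xlen_t x = a; x < ae; ++x)
      for (R_xlen_t y = b; y < be; ++y) {
        ops += 1.0;
        ++acc[static_cast<int64_t>(s1_row[x]) * 0x80000000LL + s2_row[y]];
      }
    a = ae;
    b = be;
  }
  const R_xlen_t nout = acc.size();
  IntegerVector oi(nout), ok(nout), on(nout);
  R_xlen_t t = 0;
  for (const auto &kv : acc) {
    oi[t] = static_cast<int>(kv.first / 0x80000000LL);
    ok[t] = static_cast<int>(kv.first % 0x80000000LL);
    on[t] = kv.second;
    ++t;
  }
  return List::create(_["pat_row"] = oi, _["ergo_row"] = ok,
                      _["count"] = on, _["ops"] = ops);
}

// Report builder for the sort-merge matcher at scale. s1 is sorted by
// (row, key) so each PAT row's keys are contiguous; s2 is sorted by
// (key, row). Each PAT key's equal-key block in s2 is located by binary
// search and its ERGO tags accumulated into an O(p) scratch array, from
// which the row's max count and argmax set are read off. Memory stays
// O(p + output) even when degraded projections make the sparse count
// matrix enormous. Binary-search and block-scan steps are counted.
// [[Rcpp::export]]
List cpp_merge_report(NumericVector s1_key, IntegerVector s1_row,
                      NumericVector s2_key, IntegerVector s2_row,
                      int m, int p) {
  const R_xlen_t n2 = s2_key.size();
  double ops = 0.0;
  IntegerVector max_count(m);
  List argmax(m);
  std::vector<int> cnt(p + 1, 0);
  std::vector<int> touched;

  const double *k2 = REAL(s2_key);
  R_xlen_t a = 0;
  const R_xlen_t n1 = s1_key.size();
  while (a < n1) {
    const int i = s1_row[a];
    touched.clear();
    R_xlen_t ae = a;
    while (ae < n1 && s1_row[ae] == i) {
      const double key = s1_key[ae];
      // lower_bound with comparison counting
      R_xlen_t lo = 0, hi = n2;
      while (lo < hi) {
        ops += 1.0;
        const R_xlen_t mid = lo + (hi - lo) / 2;
        if (k2[mid] < key) lo = mid + 1; else hi = mid;
      }
      for (R_xlen_t y = lo; y < n2 && k2[y] == key; ++y) {
        ops += 1.0;
        const int k = s2_row[y];
        if (cnt[k] == 0) touched.push_back(k);
        ++cnt[k];
      }
      ++ae;
    }
    int best = 0;
    for (int k : touched) if (cnt[k] > best) best = cnt[k];
    max_count[i - 1] = best;
    std::vector<int> rows;
    for (int k : touched) {
      if (cnt[k] == best) rows.push_back(k);
      cnt[k] = 0;
    }
    std::sort(rows.begin(), rows.end());
    argmax[i - 1] = IntegerVector(rows.begin(), rows.end());
    a = ae;
  }
  for (int i = 0; i < m; ++i)
    if (argmax[i] == R_NilValue) argmax[i] = IntegerVector(0);
  return List::create(_["max_count"] = max_count, _["argmax"] = argmax,
                      _["ops"] = ops);
}
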