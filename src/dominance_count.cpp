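#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fenwick tree over p-ranks; used for offline 2-D dominance counting.
static inline void bit_add(std::vector<int>& t, int i) {
  for (; i < (int)t.size(); i += i & (-i)) t[i]++;
}
static inline int bit_sum(const std::vector<int>& t, int i) {
  int s = 0;
  for (; i > 0; i -= i & (-i)) s += t[i];
  return s;
}

// For each i, count #{j : p[j] <= p[i] && q[j] <= q[i]}, inclusive of i.
// Sweep in q order, processing blocks of tied q together so that ties on
// either axis use inclusive (<=) counts. O(N log N).
// [[Rcpp::export]]
IntegerVector joint_dominance_count(NumericVector p, NumericVector q) {
  const int n = p.size();
  IntegerVector out(n);
  if (n == 0) return out;

  std::vector<double> ps(p.begin(), p.end());
  std::sort(ps.begin(), ps.end());

  // insertion rank: ties get distinct slots; query rank: upper bound, so a
  // query at p[i] covers every slot whose value is <= p[i]
  std::vector<int> r_ins(n), r_qry(n);
  {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (p[a] != p[b]) return p[a] < p[b];
      return a < b;
    });
    for (int k = 0; k < n; ++k) r_ins[idx[k]] = k + 1;
  }
  for (int i = 0; i < n; ++i)
    r_qry[i] = (int)(std::upper_bound(ps.begin(), ps.end(), p[i]) - ps.begin());

  std::vector<int> qidx(n);
  for (int i = 0; i < n; ++i) qidx[i] = i;
  std::sort(qidx.begin(), qidx.end(), [&](int a, int b) { return q[a] < q[b]; });

  std::vector<int> tree(n + 1, 0);
  int s = 0;
  while (s < n) {
    int e = s;
    while (e < n && q[qidx[e]] == q[qidx[s]]) ++e;
    for (int k = s; k < e; ++k) bit_add(tree, r_ins[qidx[k]]);
    for (int k = s; k < e; ++k) out[qidx[k]] = bit_sum(tree, r_qry[qidx[k]]);
    s = e;
  }
  return out;
}
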