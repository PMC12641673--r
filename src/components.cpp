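#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling over a logical volume.
// dims: (d1, d2, d3) with the first index fastest (R column-major array).
// connectivity: 6, 18 or 26. Labels are assigned in linear scan order of
// each component's first voxel, so the labeling is deterministic.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector vol, IntegerVector dims, int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (vol.size() != n) stop("volume length does not match dims");

  // neighbor offsets as (a,b,c) steps
  std::vector<int> off_a, off_b, off_c;
  int maxsum;
  if (connectivity == 6) maxsum = 1;
  else if (connectivity == 18) maxsum = 2;
  else if (connectivity == 26) maxsum = 3;
  else stop("connectivity must be 6, 18 or 26");
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0 || s > maxsum) continue;
        off_a.push_back(a); off_b.push_back(b); off_c.push_back(c);
      }
  const int noff = (int)off_a.size();

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next_label = 0;

  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!vol[idx] || lab[idx] != 0) continue;
    ++next_label;
    lab[idx] = next_label;
    queue.clear();
    queue.push_back(idx);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t cur = queue[head++];
      int a = (int)(cur % d1);
      int b = (int)((cur / d1) % d2);
      int c = (int)(cur / ((R_xlen_t)d1 * d2));
      for (int k = 0; k < noff; ++k) {
        int na = a + off_a[k], nb = b + off_b[k], nc = c + off_c[k];
        if (na < 0 || na >= d1 || nb < 0 || nb >= d2 || nc < 0 || nc >= d3) continue;
        R_xlen_t nidx = na + (R_xlen_t)d1 * (nb + (R_xlen_t)d2 * nc);
        if (vol[nidx] && lab[nidx] == 0) {
          lab[nidx] = next_label;
          queue.push_back(nidx);
        }
      }
    }
  }
  lab.attr("n_components") = next_label;
  return lab;
}
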