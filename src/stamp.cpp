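#include <Rcpp.h>
using namespace Rcpp;

// Mark every voxel (center + offset) in a logical label array, in place.
// `centers` are 1-based linear indices of skeleton points; `offsets` are
// 0-based linear index offsets of the tubule cross-section ball. The label
// vector must be owned exclusively by the caller (freshly allocated per
// phantom) since it is modified without copying. Returns the number of
// voxels newly marked.
// [[Rcpp::export]]
int stamp_mark(LogicalVector label, IntegerVector centers,
               IntegerVector offsets) {
  const R_xlen_t nc = centers.size(), no = offsets.size();
  int* lab = LOGICAL(label);
  int fresh = 0;
  for (R_xlen_t j = 0; j < no; ++j) {
    const int off = offsets[j] - 1;  // 1-based center + offset -> 0-based
    for (R_xlen_t i = 0; i < nc; ++i) {
      const int idx = centers[i] + off;
      if (!lab[idx]) {
        lab[idx] = 1;
        ++fresh;
      }
    }
  }
  return fresh;
}
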