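// Training allocates and frees many large activation tensors per batch; on
// glibc each such allocation is served by mmap and costs a page-fault sweep.
// Raising the mmap/trim thresholds lets the heap recycle those blocks.

#include <Rcpp.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// [[Rcpp::export]]
void tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1024 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}
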