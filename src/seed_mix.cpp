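#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// SplitMix64 finalizer over (master, index): yields well-scattered,
// reproducible substream seeds in [1, 2^31 - 2] for set.seed(). A strong
// nonlinear mix avoids the lattice structure an affine combination of run
// and participant indices would imprint on the seed sequence.
// [[Rcpp::export]]
int mix_seed(double master, double index) {
  uint64_t z = (static_cast<uint64_t>(static_cast<uint32_t>(master)) << 32) ^
               static_cast<uint64_t>(static_cast<int64_t>(index));
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  z ^= z >> 31;
  return static_cast<int>(z % 2147483645ULL) + 1;
}
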