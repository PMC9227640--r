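// Compiled with -mavx2 -mfma (see Makevars); only ever called after a
// runtime __builtin_cpu_supports check.
#include <vector>
#include <algorithm>
#include <cstddef>
#define NAME(f) f##_avx2
#include "conv_cores.inc"
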