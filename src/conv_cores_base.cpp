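#include <vector>
#include <algorithm>
#include <cstddef>
#define NAME(f) f##_base
#include "conv_cores.inc"
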