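#ifndef EGAN3D_CONV_CORES_H
#define EGAN3D_CONV_CORES_H
#include <cstddef>

#define DECL_SET(SUF)                                                        \
  void conv3s1_core##SUF(const double*, const double*, const double*,        \
                         double*, int, int, int, int, int);                  \
  void conv3s1_gw_core##SUF(const double*, const double*, double*, double*,  \
                            int, int, int, int, int);                        \
  void conv4s2_core##SUF(const double*, const double*, const double*,        \
                         double*, int, int, int, int, int);                  \
  void conv4s2_grad_core##SUF(const double*, const double*, const double*,   \
                              double*, double*, double*, int, int, int,      \
                              int, int);
DECL_SET(_base)
DECL_SET(_avx2)
#undef DECL_SET

inline bool egan3d_use_avx2() {
#if defined(__GNUC__) && defined(__x86_64__)
  static const bool ok =
      __builtin_cpu_supports("avx2") && __builtin_cpu_supports("fma");
  return ok;
#else
  return false;
#endif
}

#define CONV_DISPATCH(fn, ...)                                               \
  (egan3d_use_avx2() ? fn##_avx2(__VA_ARGS__) : fn##_base(__VA_ARGS__))

#endif
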