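PKG_CXXFLAGS = -O3
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)

all: $(SHLIB)

conv_cores_avx2.o: conv_cores_avx2.cpp
	$(CXX) $(ALL_CPPFLAGS) $(ALL_CXXFLAGS) -mavx2 -mfma -c conv_cores_avx2.cpp -o conv_cores_avx2.o
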