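# The numerical core is dominated by vectorized elementwise loops and
# single-precision GEMM; build it at -O3 with the AVX2/FMA baseline that
# every contemporary x86-64 server provides (the toolchain's default
# -march is far older). `override` is needed because this file is read
# before the site Makeconf.
override CXXFLAGS += -O3 -mavx2 -mfma -mtune=haswell -ftree-vectorize
PKG_CXXFLAGS = -DARMA_NO_DEBUG
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
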