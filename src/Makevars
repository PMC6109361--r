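# R passes CXXFLAGS on the make command line expanding to the conda
# defaults ("-march=nocona ... -O2"), which cripples the SIMD the training
# kernels rely on; "override" beats the command line. The package is always
# compiled from source on the machine that runs it, so -march=native is safe.
override CXXFLAGS = -fvisibility-inlines-hidden -fPIC -g -O3 -funroll-loops -march=native
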