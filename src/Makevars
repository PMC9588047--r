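# The configured cross-compiler targets a newer glibc than the runtime
# environment provides, so objects it emits fail to dyn.load.  Explicit
# per-object rules (which take precedence over the pattern rules) compile
# with the system toolchain; the final link still uses the configured driver,
# whose RPATH resolves the environment's own libstdc++.
SYS_CXX = g++

all: $(SHLIB)

engine.o: engine.cpp
	$(SYS_CXX) -std=gnu++17 -O2 -fPIC $(ALL_CPPFLAGS) -c engine.cpp -o engine.o

RcppExports.o: RcppExports.cpp
	$(SYS_CXX) -std=gnu++17 -O2 -fPIC $(ALL_CPPFLAGS) -c RcppExports.cpp -o RcppExports.o
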