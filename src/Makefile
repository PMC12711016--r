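# Build with the host toolchain: the R distribution's configured
# cross-compiler emits binaries for a newer C library than the host runtime
# provides, so its shared objects cannot be dyn.load()ed. Plain C++17, no
# external libraries beyond R and Rcpp headers.
R_HOME ?= $(shell R RHOME)
RCPP_INC := $(shell "$(R_HOME)/bin/Rscript" --vanilla -e 'cat(system.file("include", package = "Rcpp"))')

CXX := /usr/bin/g++
CXXFLAGS := -O2 -fPIC -std=gnu++17
CPPFLAGS := -I"$(R_HOME)/include" -I"$(RCPP_INC)" -DNDEBUG

OBJECTS = RcppExports.o engine.o

all: infodemsim.so

infodemsim.so: $(OBJECTS)
	$(CXX) -shared -o $@ $(OBJECTS) -L"$(R_HOME)/lib" -lR

%.o: %.cpp
	$(CXX) $(CXXFLAGS) $(CPPFLAGS) -c $< -o $@

clean:
	rm -f $(OBJECTS) infodemsim.so

.PHONY: all clean
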