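# Build with the system C++ toolchain.
override CXX = g++
override CXX11 = g++
override CXX14 = g++
override CXX17 = g++
override CXX20 = g++
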