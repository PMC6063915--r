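# conda's cross compiler targets glibc 2.38 but the runtime loader is
# glibc 2.35; build with the system toolchain so the object loads.
override CC = /usr/bin/gcc
override CXX = /usr/bin/g++
override CXX17 = /usr/bin/g++
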