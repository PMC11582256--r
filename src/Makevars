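RHDF5_LIBS = $(shell echo 'Rhdf5lib::pkgconfig("PKG_C_LIBS")' | "${R_HOME}/bin/R" --vanilla --slave)
PKG_CPPFLAGS = -I$(shell echo 'cat(system.file("include", package="Rhdf5lib"))' | "${R_HOME}/bin/R" --vanilla --slave)
PKG_LIBS = $(RHDF5_LIBS)
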