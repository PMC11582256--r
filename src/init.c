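#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP C_h5_write_scan(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP C_h5_read_scan(SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_h5_write_scan", (DL_FUNC) &C_h5_write_scan, 6},
    {"C_h5_read_scan",  (DL_FUNC) &C_h5_read_scan,  1},
    {NULL, NULL, 0}
};

void R_init_mrisynth(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
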