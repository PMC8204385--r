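#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_set_mpdpde_parms(SEXP v);
SEXP C_mpdpde_rk4(SEXP times_, SEXP dt_, SEXP tswitch_);
void mpdpde_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
    {"C_set_mpdpde_parms", (DL_FUNC) &C_set_mpdpde_parms, 1},
    {"C_mpdpde_rk4", (DL_FUNC) &C_mpdpde_rk4, 3},
    {NULL, NULL, 0}
};

/* registered as a .C routine so deSolve's getNativeSymbolInfo finds it */
static const R_CMethodDef c_entries[] = {
    {"mpdpde_derivs", (DL_FUNC) &mpdpde_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_tetherspr(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
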