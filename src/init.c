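#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void spr_initmod(void (*odeparms)(int *, double *));
void spr_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);
SEXP C_coop_mc(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
               SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_coop_mc", (DL_FUNC) &C_coop_mc, 11},
    {NULL, NULL, 0}
};

/* deSolve looks the model functions up by name in this DLL */
static const R_CMethodDef CEntries[] = {
    {"spr_initmod", (DL_FUNC) &spr_initmod, 0},
    {"spr_derivs",  (DL_FUNC) &spr_derivs,  0},
    {NULL, NULL, 0}
};

void R_init_decorakin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
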