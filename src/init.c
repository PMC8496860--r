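#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void gal_initmod(void (*odeparms)(int *, double *));
void gal_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"gal_initmod", (DL_FUNC) &gal_initmod, 1},
    {"gal_derivs",  (DL_FUNC) &gal_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_galswitch(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
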