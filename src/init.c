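#include <R.h>
#include <R_ext/Rdynload.h>

void crm_initparms(void (*odeparms)(int *, double *));
void crm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"crm_initparms", (DL_FUNC) &crm_initparms, 1},
    {"crm_derivs",    (DL_FUNC) &crm_derivs,    6},
    {NULL, NULL, 0}
};

void R_init_soilregimes(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
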