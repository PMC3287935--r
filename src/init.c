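#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include "spikegene.h"

static const R_CallMethodDef callMethods[] = {
    {"C_rpg",       (DL_FUNC) &C_rpg,       2},
    {"C_run_chain", (DL_FUNC) &C_run_chain, 7},
    {NULL, NULL, 0}
};

void R_init_spikegene(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
    R_forceSymbols(info, TRUE);
}
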