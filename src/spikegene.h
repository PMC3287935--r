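#ifndef SPIKEGENE_H
#define SPIKEGENE_H

#include <Rinternals.h>

double spikegene_rpg1(double c);

SEXP C_rpg(SEXP n_, SEXP z_);
SEXP C_run_chain(SEXP y_, SEXP X_, SEXP Z_, SEXP prior_, SEXP config_,
                 SEXP init_, SEXP modes_);

#endif
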