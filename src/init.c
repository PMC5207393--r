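#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* .Call wrappers generated in RcppExports.cpp */
extern SEXP _tsp1net_term_fluxes_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _tsp1net_network_rhs_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                     SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                     SEXP);
extern SEXP _tsp1net_reaction_fluxes_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                         SEXP, SEXP, SEXP, SEXP);
extern SEXP _tsp1net_load_model_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                    SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

/* native solver entry points in rhs.cpp, resolved by deSolve */
extern void tsp1net_initmod(void (*odeparms)(int *, double *));
extern void tsp1net_derivs(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip);

static const R_CallMethodDef CallEntries[] = {
    {"_tsp1net_term_fluxes_cpp", (DL_FUNC) &_tsp1net_term_fluxes_cpp, 7},
    {"_tsp1net_network_rhs_cpp", (DL_FUNC) &_tsp1net_network_rhs_cpp, 15},
    {"_tsp1net_reaction_fluxes_cpp", (DL_FUNC) &_tsp1net_reaction_fluxes_cpp, 10},
    {"_tsp1net_load_model_cpp", (DL_FUNC) &_tsp1net_load_model_cpp, 14},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"tsp1net_initmod", (DL_FUNC) &tsp1net_initmod, 1},
    {"tsp1net_derivs", (DL_FUNC) &tsp1net_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_tsp1net(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
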