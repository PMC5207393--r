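#include <Rcpp.h>
using namespace Rcpp;

// Factor kinds (must stay in sync with R/rate-laws.R):
//  1 pow        f = S1^p1
//  2 sat        f = S1 / (p1 + S1)
//  3 hill_act   f = S1^p2 / (p1^p2 + S1^p2)
//  4 hill_rep   f = p1^p2 / (p1^p2 + S1^p2)
//  5 fold_act   f = 1 + p3 * hill_act(S1; p1, p2)
//  6 fold_rep   f = 1 / (1 + p3 * hill_act(S1; p1, p2))
//  7 ratio_hill_act  M = S1/(1 + S2/p3); f = hill_act(M; p1, p2)
//  8 ratio_fold_act  M = S1/(1 + S2/p4); f = 1 + p3 * hill_act(M; p1, p2)
//  9 ratio_fold_rep  M = S1/(1 + S2/p4); f = 1 / (1 + p3 * hill_act(M; p1, p2))
// Concentrations are clamped at 0 from below so that transient small negative
// values produced by the integrator cannot generate NaNs in fractional powers.

static inline double hill(double s, double K, double n) {
  if (s <= 0.0) return 0.0;
  double sn = pow(s, n), Kn = pow(K, n);
  return sn / (Kn + sn);
}

static inline double eval_factor(int kind, double s1, double s2,
                                 double p1, double p2, double p3, double p4) {
  if (s1 < 0.0) s1 = 0.0;
  if (s2 < 0.0) s2 = 0.0;
  switch (kind) {
  case 1: return (p1 == 1.0) ? s1 : pow(s1, p1);
  case 2: return s1 / (p1 + s1);
  case 3: return hill(s1, p1, p2);
  case 4: return 1.0 - hill(s1, p1, p2);
  case 5: return 1.0 + p3 * hill(s1, p1, p2);
  case 6: return 1.0 / (1.0 + p3 * hill(s1, p1, p2));
  case 7: return hill(s1 / (1.0 + s2 / p3), p1, p2);
  case 8: return 1.0 + p3 * hill(s1 / (1.0 + s2 / p4), p1, p2);
  case 9: return 1.0 / (1.0 + p3 * hill(s1 / (1.0 + s2 / p4), p1, p2));
  default: Rcpp::stop("unknown factor kind");
  }
  return NA_REAL;
}

// Flux of every elementary term (forward or reverse half of a reaction).
// [[Rcpp::export(name = ".term_fluxes_cpp")]]
NumericVector term_fluxes_cpp(NumericVector state, NumericVector k_term,
                              IntegerVector fct_term, IntegerVector fct_kind,
                              IntegerVector fct_s1, IntegerVector fct_s2,
                              NumericMatrix fct_par) {
  int nterm = k_term.size(), nf = fct_term.size();
  NumericVector f(clone(k_term));
  for (int j = 0; j < nf; j++) {
    int t = fct_term[j];
    double s1 = fct_s1[j] >= 0 ? state[fct_s1[j]] : 0.0;
    double s2 = fct_s2[j] >= 0 ? state[fct_s2[j]] : 0.0;
    f[t] *= eval_factor(fct_kind[j], s1, s2,
                        fct_par(j, 0), fct_par(j, 1), fct_par(j, 2), fct_par(j, 3));
  }
  return f;
}

// Time derivative of the state: dx = S %*% (signed term fluxes), clamped
// species forced to zero derivative.
// [[Rcpp::export(name = ".network_rhs_cpp")]]
NumericVector network_rhs_cpp(NumericVector state, NumericVector k_term,
                              IntegerVector term_sign, IntegerVector term_rxn,
                              IntegerVector fct_term, IntegerVector fct_kind,
                              IntegerVector fct_s1, IntegerVector fct_s2,
                              NumericMatrix fct_par,
                              IntegerVector st_sp, IntegerVector st_rxn,
                              NumericVector st_coef,
                              IntegerVector clamped, int nspec, int nrxn) {
  NumericVector tf = term_fluxes_cpp(state, k_term, fct_term, fct_kind,
                                     fct_s1, fct_s2, fct_par);
  std::vector<double> rflux(nrxn, 0.0);
  for (int i = 0; i < tf.size(); i++)
    rflux[term_rxn[i]] += term_sign[i] * tf[i];
  NumericVector dx(nspec);
  for (int i = 0; i < st_sp.size(); i++)
    dx[st_sp[i]] += st_coef[i] * rflux[st_rxn[i]];
  for (int i = 0; i < clamped.size(); i++)
    dx[clamped[i]] = 0.0;
  return dx;
}

// Net flux per reaction (forward minus reverse), used for flux readouts.
// [[Rcpp::export(name = ".reaction_fluxes_cpp")]]
NumericVector reaction_fluxes_cpp(NumericVector state, NumericVector k_term,
                                  IntegerVector term_sign, IntegerVector term_rxn,
                                  IntegerVector fct_term, IntegerVector fct_kind,
                                  IntegerVector fct_s1, IntegerVector fct_s2,
                                  NumericMatrix fct_par, int nrxn) {
  NumericVector tf = term_fluxes_cpp(state, k_term, fct_term, fct_kind,
                                     fct_s1, fct_s2, fct_par);
  NumericVector rflux(nrxn);
  for (int i = 0; i < tf.size(); i++)
    rflux[term_rxn[i]] += term_sign[i] * tf[i];
  return rflux;
}

// ---------------------------------------------------------------------------
// Native right-hand side for deSolve: the compiled network is staged into
// module-level storage with load_model_cpp(), after which the integrator can
// call tsp1net_derivs without touching the R evaluator. Single-threaded use.

namespace {
struct ModelSpec {
  std::vector<double> term_k, st_coef;
  std::vector<int> term_sign, term_rxn, fct_term, fct_kind, fct_s1, fct_s2;
  std::vector<double> fct_par;  // row-major, 4 per factor
  std::vector<int> st_sp, st_rxn, clamped;
  int nspec = 0, nrxn = 0, nterm = 0;
  std::vector<double> tf, rflux;
};
ModelSpec g_model;
}

// [[Rcpp::export(name = ".load_model_cpp")]]
void load_model_cpp(NumericVector k_term, IntegerVector term_sign,
                    IntegerVector term_rxn, IntegerVector fct_term,
                    IntegerVector fct_kind, IntegerVector fct_s1,
                    IntegerVector fct_s2, NumericMatrix fct_par,
                    IntegerVector st_sp, IntegerVector st_rxn,
                    NumericVector st_coef, IntegerVector clamped,
                    int nspec, int nrxn) {
  ModelSpec &m = g_model;
  m.term_k.assign(k_term.begin(), k_term.end());
  m.term_sign.assign(term_sign.begin(), term_sign.end());
  m.term_rxn.assign(term_rxn.begin(), term_rxn.end());
  m.fct_term.assign(fct_term.begin(), fct_term.end());
  m.fct_kind.assign(fct_kind.begin(), fct_kind.end());
  m.fct_s1.assign(fct_s1.begin(), fct_s1.end());
  m.fct_s2.assign(fct_s2.begin(), fct_s2.end());
  int nf = fct_term.size();
  m.fct_par.resize(4 * nf);
  for (int j = 0; j < nf; j++)
    for (int c = 0; c < 4; c++) m.fct_par[4 * j + c] = fct_par(j, c);
  m.st_sp.assign(st_sp.begin(), st_sp.end());
  m.st_rxn.assign(st_rxn.begin(), st_rxn.end());
  m.st_coef.assign(st_coef.begin(), st_coef.end());
  m.clamped.assign(clamped.begin(), clamped.end());
  m.nspec = nspec;
  m.nrxn = nrxn;
  m.nterm = k_term.size();
  m.tf.resize(m.nterm);
  m.rflux.resize(nrxn);
}

extern "C" {

void tsp1net_initmod(void (*odeparms)(int *, double *)) {
  // model structure is staged via load_model_cpp(); nothing to do here
  (void) odeparms;
}

void tsp1net_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip) {
  (void) t; (void) yout; (void) ip;
  ModelSpec &m = g_model;
  if (*neq != m.nspec) return;
  for (int i = 0; i < m.nterm; i++) m.tf[i] = m.term_k[i];
  int nf = m.fct_term.size();
  for (int j = 0; j < nf; j++) {
    double s1 = m.fct_s1[j] >= 0 ? y[m.fct_s1[j]] : 0.0;
    double s2 = m.fct_s2[j] >= 0 ? y[m.fct_s2[j]] : 0.0;
    m.tf[m.fct_term[j]] *= eval_factor(m.fct_kind[j], s1, s2,
                                       m.fct_par[4 * j], m.fct_par[4 * j + 1],
                                       m.fct_par[4 * j + 2],
                                       m.fct_par[4 * j + 3]);
  }
  std::fill(m.rflux.begin(), m.rflux.end(), 0.0);
  for (int i = 0; i < m.nterm; i++)
    m.rflux[m.term_rxn[i]] += m.term_sign[i] * m.tf[i];
  std::fill(ydot, ydot + m.nspec, 0.0);
  for (size_t i = 0; i < m.st_sp.size(); i++)
    ydot[m.st_sp[i]] += m.st_coef[i] * m.rflux[m.st_rxn[i]];
  for (size_t i = 0; i < m.clamped.size(); i++) ydot[m.clamped[i]] = 0.0;
}

}
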