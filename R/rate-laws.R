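#' Rate-law factor constructors
#'
#' A reaction flux in this package is an elementary product
#' \eqn{v = k \prod_j f_j(S_{i_j}; \theta_j)} of unit factors, each depending on
#' one (or, for Myc/MXI-1 activity ratios, two) species. Reversible reactions
#' carry a second such product with opposite sign. The classic rate-law
#' families are special cases: mass action is a product of `pow` factors over
#' the reactants, Michaelis-Menten is `pow(enzyme) * sat(substrate, Km)`, and
#' transcriptional activation/repression use the Hill factors. Parameters may
#' be given as registry names (character) or numeric literals.
#'
#' @param species species name the factor reads (character scalar).
#' @param n,K,A,R,Kx Hill exponent, half-saturation constant (uM), activation
#'   amplitude (dimensionless fold - 1), repression strength (dimensionless),
#'   and competitor constant (uM); each either a parameter name or a number.
#' @param species2 competitor species for the activity-ratio factors
#'   (e.g. MXI-1 damping the effective Myc activity).
#' @return A factor object (list) for use in [reaction()].
#' @name rate_factors
NULL

.factor_kinds <- c(pow = 1L, sat = 2L, hill_act = 3L, hill_rep = 4L,
                   fold_act = 5L, fold_rep = 6L, ratio_hill_act = 7L,
                   ratio_fold_act = 8L, ratio_fold_rep = 9L)

.new_factor <- function(kind, species, species2 = NA_character_, pars) {
  stopifnot(kind %in% names(.factor_kinds))
  structure(list(kind = kind, species = species, species2 = species2,
                 pars = pars), class = "rate_factor")
}

#' @rdname rate_factors
#' @export
f_pow <- function(species, n = 1) .new_factor("pow", species, pars = list(n))

#' @rdname rate_factors
#' @export
f_sat <- function(species, K) .new_factor("sat", species, pars = list(K))

#' @rdname rate_factors
#' @export
f_hill_act <- function(species, K, n = 1) {
  .new_factor("hill_act", species, pars = list(K, n))
}

#' @rdname rate_factors
#' @export
f_hill_rep <- function(species, K, n = 1) {
  .new_factor("hill_rep", species, pars = list(K, n))
}

#' @rdname rate_factors
#' @export
f_fold_act <- function(species, K, n, A) {
  .new_factor("fold_act", species, pars = list(K, n, A))
}

#' @rdname rate_factors
#' @export
f_fold_rep <- function(species, K, n, R) {
  .new_factor("fold_rep", species, pars = list(K, n, R))
}

#' @rdname rate_factors
#' @export
f_ratio_hill_act <- function(species, species2, K, n, Kx) {
  .new_factor("ratio_hill_act", species, species2, pars = list(K, n, Kx))
}

#' @rdname rate_factors
#' @export
f_ratio_fold_act <- function(species, species2, K, n, A, Kx) {
  .new_factor("ratio_fold_act", species, species2, pars = list(K, n, A, Kx))
}

#' @rdname rate_factors
#' @export
f_ratio_fold_rep <- function(species, species2, K, n, R, Kx) {
  .new_factor("ratio_fold_rep", species, species2, pars = list(K, n, R, Kx))
}

.hill <- function(s, K, n) {
  if (s <= 0) return(0)
  s^n / (K^n + s^n)
}

## Pure-R evaluation of a single factor; reference path used by evaluate_rate().
.eval_factor_r <- function(fct, state, params) {
  p <- vapply(fct$pars, function(x) {
    if (is.character(x)) .param_value(params, x) else as.numeric(x)
  }, numeric(1))
  s1 <- max(state[[fct$species]], 0)
  s2 <- if (!is.na(fct$species2)) max(state[[fct$species2]], 0) else 0
  switch(fct$kind,
    pow            = s1^p[1],
    sat            = s1 / (p[1] + s1),
    hill_act       = .hill(s1, p[1], p[2]),
    hill_rep       = 1 - .hill(s1, p[1], p[2]),
    fold_act       = 1 + p[3] * .hill(s1, p[1], p[2]),
    fold_rep       = 1 / (1 + p[3] * .hill(s1, p[1], p[2])),
    ratio_hill_act = .hill(s1 / (1 + s2 / p[3]), p[1], p[2]),
    ratio_fold_act = 1 + p[3] * .hill(s1 / (1 + s2 / p[4]), p[1], p[2]),
    ratio_fold_rep = 1 / (1 + p[3] * .hill(s1 / (1 + s2 / p[4]), p[1], p[2])),
    stop("unknown factor kind: ", fct$kind)
  )
}

.param_value <- function(params, name) {
  if (!name %in% names(params)) {
    stop("unknown parameter symbol: ", name, call. = FALSE)
  }
  unname(params[[name]])
}

#' Evaluate the net rate of one reaction
#'
#' Computes the instantaneous net flux (uM/min) of a reaction at a given
#' state. For reversible reactions the flux is forward minus reverse; for
#' irreversible laws the flux is non-negative whenever the state is
#' non-negative.
#'
#' @param reaction a reaction object (see [reaction()]).
#' @param state named numeric vector of species concentrations (uM). All
#'   species read by the rate law must be present and non-negative.
#' @param params named numeric vector of parameter values; defaults to the
#'   values bound in the reaction's network at build time when evaluated via
#'   [reaction_fluxes()].
#' @return net flux in uM/min (scalar).
#' @export
evaluate_rate <- function(reaction, state, params) {
  need <- .reaction_species(reaction)
  missing_sp <- setdiff(need, names(state))
  if (length(missing_sp)) {
    stop("state is missing species: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  if (any(state[need] < 0)) {
    stop("negative concentration passed to evaluate_rate()", call. = FALSE)
  }
  eval_term <- function(term) {
    k <- if (is.character(term$k)) .param_value(params, term$k) else term$k
    for (fct in term$factors) k <- k * .eval_factor_r(fct, state, params)
    k
  }
  v <- eval_term(reaction$fwd)
  if (!is.null(reaction$rev)) v <- v - eval_term(reaction$rev)
  v
}

.reaction_species <- function(reaction) {
  sp <- unique(c(names(reaction$reactants), names(reaction$products),
                 reaction$modifiers,
                 unlist(lapply(c(reaction$fwd$factors, reaction$rev$factors),
                               function(f) c(f$species, f$species2)))))
  sp[!is.na(sp)]
}
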