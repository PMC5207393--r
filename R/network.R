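#' Construct a reaction
#'
#' Builds one reaction of a compartmental network. Reactants/products are
#' named numeric vectors of stoichiometries; modifiers are species that appear
#' in the rate law without being consumed (enzymes, transcription factors).
#' The rate is the product of a rate constant (registry symbol) and unit
#' factors (see [rate_factors]); reversible reactions give `kr`/`rev_factors`.
#'
#' @param id reaction identifier (the network's `v#` numbering).
#' @param name human-readable description.
#' @param kind one of `"mass_action"`, `"michaelis_menten"`,
#'   `"hill_activation"`, `"hill_repression"`, `"rule_based"`.
#' @param reactants,products named numeric vectors (species -> stoichiometry).
#' @param modifiers character vector of modifier species.
#' @param kf,kr forward/reverse rate-constant symbols (or numbers).
#' @param factors,rev_factors lists of factor objects for forward/reverse flux.
#'   If `factors` is `NULL`, mass-action `pow` factors over the reactants are
#'   generated; likewise `rev_factors` over the products when `kr` is given.
#' @param tags free-form labels; `"translation"` marks the protein-synthesis
#'   steps zeroed by cycloheximide, `"degradation"` marks sink reactions.
#' @return a `reaction` object.
#' @export
reaction <- function(id, name = id, kind = "mass_action",
                     reactants = numeric(), products = numeric(),
                     modifiers = character(), kf, kr = NULL,
                     factors = NULL, rev_factors = NULL,
                     tags = character()) {
  stopifnot(is.character(id), length(id) == 1L)
  if (is.null(factors)) {
    factors <- lapply(seq_along(reactants), function(i) {
      f_pow(names(reactants)[i], unname(reactants[i]))
    })
  }
  rev <- NULL
  if (!is.null(kr)) {
    if (is.null(rev_factors)) {
      rev_factors <- lapply(seq_along(products), function(i) {
        f_pow(names(products)[i], unname(products[i]))
      })
    }
    rev <- list(k = kr, factors = rev_factors)
  }
  structure(list(id = id, name = name, kind = kind,
                 reactants = reactants, products = products,
                 modifiers = modifiers,
                 fwd = list(k = kf, factors = factors), rev = rev,
                 tags = tags),
            class = "reaction")
}

.compartments_default <- function() {
  data.frame(name = c("cytoplasm", "nucleus", "endosome", "extracellular"),
             volume_pl = 1, stringsAsFactors = FALSE)
}

#' Assemble a validated reaction network
#'
#' Validates and assembles species, reactions and the parameter registry into
#' a `reaction_network`, the executable form of the model definition. All
#' cross-references (reaction species, parameter symbols, compartments) are
#' resolved here and a structural error names the offending reaction.
#'
#' @param species data.frame with columns `name`, `compartment`, `init`
#'   (uM), and optionally `clamped` (buffered species with zero derivative,
#'   e.g. dissolved oxygen) and `role`.
#' @param reactions list of [reaction()] objects.
#' @param parameters named numeric vector, the kinetic parameter registry.
#' @param compartments data.frame `name`/`volume_pl`; defaults to the four
#'   1-pL compartments (cytoplasm, nucleus, endosome, extracellular).
#' @param provenance free-form list recorded with the network.
#' @return a `reaction_network` object.
#' @export
build_network <- function(species, reactions, parameters = numeric(),
                          compartments = .compartments_default(),
                          provenance = list()) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (nrow(species)) {
    stopifnot(all(c("name", "compartment", "init") %in% names(species)))
    if (is.null(species$clamped)) species$clamped <- FALSE
    if (is.null(species$role)) species$role <- ""
    if (anyDuplicated(species$name)) {
      stop("duplicate species name(s): ",
           paste(unique(species$name[duplicated(species$name)]), collapse = ", "),
           call. = FALSE)
    }
    bad_cmp <- setdiff(species$compartment, compartments$name)
    if (length(bad_cmp)) {
      stop("unknown compartment(s): ", paste(bad_cmp, collapse = ", "),
           call. = FALSE)
    }
    if (any(species$init < 0)) stop("negative initial concentration", call. = FALSE)
  } else {
    species <- data.frame(name = character(), compartment = character(),
                          init = numeric(), clamped = logical(),
                          role = character(), stringsAsFactors = FALSE)
  }
  if (any(compartments$volume_pl <= 0)) {
    stop("compartment volumes must be positive", call. = FALSE)
  }
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(parameters))) {
    stop("duplicate parameter symbol(s) in registry: ",
         paste(unique(names(parameters)[duplicated(names(parameters))]),
               collapse = ", "), call. = FALSE)
  }
  for (rx in reactions) {
    unknown <- setdiff(.reaction_species(rx), species$name)
    if (length(unknown)) {
      stop("reaction ", rx$id, " references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (term in list(rx$fwd, rx$rev)) {
      if (is.null(term)) next
      syms <- c(if (is.character(term$k)) term$k,
                unlist(lapply(term$factors, function(f) {
                  unlist(Filter(is.character, f$pars))
                })))
      missing_p <- setdiff(syms, names(parameters))
      if (length(missing_p)) {
        stop("reaction ", rx$id, " references unknown parameter(s): ",
             paste(missing_p, collapse = ", "), call. = FALSE)
      }
    }
  }
  names(reactions) <- ids
  net <- structure(list(species = species, reactions = reactions,
                        params = parameters, compartments = compartments,
                        provenance = provenance),
                   class = "reaction_network")
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions, %d parameters\n",
              nrow(x$species), length(x$reactions), length(x$params)))
  invisible(x)
}

#' Network dimensions
#'
#' @param net a `reaction_network`.
#' @return named integer vector `c(species, reactions, parameters)`.
#' @export
network_counts <- function(net) {
  c(species = nrow(net$species), reactions = length(net$reactions),
    parameters = length(net$params))
}

#' Stoichiometry matrix
#'
#' @param net a `reaction_network`.
#' @return numeric matrix (n_species x n_reactions); entry (i, j) is the net
#'   stoichiometric coefficient of species i in reaction j.
#' @export
stoichiometry_matrix <- function(net) {
  S <- matrix(0, nrow(net$species), length(net$reactions),
              dimnames = list(net$species$name,
                              vapply(net$reactions, `[[`, character(1), "id")))
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    for (i in seq_along(rx$reactants)) {
      S[names(rx$reactants)[i], j] <- S[names(rx$reactants)[i], j] - rx$reactants[i]
    }
    for (i in seq_along(rx$products)) {
      S[names(rx$products)[i], j] <- S[names(rx$products)[i], j] + rx$products[i]
    }
  }
  S
}

## Resolve symbols to dense arrays consumed by the C++ evaluator.
compile_network <- function(net, params = net$params) {
  spidx <- stats::setNames(seq_len(nrow(net$species)) - 1L, net$species$name)
  term_k <- numeric(0); term_sign <- integer(0); term_rxn <- integer(0)
  fct_term <- integer(0); fct_kind <- integer(0)
  fct_s1 <- integer(0); fct_s2 <- integer(0)
  fct_par <- matrix(0, 0, 4)
  resolve <- function(x) if (is.character(x)) .param_value(params, x) else as.numeric(x)
  t_i <- 0L
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    for (dir in c(1L, -1L)) {
      term <- if (dir == 1L) rx$fwd else rx$rev
      if (is.null(term)) next
      term_k <- c(term_k, resolve(term$k))
      term_sign <- c(term_sign, dir)
      term_rxn <- c(term_rxn, j - 1L)
      for (fct in term$factors) {
        fct_term <- c(fct_term, t_i)
        fct_kind <- c(fct_kind, .factor_kinds[[fct$kind]])
        fct_s1 <- c(fct_s1, spidx[[fct$species]])
        fct_s2 <- c(fct_s2, if (is.na(fct$species2)) -1L else spidx[[fct$species2]])
        p <- vapply(fct$pars, resolve, numeric(1))
        fct_par <- rbind(fct_par, c(p, rep(0, 4 - length(p))))
      }
      t_i <- t_i + 1L
    }
  }
  Smat <- stoichiometry_matrix(net)
  nz <- which(Smat != 0, arr.ind = TRUE)
  list(term_k = term_k, term_sign = term_sign, term_rxn = term_rxn,
       fct_term = fct_term, fct_kind = fct_kind,
       fct_s1 = fct_s1, fct_s2 = fct_s2, fct_par = fct_par,
       st_sp = as.integer(nz[, 1] - 1L), st_rxn = as.integer(nz[, 2] - 1L),
       st_coef = Smat[nz],
       clamped = as.integer(which(net$species$clamped) - 1L),
       nspec = nrow(net$species), nrxn = length(net$reactions),
       species = net$species$name,
       rxn_ids = vapply(net$reactions, `[[`, character(1), "id"))
}

#' Assemble the ODE right-hand side
#'
#' Compiles the network into a derivative function `f(t, state)` returning
#' d(state)/dt in uM/min: for each species the signed sum of reaction fluxes
#' weighted by stoichiometry, with clamped (buffered) species held constant.
#'
#' @param net a `reaction_network`.
#' @param params optional parameter vector overriding the network registry.
#' @return function `(t, state) -> named derivative vector`.
#' @export
assemble_derivatives <- function(net, params = net$params) {
  cm <- compile_network(net, params)
  function(t, state) {
    dx <- .network_rhs_cpp(as.numeric(state), cm$term_k, cm$term_sign,
                           cm$term_rxn, cm$fct_term, cm$fct_kind,
                           cm$fct_s1, cm$fct_s2, cm$fct_par,
                           cm$st_sp, cm$st_rxn, cm$st_coef,
                           cm$clamped, cm$nspec, cm$nrxn)
    names(dx) <- cm$species
    dx
  }
}

#' Net flux of every reaction at a state
#'
#' @param net a `reaction_network`.
#' @param state named numeric vector of concentrations (uM); defaults to the
#'   network's initial conditions.
#' @param params optional parameter override.
#' @return named numeric vector of net fluxes (uM/min) by reaction id.
#' @export
reaction_fluxes <- function(net, state = initial_state(net), params = net$params) {
  cm <- compile_network(net, params)
  fl <- .reaction_fluxes_cpp(as.numeric(state[cm$species]), cm$term_k,
                             cm$term_sign, cm$term_rxn, cm$fct_term,
                             cm$fct_kind, cm$fct_s1, cm$fct_s2, cm$fct_par,
                             cm$nrxn)
  stats::setNames(fl, cm$rxn_ids)
}

#' Initial state of a network
#'
#' @param net a `reaction_network`.
#' @return named numeric vector of initial concentrations (uM).
#' @export
initial_state <- function(net) {
  stats::setNames(net$species$init, net$species$name)
}

#' Modify parameters or initial conditions of a network
#'
#' @param net a `reaction_network`.
#' @param params named numeric vector of parameter values to set.
#' @param init named numeric vector of initial concentrations to set.
#' @return the modified network.
#' @export
set_network <- function(net, params = NULL, init = NULL) {
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(net$params))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    net$params[names(params)] <- params
  }
  if (!is.null(init)) {
    bad <- setdiff(names(init), net$species$name)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    net$species$init[match(names(init), net$species$name)] <- init
  }
  net
}

#' Reactions carrying a given tag
#'
#' @param net a `reaction_network`.
#' @param tag tag to search for (e.g. `"translation"`).
#' @return character vector of reaction ids.
#' @export
reactions_with_tag <- function(net, tag) {
  ids <- vapply(net$reactions, `[[`, character(1), "id")
  ids[vapply(net$reactions, function(rx) tag %in% rx$tags, logical(1))]
}
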