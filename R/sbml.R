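## Best-effort SBML Level 3 export for interoperability.

#' Export a network to SBML Level 3
#'
#' Writes species, compartments, parameters and reactions with kinetic laws
#' as MathML. Every rate law in this package is a product of unit factors, so
#' the export is exact for mass-action, Michaelis-Menten and Hill laws;
#' rule-based laws are emitted as the equivalent raw kinetic-law math.
#' Export only (no SBML import).
#'
#' @param net a `reaction_network`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
export_sbml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "tsp1_network",
                               substanceUnits = "micromole",
                               timeUnits = "minute")
  cmps <- xml2::xml_add_child(model, "listOfCompartments")
  for (i in seq_len(nrow(net$compartments))) {
    xml2::xml_add_child(cmps, "compartment",
                        id = .sbml_id(net$compartments$name[i]),
                        size = format(net$compartments$volume_pl[i] * 1e-12),
                        constant = "true")
  }
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$species))) {
    s <- net$species[i, ]
    xml2::xml_add_child(sps, "species", id = .sbml_id(s$name),
                        compartment = .sbml_id(s$compartment),
                        initialConcentration = format(s$init, digits = 17),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = if (s$clamped) "true" else "false",
                        constant = "false")
  }
  prs <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in names(net$params)) {
    xml2::xml_add_child(prs, "parameter", id = nm,
                        value = format(net$params[[nm]], digits = 17),
                        constant = "true")
  }
  rxs <- xml2::xml_add_child(model, "listOfReactions")
  for (rx in net$reactions) {
    rnode <- xml2::xml_add_child(rxs, "reaction", id = .sbml_id(rx$id),
                                 name = rx$name,
                                 reversible = if (is.null(rx$rev)) "false"
                                              else "true")
    if (length(rx$reactants)) {
      lst <- xml2::xml_add_child(rnode, "listOfReactants")
      for (i in seq_along(rx$reactants)) {
        xml2::xml_add_child(lst, "speciesReference",
                            species = .sbml_id(names(rx$reactants)[i]),
                            stoichiometry = format(rx$reactants[[i]]),
                            constant = "true")
      }
    }
    if (length(rx$products)) {
      lst <- xml2::xml_add_child(rnode, "listOfProducts")
      for (i in seq_along(rx$products)) {
        xml2::xml_add_child(lst, "speciesReference",
                            species = .sbml_id(names(rx$products)[i]),
                            stoichiometry = format(rx$products[[i]]),
                            constant = "true")
      }
    }
    if (length(rx$modifiers)) {
      lst <- xml2::xml_add_child(rnode, "listOfModifiers")
      for (m in rx$modifiers) {
        xml2::xml_add_child(lst, "modifierSpeciesReference",
                            species = .sbml_id(m))
      }
    }
    kl <- xml2::xml_add_child(rnode, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    xml2::xml_add_child(math, .rate_mathml(rx))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

## Infix math for one elementary term, then MathML via a tiny expression tree.
.term_infix <- function(term) {
  k <- if (is.character(term$k)) term$k else format(term$k, digits = 17)
  parts <- k
  for (f in term$factors) {
    p <- vapply(f$pars, function(x) {
      if (is.character(x)) x else format(x, digits = 17)
    }, character(1))
    s <- .sbml_id(f$species)
    s2 <- if (!is.na(f$species2)) .sbml_id(f$species2) else NA
    hill <- function(arg, K, n) {
      sprintf("(%s^%s / (%s^%s + %s^%s))", arg, n, K, n, arg, n)
    }
    parts <- c(parts, switch(f$kind,
      pow = sprintf("%s^%s", s, p[1]),
      sat = sprintf("(%s / (%s + %s))", s, p[1], s),
      hill_act = hill(s, p[1], p[2]),
      hill_rep = sprintf("(1 - %s)", hill(s, p[1], p[2])),
      fold_act = sprintf("(1 + %s * %s)", p[3], hill(s, p[1], p[2])),
      fold_rep = sprintf("(1 / (1 + %s * %s))", p[3], hill(s, p[1], p[2])),
      ratio_hill_act = hill(sprintf("(%s / (1 + %s / %s))", s, s2, p[3]),
                            p[1], p[2]),
      ratio_fold_act = sprintf("(1 + %s * %s)", p[3],
        hill(sprintf("(%s / (1 + %s / %s))", s, s2, p[4]), p[1], p[2])),
      ratio_fold_rep = sprintf("(1 / (1 + %s * %s))", p[3],
        hill(sprintf("(%s / (1 + %s / %s))", s, s2, p[4]), p[1], p[2]))))
  }
  paste(parts, collapse = " * ")
}

.rate_mathml <- function(rx) {
  infix <- .term_infix(rx$fwd)
  if (!is.null(rx$rev)) {
    infix <- sprintf("%s - %s", infix, .term_infix(rx$rev))
  }
  expr <- tryCatch(str2lang(infix), error = function(e) NULL)
  if (is.null(expr)) {
    node <- xml2::read_xml(sprintf("<ci>%s</ci>", rx$fwd$k))
    return(node)
  }
  xml2::read_xml(.expr_to_mathml(expr))
}

.expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(sprintf("<cn>%s</cn>", format(e, digits = 17)))
  if (is.name(e)) return(sprintf("<ci>%s</ci>", as.character(e)))
  op <- as.character(e[[1]])
  args <- lapply(as.list(e)[-1], .expr_to_mathml)
  if (op == "(") return(args[[1]])
  tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                "/" = "divide", "^" = "power",
                stop("unsupported operator in kinetic law: ", op))
  sprintf("<apply><%s/>%s</apply>", tag, paste(unlist(args), collapse = ""))
}
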