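#' Read and write model-definition files
#'
#' The model definition is a YAML document with sections `provenance`,
#' `compartments`, `parameters`, `species` and `reactions`. A reaction entry
#' is a flow map `{id, kind, reactants, products, modifiers, kf, kr, factors,
#' rev_factors, tags}`; when `factors` is omitted the rate is mass action over
#' the reactants. The writer emits this dialect and the pair round-trips
#' losslessly (to full double precision).
#'
#' @param path file path.
#' @return `load_network_definition()` returns a validated
#'   [build_network()] `reaction_network`.
#' @export
load_network_definition <- function(path) {
  doc <- yaml::read_yaml(path)
  for (sec in c("species", "reactions", "parameters")) {
    if (is.null(doc[[sec]])) doc[[sec]] <- list()
  }
  params <- vapply(doc$parameters, .as_num, numeric(1))
  species <- if (length(doc$species)) {
    data.frame(
      name = vapply(doc$species, `[[`, character(1), "name"),
      compartment = vapply(doc$species, `[[`, character(1), "compartment"),
      init = vapply(doc$species, function(s) .as_num(s$init), numeric(1)),
      clamped = vapply(doc$species, function(s) isTRUE(s$clamped), logical(1)),
      role = vapply(doc$species, function(s) s$role %||% "", character(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(), compartment = character(), init = numeric(),
               clamped = logical(), role = character(), stringsAsFactors = FALSE)
  }
  compartments <- if (!is.null(doc$compartments)) {
    data.frame(
      name = vapply(doc$compartments, `[[`, character(1), "name"),
      volume_pl = vapply(doc$compartments, function(x) .as_num(x$volume_pl),
                         numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    .compartments_default()
  }
  reactions <- lapply(doc$reactions, function(rx) {
    if (is.null(rx$id)) stop("reaction entry without id", call. = FALSE)
    reaction(
      id = rx$id, name = rx$name %||% rx$id,
      kind = rx$kind %||% "mass_action",
      reactants = .num_map(rx$reactants), products = .num_map(rx$products),
      modifiers = as.character(unlist(rx$modifiers)),
      kf = .k_val(rx$kf), kr = if (!is.null(rx$kr)) .k_val(rx$kr),
      factors = .parse_factors(rx$factors),
      rev_factors = .parse_factors(rx$rev_factors),
      tags = as.character(unlist(rx$tags)))
  })
  build_network(species, reactions, params, compartments,
                provenance = doc$provenance %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_num <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("expected a number, got: ", x, call. = FALSE)
  v
}

.num_map <- function(x) {
  if (is.null(x) || !length(x)) return(numeric())
  stats::setNames(vapply(x, .as_num, numeric(1)), names(x))
}

.k_val <- function(x) if (is.character(x)) x else .as_num(x)

.parse_factors <- function(x) {
  if (is.null(x)) return(NULL)
  lapply(x, function(f) {
    pars <- lapply(f$pars, function(p) if (is.character(p)) p else .as_num(p))
    .new_factor(f$kind, f$species, f$species2 %||% NA_character_, pars)
  })
}

.fmt_num <- function(x) {
  s <- format(x, digits = 17, scientific = NA, trim = TRUE)
  # ensure scientific-notation mantissas carry a decimal point so every YAML
  # parser resolves them as floats
  fix <- grepl("e", s, fixed = TRUE) & !grepl(".", sub("e.*$", "", s), fixed = TRUE)
  s[fix] <- sub("e", ".0e", s[fix], fixed = TRUE)
  s
}

.yaml_scalar <- function(x) {
  if (is.character(x)) {
    if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", x)) x else paste0('"', x, '"')
  } else {
    .fmt_num(x)
  }
}

.yaml_map <- function(x) {
  paste0("{", paste(sprintf("%s: %s", names(x),
                            vapply(x, .yaml_scalar, character(1))),
                    collapse = ", "), "}")
}

.factor_yaml <- function(f) {
  parts <- c(sprintf("kind: %s", f$kind), sprintf("species: %s", f$species))
  if (!is.na(f$species2)) parts <- c(parts, sprintf("species2: %s", f$species2))
  pars <- paste(vapply(f$pars, .yaml_scalar, character(1)), collapse = ", ")
  parts <- c(parts, sprintf("pars: [%s]", pars))
  paste0("{", paste(parts, collapse = ", "), "}")
}

.is_auto_ma <- function(factors, side) {
  if (length(factors) != length(side)) return(FALSE)
  all(vapply(seq_along(side), function(i) {
    f <- factors[[i]]
    f$kind == "pow" && identical(f$species, names(side)[i]) &&
      length(f$pars) == 1L && is.numeric(f$pars[[1]]) &&
      f$pars[[1]] == unname(side[i])
  }, logical(1)))
}

#' @rdname load_network_definition
#' @param net a `reaction_network` to serialize.
#' @export
write_network_definition <- function(net, path) {
  out <- character()
  emit <- function(...) out <<- c(out, sprintf(...))
  if (length(net$provenance)) {
    emit("provenance:")
    for (nm in names(net$provenance)) {
      emit('  %s: "%s"', nm, gsub('"', "'", as.character(net$provenance[[nm]])))
    }
  }
  emit("compartments:")
  for (i in seq_len(nrow(net$compartments))) {
    emit("  - {name: %s, volume_pl: %s}", net$compartments$name[i],
         .fmt_num(net$compartments$volume_pl[i]))
  }
  emit("parameters:")
  for (nm in names(net$params)) emit("  %s: %s", nm, .fmt_num(net$params[[nm]]))
  emit("species:")
  for (i in seq_len(nrow(net$species))) {
    s <- net$species[i, ]
    line <- sprintf("  - {name: %s, compartment: %s, init: %s",
                    s$name, s$compartment, .fmt_num(s$init))
    if (s$clamped) line <- paste0(line, ", clamped: true")
    if (nzchar(s$role)) line <- paste0(line, sprintf(', role: "%s"', s$role))
    out <- c(out, paste0(line, "}"))
  }
  emit("reactions:")
  for (rx in net$reactions) {
    emit("  - id: %s", rx$id)
    if (!identical(rx$name, rx$id)) emit('    name: "%s"', rx$name)
    emit("    kind: %s", rx$kind)
    if (length(rx$reactants)) emit("    reactants: %s", .yaml_map(rx$reactants))
    if (length(rx$products)) emit("    products: %s", .yaml_map(rx$products))
    if (length(rx$modifiers)) {
      emit("    modifiers: [%s]", paste(rx$modifiers, collapse = ", "))
    }
    emit("    kf: %s", .yaml_scalar(rx$fwd$k))
    if (!.is_auto_ma(rx$fwd$factors, rx$reactants)) {
      emit("    factors:")
      for (f in rx$fwd$factors) emit("      - %s", .factor_yaml(f))
    }
    if (!is.null(rx$rev)) {
      emit("    kr: %s", .yaml_scalar(rx$rev$k))
      if (!.is_auto_ma(rx$rev$factors, rx$products)) {
        emit("    rev_factors:")
        for (f in rx$rev$factors) emit("      - %s", .factor_yaml(f))
      }
    }
    if (length(rx$tags)) emit("    tags: [%s]", paste(rx$tags, collapse = ", "))
  }
  writeLines(out, path)
  invisible(path)
}
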