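#' Typed perturbations applied at the start of a protocol
#'
#' Interventions modify the network and/or its state as a step at t = 0 of
#' the treatment phase, after normoxic pre-equilibration:
#'
#' * `binding_inhibitor`: a small molecule or antagonist that reversibly binds
#'   and sequesters `target` into an inert complex at the stated `Kd`.
#'   The shipped network carries dedicated inhibitor species for cytoplasmic
#'   Myc, p53, the let-7 RISC and the miR-18a RISC (reactions tagged
#'   `inhibitor_binding`); for any other target a fresh inhibitor species,
#'   complex and reversible binding reaction are added.
#' * `synthesis_scale`: multiplies the rate constant of every synthesis
#'   (translation/transcription) reaction producing `target` by `factor`
#'   (e.g. Myc hyperactivity = factor 5).
#' * `synthesis_block`: `synthesis_scale` with factor 0.
#' * `rate_modifier`: multiplies the named rate parameter by `factor`
#'   (e.g. the NFAT dephosphorylation rate x 0.3 for VIVIT).
#' * `initial_bump`: adds `amount` (uM) to the species' state (miR mimics
#'   bump the corresponding precursor miR).
#' * `chx`: cycloheximide; zeroes every translation-tagged rate constant.
#'
#' @param kind one of `"binding_inhibitor"`, `"synthesis_scale"`,
#'   `"synthesis_block"`, `"rate_modifier"`, `"initial_bump"`, `"chx"`.
#' @param target species name (`binding_inhibitor`, `synthesis_scale`,
#'   `synthesis_block`, `initial_bump`) or parameter symbol (`rate_modifier`).
#' @param dose inhibitor dose, in units of `units`.
#' @param units `"nM"` or `"uM"` for `dose` (nM doses are converted
#'   internally, x 1e-3).
#' @param Kd dissociation constant of the inhibitor (uM), default 1e-3 uM
#'   (1 nM).
#' @param factor multiplicative factor (>= 0).
#' @param amount added concentration (uM) for `initial_bump`.
#' @return an `intervention` object.
#' @export
intervention <- function(kind, target = NULL, dose = NULL, units = "nM",
                         Kd = 1e-3, factor = NULL, amount = NULL) {
  kinds <- c("binding_inhibitor", "synthesis_scale", "synthesis_block",
             "rate_modifier", "initial_bump", "chx")
  if (!kind %in% kinds) {
    stop("unknown intervention kind '", kind, "'; allowed: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  if (kind == "binding_inhibitor") {
    stopifnot(!is.null(target), !is.null(dose), dose >= 0, Kd > 0)
    if (!units %in% c("nM", "uM")) stop("units must be nM or uM", call. = FALSE)
  }
  if (kind %in% c("synthesis_scale", "rate_modifier")) {
    stopifnot(!is.null(target), !is.null(factor), factor >= 0)
  }
  if (kind == "synthesis_block") factor <- 0
  if (kind == "initial_bump") stopifnot(!is.null(target), !is.null(amount))
  structure(list(kind = kind, target = target, dose = dose, units = units,
                 Kd = Kd, factor = factor, amount = amount),
            class = "intervention")
}

#' Apply an intervention to a network and state
#'
#' @param net a `reaction_network`.
#' @param state named state vector (uM) at the moment of application.
#' @param iv an [intervention()].
#' @return list with elements `network` and `state`.
#' @export
apply_intervention <- function(net, state, iv) {
  stopifnot(inherits(iv, "intervention"))
  switch(iv$kind,
    chx = {
      ks <- unique(unlist(lapply(net$reactions, function(rx) {
        if ("translation" %in% rx$tags && is.character(rx$fwd$k)) rx$fwd$k
      })))
      net$params[ks] <- 0
      list(network = net, state = state)
    },
    rate_modifier = {
      if (!iv$target %in% names(net$params)) {
        stop("unknown parameter: ", iv$target, call. = FALSE)
      }
      net$params[iv$target] <- net$params[iv$target] * iv$factor
      list(network = net, state = state)
    },
    synthesis_scale = ,
    synthesis_block = {
      ids <- .synthesis_reactions(net, iv$target)
      if (!length(ids)) {
        stop("no synthesis reaction found for target: ", iv$target,
             call. = FALSE)
      }
      ks <- unique(unlist(lapply(net$reactions[ids], function(rx) rx$fwd$k)))
      shared <- vapply(net$reactions, function(rx) {
        is.character(rx$fwd$k) && rx$fwd$k %in% ks && !rx$id %in% ids
      }, logical(1))
      if (any(shared)) {
        stop("synthesis rate constant shared with reactions outside the ",
             "target; cannot scale ", iv$target, call. = FALSE)
      }
      net$params[ks] <- net$params[ks] * iv$factor
      list(network = net, state = state)
    },
    initial_bump = {
      if (!iv$target %in% names(state)) {
        stop("unknown species: ", iv$target, call. = FALSE)
      }
      state[iv$target] <- state[iv$target] + iv$amount
      list(network = net, state = state)
    },
    binding_inhibitor = .apply_binding_inhibitor(net, state, iv)
  )
}

.synthesis_reactions <- function(net, target) {
  ids <- vapply(net$reactions, `[[`, character(1), "id")
  ids[vapply(net$reactions, function(rx) {
    target %in% names(rx$products) &&
      any(c("translation", "transcription", "synthesis") %in% rx$tags)
  }, logical(1))]
}

.dose_um <- function(dose, units) if (units == "nM") dose * 1e-3 else dose

.apply_binding_inhibitor <- function(net, state, iv) {
  dose_um <- .dose_um(iv$dose, iv$units)
  if (!iv$target %in% net$species$name) {
    stop("unknown target species: ", iv$target, call. = FALSE)
  }
  # existing dedicated binding reaction?
  hit <- NULL
  for (rx in net$reactions) {
    if ("inhibitor_binding" %in% rx$tags && iv$target %in% names(rx$reactants)) {
      hit <- rx
      break
    }
  }
  if (!is.null(hit)) {
    inhib <- setdiff(names(hit$reactants), iv$target)
    kon_sym <- hit$fwd$k
    koff_sym <- hit$rev$k
    kon <- net$params[[kon_sym]]
    net$params[koff_sym] <- kon * iv$Kd
    state[inhib] <- state[inhib] + dose_um
    return(list(network = net, state = state))
  }
  # add a fresh inhibitor species + reversible sequestration reaction
  inhib <- paste0(iv$target, "_inhibitor")
  cplx <- paste0(iv$target, "_inhibitor_cplx")
  cmp <- net$species$compartment[net$species$name == iv$target]
  add <- data.frame(name = c(inhib, cplx), compartment = cmp, init = 0,
                    clamped = FALSE, role = "therapy inhibitor",
                    stringsAsFactors = FALSE)
  kon_sym <- paste0("kon_", inhib)
  koff_sym <- paste0("koff_", inhib)
  params <- net$params
  params[kon_sym] <- 10           # 1/(uM.min); Kd sets the off-rate
  params[koff_sym] <- 10 * iv$Kd
  rx <- reaction(paste0("vI_", inhib),
                 name = paste("inhibitor sequesters", iv$target),
                 reactants = stats::setNames(c(1, 1), c(iv$target, inhib)),
                 products = stats::setNames(1, cplx),
                 kf = kon_sym, kr = koff_sym, tags = "inhibitor_binding")
  net2 <- build_network(rbind(net$species, add), c(net$reactions, list(rx)),
                        params, net$compartments, net$provenance)
  st <- c(state, stats::setNames(c(dose_um, 0), c(inhib, cplx)))
  list(network = net2, state = st[net2$species$name])
}

#' Scan an intervention over a dose grid
#'
#' Runs one simulation per dose, records the readout, and locates the plateau
#' dose: the smallest dose whose readout reaches 99 percent of the asymptotic
#' (maximum-dose) effect relative to the zero-dose baseline, refined by
#' bisection between the bracketing grid points.
#'
#' @param net a `reaction_network`.
#' @param make_intervention function(dose_nM) returning the [intervention()]
#'   for that dose.
#' @param dose_grid_nm sorted dose grid in nM (>= 5 points).
#' @param readout function(trajectory) returning a scalar readout.
#' @param protocol base [simulation_protocol()]; the intervention is appended.
#' @param refine number of bisection steps for the plateau dose.
#' @return list with `doses_nm`, `readout`, `plateau_dose_nm`.
#' @export
dose_scan <- function(net, make_intervention, dose_grid_nm, readout, protocol,
                      refine = 6) {
  stopifnot(length(dose_grid_nm) >= 5, !is.unsorted(dose_grid_nm))
  run_dose <- function(d) {
    ivs <- protocol$interventions
    if (d > 0) ivs <- c(ivs, list(make_intervention(d)))
    p <- protocol
    p$interventions <- ivs
    readout(simulate_protocol(net, p))
  }
  vals <- vapply(dose_grid_nm, run_dose, numeric(1))
  base <- if (dose_grid_nm[1] == 0) vals[1] else run_dose(0)
  asym <- vals[length(vals)]
  total <- asym - base
  if (abs(total) < .Machine$double.eps) {
    return(list(doses_nm = dose_grid_nm, readout = vals,
                plateau_dose_nm = dose_grid_nm[1]))
  }
  eff <- (vals - base) / total
  if (any(diff(eff) < -0.02)) {
    warning("dose-response readout is non-monotone beyond noise tolerance")
  }
  idx <- which(eff >= 0.99)[1]
  if (is.na(idx)) {
    return(list(doses_nm = dose_grid_nm, readout = vals,
                plateau_dose_nm = NA_real_))
  }
  lo <- if (idx == 1) 0 else dose_grid_nm[idx - 1]
  hi <- dose_grid_nm[idx]
  for (i in seq_len(refine)) {
    mid <- (lo + hi) / 2
    e <- (run_dose(mid) - base) / total
    if (e >= 0.99) hi <- mid else lo <- mid
  }
  list(doses_nm = dose_grid_nm, readout = vals, plateau_dose_nm = hi)
}
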