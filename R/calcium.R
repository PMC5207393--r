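## Calcium / calmodulin / calcineurin / NFATc1 module operations.

#' Calcium influx and outflux rates at a state
#'
#' The TGF-beta activation signal (the ligand-bound signaling receptor
#' complex) drives calcium entry through the rule
#' `vm27 * (1 + A_ca * S^n / (K_ca^n + S^n))`; the basal term `vm27` is the
#' leak that balances the first-order pump `k_caout * [Ca]` at baseline
#' calcium, so with zero signal calcium is stationary.
#'
#' @param net a `reaction_network`.
#' @param state named state vector (uM), non-negative.
#' @param tgfb_signal optional override for the signal level (uM); defaults
#'   to the `LRC_e` concentration in `state`.
#' @return list with `influx`, `outflux` and `net` rates (uM/min).
#' @export
calcium_rules <- function(net, state, tgfb_signal = NULL) {
  if (any(state < 0)) stop("state must be non-negative", call. = FALSE)
  p <- net$params
  S <- if (is.null(tgfb_signal)) state[["LRC_e"]] else tgfb_signal
  influx <- p[["vm27"]] * (1 + p[["A_ca"]] * .hill(S, p[["K_ca"]], p[["n_ca"]]))
  outflux <- p[["k_caout"]] * state[["Ca"]]
  list(influx = unname(influx), outflux = unname(outflux),
       net = unname(influx - outflux))
}

#' Calcineurin-mediated NFATc1 dephosphorylation flux
#'
#' Michaelis-Menten in the inactive (phosphorylated, cytoplasmic) NFATc1 with
#' active calcineurin as the enzyme, scaled by a VIVIT factor: the NFAT
#' inhibitor is modeled as a fractional reduction of this rate (0.3 = the
#' 70 percent inhibition used for micromolar VIVIT).
#'
#' @param net a `reaction_network`.
#' @param state named state vector (uM).
#' @param vivit_factor multiplicative factor in (0, 1]; 1 = no inhibitor.
#' @return dephosphorylation flux in uM/min.
#' @export
nfat_activation_flux <- function(net, state, vivit_factor = 1) {
  if (vivit_factor <= 0 || vivit_factor > 1) {
    stop("vivit_factor must lie in (0, 1]", call. = FALSE)
  }
  p <- net$params
  unname(vivit_factor * p[["vm29"]] * state[["CaNa"]] *
           state[["NFATp_c"]] / (p[["Km_nfat"]] + state[["NFATp_c"]]))
}

#' Total NFATc1 over its four pools
#'
#' @param traj a `trajectory` (or named state vector).
#' @return numeric vector (or scalar) of total NFATc1 (uM).
#' @export
nfat_total <- function(traj) {
  pools <- c("NFATp_c", "NFATd_c", "NFATd_n", "NFATp_n")
  if (inherits(traj, "trajectory")) species_total(traj, pools)
  else sum(traj[pools])
}
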