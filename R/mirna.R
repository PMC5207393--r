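## microRNA biogenesis / targeting module operations.

#' microRNA processing fluxes at a state
#'
#' Reports the instantaneous biogenesis fluxes for let-7 and miR-18a:
#' primary-to-precursor processing (Hill-repressed by nuclear Lin28B for
#' let-7), Dicer cleavage of the cytoplasmic precursor (Michaelis-Menten in
#' the precursor with Dicer as the enzyme), RISC loading onto AGO1, and for
#' miR-18a the repression flux onto free TSP-1 mRNA.
#'
#' @param net a `reaction_network` (the shipped TSP-1 network).
#' @param state named state vector (uM), non-negative.
#' @return data.frame with columns `mir`, `step`, `flux_um_min`.
#' @export
mir_processing_fluxes <- function(net, state) {
  if (any(state < 0)) stop("state must be non-negative", call. = FALSE)
  fl <- reaction_fluxes(net, state)
  steps <- rbind(
    data.frame(mir = "let7", step = "pri_to_pre", id = "v53"),
    data.frame(mir = "let7", step = "dicer_cleavage", id = "v55"),
    data.frame(mir = "let7", step = "risc_loading", id = "v58"),
    data.frame(mir = "mir18", step = "pri_to_pre", id = "v69"),
    data.frame(mir = "mir18", step = "dicer_cleavage", id = "v71"),
    data.frame(mir = "mir18", step = "risc_loading", id = "v74"),
    data.frame(mir = "mir18", step = "mrna_repression", id = "v79"))
  data.frame(mir = steps$mir, step = steps$step,
             flux_um_min = unname(fl[steps$id]))
}

#' Ratio of repressed to free TSP-1 mRNA
#'
#' @param state named state vector with `TSP1_mRNA_rep` and `TSP1_mRNA`, or a
#'   `trajectory` (then evaluated at time `t`).
#' @param t time in minutes when `state` is a trajectory.
#' @return dimensionless ratio `[repressed]/[free]`.
#' @export
repressed_to_free_ratio <- function(state, t = NULL) {
  if (inherits(state, "trajectory")) {
    rep_ <- species_at(state, "TSP1_mRNA_rep", t)
    free <- species_at(state, "TSP1_mRNA", t)
  } else {
    rep_ <- state[["TSP1_mRNA_rep"]]
    free <- state[["TSP1_mRNA"]]
  }
  if (free <= 0) stop("free TSP-1 mRNA is zero; ratio undefined", call. = FALSE)
  rep_ / free
}
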