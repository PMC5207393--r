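## TSP-1 transcription function and the Myc/MXI-1/PSAP/p53 axis.

#' TSP-1 transcription rate for given transcription-factor inputs
#'
#' The TSP-1 gene integrates five transcription-factor inputs
#' multiplicatively: nuclear HIF-2 dimer, nuclear phospho-SMAD2-SMAD4,
#' nuclear active NFATc1 and p53 contribute Hill-activation fold terms
#' (>= 1 relative to the zero-TF basal rate); Myc contributes a weak
#' Hill-repression fold (<= 1) whose effective activity is damped by nuclear
#' MXI-1 (`Myc_eff = Myc_n / (1 + MXI1_n / K_mxi)`). A basal leak keeps
#' transcription positive when any single activator is absent.
#'
#' @param net a `reaction_network` (the shipped TSP-1 network supplies the
#'   Hill constants and the maximal rate).
#' @param inputs named list/vector with `HIF2d_n`, `Myc_n`, `MXI1_n`,
#'   `pS2S4_n`, `NFATd_n`, `p53` (uM, non-negative). Missing entries
#'   default to 0.
#' @return transcription rate in uM/min.
#' @export
tsp1_transcription_rate <- function(net, inputs) {
  need <- c("HIF2d_n", "Myc_n", "MXI1_n", "pS2S4_n", "NFATd_n", "p53")
  state <- stats::setNames(numeric(length(net$species$name)), net$species$name)
  for (nm in intersect(need, names(inputs))) {
    if (inputs[[nm]] < 0) stop("inputs must be non-negative", call. = FALSE)
    state[nm] <- inputs[[nm]]
  }
  evaluate_rate(net$reactions[["v76"]], state, net$params)
}

#' Regulatory fluxes of the Myc/MXI-1/PSAP/p53 axis
#'
#' Instantaneous fluxes of the hypoxia-facing gene-regulation axis:
#' HIF-promoted Myc degradation, MXI-1 induction, Myc-driven Lin28B and
#' miR-18a transcription, Myc repression of PSAP, p53 turnover (repressed by
#' HIF-1alpha and PSAP), and TGF-beta-signal-regulated Myc transcription.
#'
#' @param net a `reaction_network`.
#' @param state named state vector (uM), non-negative.
#' @return data.frame with columns `flux` and `value_um_min`.
#' @export
myc_p53_axis_fluxes <- function(net, state) {
  if (any(state < 0)) stop("state must be non-negative", call. = FALSE)
  fl <- reaction_fluxes(net, state)
  map <- c(myc_transcription = "v34",
           myc_degradation_basal = "v37",
           myc_degradation_hif = "v38",
           mxi1_induction = "v40",
           psap_synthesis = "v43",
           p53_degradation = "v48",
           lin28b_synthesis = "v49",
           mir18a_transcription = "v68")
  data.frame(flux = names(map), value_um_min = unname(fl[map]))
}
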