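.pkg_cache <- new.env(parent = emptyenv())

#' The shipped TSP-1 regulation network
#'
#' Loads the packaged model definition: a curated, compartmentalized
#' reconstruction of the endothelial TSP-1 regulatory network (109 species,
#' 138 reactions, 195 kinetic parameters) coupling PHD/FIH oxygen sensing of
#' HIF-1alpha/HIF-2alpha, the Myc/MXI-1/PSAP/p53 axis, let-7 and miR-18a
#' biogenesis and targeting, TGF-beta receptor trafficking with SMAD
#' activation and SMAD7 feedback, and calcium-driven NFATc1 activation.
#' Initial conditions are the normoxic (21 percent O2, no TGF-beta) steady
#' state.
#'
#' @param path optional path to an alternative definition file.
#' @return a `reaction_network`.
#' @export
tsp1_network <- function(path = NULL) {
  if (is.null(path)) {
    hit <- .pkg_cache$tsp1_network
    if (!is.null(hit)) return(hit)
    path <- system.file("extdata", "tsp1_network.yaml", package = "tsp1net",
                        mustWork = TRUE)
    net <- load_network_definition(path)
    .pkg_cache$tsp1_network <- net
    return(net)
  }
  load_network_definition(path)
}
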