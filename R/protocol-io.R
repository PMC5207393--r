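## Protocol files, result writers and run manifests.

#' Load a simulation protocol from a YAML file
#'
#' The protocol schema is
#' `{oxygen: {percent}, tgfb: {dose_ng_ml, chx}, duration, times,
#' interventions: [{kind, target, dose, units, Kd, factor, amount}],
#' solver: {rtol, atol, method}}`.
#' Missing fields get defaults: 21 percent O2, no TGF-beta, no
#' interventions, 24 h.
#'
#' @param path YAML file path.
#' @return a [simulation_protocol()].
#' @export
load_protocol <- function(path) {
  doc <- yaml::read_yaml(path)
  allowed <- c("oxygen", "tgfb", "duration", "times", "interventions",
               "solver")
  bad <- setdiff(names(doc), allowed)
  if (length(bad)) {
    stop("unknown protocol field(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  ivs <- lapply(doc$interventions, function(iv) {
    if (is.null(iv$kind)) stop("intervention without kind", call. = FALSE)
    do.call(intervention, iv[intersect(names(iv),
      c("kind", "target", "dose", "units", "Kd", "factor", "amount"))])
  })
  solver <- do.call(solver_settings, as.list(doc$solver))
  simulation_protocol(
    oxygen_percent = doc$oxygen$percent %||% 21,
    tgfb_ng_ml = doc$tgfb$dose_ng_ml %||% 0,
    chx = isTRUE(doc$tgfb$chx),
    duration = doc$duration %||% 1440,
    times = if (!is.null(doc$times)) as.numeric(unlist(doc$times)),
    interventions = ivs, solver = solver)
}

#' Run manifest
#'
#' Collects everything needed to reproduce a run bit-for-bit (given the same
#' build): the model definition checksum, the protocol, solver settings, seed
#' and package version.
#'
#' @param net a `reaction_network`.
#' @param protocol the protocol that was run (or NULL).
#' @param seed the seed used (or NULL for deterministic runs).
#' @return a list suitable for JSON serialization.
#' @export
run_manifest <- function(net, protocol = NULL, seed = NULL) {
  tf <- tempfile()
  on.exit(unlink(tf))
  write_network_definition(net, tf)
  list(model_checksum = unname(tools::md5sum(tf)),
       species = nrow(net$species), reactions = length(net$reactions),
       parameters = length(net$params),
       protocol = if (!is.null(protocol)) {
         list(oxygen_percent = protocol$oxygen_percent,
              tgfb_ng_ml = protocol$tgfb_ng_ml, chx = protocol$chx,
              duration = protocol$duration,
              n_interventions = length(protocol$interventions),
              solver = protocol$solver)
       },
       seed = seed,
       package_version = as.character(utils::packageVersion("tsp1net")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write simulation results to a directory
#'
#' Trajectories become tab-delimited tables (time in minutes, one species
#' column per uM concentration); sensitivity results become a table sorted by
#' `|PRCC|` descending (ties by parameter name); dose-response curves and fit
#' reports are written as delimited tables / JSON. A JSON run manifest
#' accompanies every result.
#'
#' @param result a `trajectory`, `sensitivity_result`, data.frame (curve), or
#'   list (fit report).
#' @param out_dir output directory (created if needed).
#' @param name base file name.
#' @param net network used (for the manifest); optional.
#' @param seed seed recorded in the manifest.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(result, out_dir, name = "result", net = NULL,
                          seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  tab_path <- file.path(out_dir, paste0(name, ".tsv"))
  if (inherits(result, "trajectory")) {
    df <- as.data.frame(result)
    names(df) <- c("time_min", paste0(result$species, "_uM"))
    # serialize at full double precision so tables round-trip losslessly
    df[] <- lapply(df, function(col) format(col, digits = 17, trim = TRUE))
    utils::write.table(df, tab_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- tab_path
  } else if (inherits(result, "sensitivity_result")) {
    utils::write.table(result$prcc, tab_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- tab_path
  } else if (is.data.frame(result)) {
    utils::write.table(result, tab_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- tab_path
  } else {
    json_path <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(result, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- json_path
  }
  if (!is.null(net)) {
    man_path <- file.path(out_dir, paste0(name, "_manifest.json"))
    proto <- if (inherits(result, "trajectory")) result$protocol
    jsonlite::write_json(run_manifest(net, proto, seed), man_path,
                         auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, man_path)
  }
  invisible(paths)
}

#' Read a trajectory table written by [write_outputs()]
#'
#' @param path the `.tsv` file.
#' @return data.frame with `time_min` and one column per species (uM).
#' @export
read_trajectory_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "numeric")
}
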