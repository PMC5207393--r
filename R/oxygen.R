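## Oxygen-sensing module operations.

#' Simulate a step change in oxygen tension
#'
#' From the normoxic steady state, the clamped dissolved-oxygen species is
#' stepped to the stated tension at t = 0 (no gas-equilibration lag) and the
#' full network is integrated.
#'
#' @param net a `reaction_network`.
#' @param oxygen_percent target oxygen tension (percent, in `[0, 21]`).
#' @param duration minutes (> 0).
#' @param times optional output grid.
#' @return a `trajectory`.
#' @export
simulate_oxygen_shift <- function(net, oxygen_percent, duration = 1440,
                                  times = NULL) {
  simulate_protocol(net, simulation_protocol(
    oxygen_percent = oxygen_percent, duration = duration, times = times))
}

#' TSP-1 protein oxygen dose response
#'
#' TSP-1 protein at fixed evaluation times across an oxygen grid, normalized
#' to the 21 percent value, together with the half-maximal induction tension
#' (linear interpolation between grid points).
#'
#' @param net a `reaction_network`.
#' @param o2_grid oxygen tensions in percent, within `[0.5, 21]`.
#' @param t_eval_h evaluation times in hours (default 24 and 48).
#' @return list with a data.frame `curve` (percent, one normalized column per
#'   evaluation time) and `half_max_percent` (named by evaluation time).
#' @export
tsp1_oxygen_dose_response <- function(net, o2_grid = c(0.5, 1, 2, 3, 4, 5, 6,
                                                       7, 8, 10, 12, 15, 21),
                                      t_eval_h = c(24, 48)) {
  if (any(o2_grid < 0.5 | o2_grid > 21)) {
    stop("o2_grid must lie within [0.5, 21] percent", call. = FALSE)
  }
  if (any(t_eval_h <= 0)) stop("evaluation times must be positive", call. = FALSE)
  o2_grid <- sort(o2_grid)
  dur <- max(t_eval_h) * 60
  vals <- sapply(o2_grid, function(p) {
    tr <- simulate_oxygen_shift(net, p, duration = dur)
    vapply(t_eval_h, function(h) species_at(tr, "TSP1", h * 60), numeric(1))
  })
  vals <- matrix(vals, nrow = length(t_eval_h))
  ref <- vals[, length(o2_grid)]           # the 21 % (or highest-grid) value
  norm <- vals / ref
  curve <- data.frame(percent = o2_grid, t(norm))
  names(curve)[-1] <- paste0("tsp1_fold_", t_eval_h, "h")
  half_max <- vapply(seq_along(t_eval_h), function(i) {
    y <- norm[i, ]                          # decreasing in O2
    target <- (max(y) + min(y)) / 2
    # walk the grid from low to high O2 and interpolate the crossing
    for (j in seq_len(length(o2_grid) - 1)) {
      y1 <- y[j]; y2 <- y[j + 1]
      if ((y1 - target) * (y2 - target) <= 0) {
        return(o2_grid[j] + (target - y1) / (y2 - y1) *
                 (o2_grid[j + 1] - o2_grid[j]))
      }
    }
    NA_real_
  }, numeric(1))
  list(curve = curve,
       half_max_percent = stats::setNames(half_max, paste0(t_eval_h, "h")))
}
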