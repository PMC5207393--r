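## TGF-beta / SMAD module operations.

#' Convert a TGF-beta dose from ng/ml to uM
#'
#' Linear conversion at 4e-5 uM per ng/ml (TGF-beta homodimer, ~25 kDa
#' monomer).
#'
#' @param dose_ng_ml dose in ng/ml (>= 0).
#' @return concentration in uM.
#' @export
tgfb_dose_to_concentration <- function(dose_ng_ml) {
  if (any(dose_ng_ml < 0)) stop("TGF-beta dose must be >= 0", call. = FALSE)
  dose_ng_ml * 4e-5
}

## Species whose sum is "total phosphorylated SMAD2" (all compartments,
## free and SMAD4-complexed) -- the quantity a phospho-blot measures.
.psmad2_species <- c("pSMAD2", "pSMAD2_n", "pS2S4_c", "pS2S4_n")
.psmad1_species <- c("pSMAD1", "pSMAD1_n", "pS1S4_c", "pS1S4_n")

#' Total phosphorylated R-SMAD along a trajectory
#'
#' @param traj a `trajectory`.
#' @param which `"SMAD2"` or `"SMAD1"`.
#' @return numeric vector over the time grid (uM).
#' @export
psmad_total <- function(traj, which = c("SMAD2", "SMAD1")) {
  which <- match.arg(which)
  species_total(traj, if (which == "SMAD2") .psmad2_species else .psmad1_species)
}

#' Simulate a TGF-beta stimulation
#'
#' Applies a TGF-beta dose at t = 0 from the normoxic steady state,
#' optionally under cycloheximide (every translation rate zeroed).
#'
#' @param net a `reaction_network`.
#' @param dose_ng_ml TGF-beta dose (ng/ml).
#' @param duration minutes (> 0).
#' @param chx logical, cycloheximide treatment.
#' @param times optional output grid.
#' @return a `trajectory`.
#' @export
simulate_tgfb <- function(net, dose_ng_ml, duration = 1440, chx = FALSE,
                          times = NULL) {
  simulate_protocol(net, simulation_protocol(
    oxygen_percent = 21, tgfb_ng_ml = dose_ng_ml, duration = duration,
    times = times, chx = chx))
}

#' Time spent above half of the peak
#'
#' Duration (min) for which a signal exceeds 50 percent of its maximum over
#' the trajectory; used to quantify how cycloheximide prolongs the
#' phospho-SMAD plateau.
#'
#' @param traj a `trajectory`.
#' @param signal numeric vector over the time grid.
#' @return time above half-peak in minutes.
#' @export
time_above_half_peak <- function(traj, signal) {
  stopifnot(length(signal) == length(traj$times))
  thr <- max(signal) / 2
  above <- signal >= thr
  sum(diff(traj$times) * (utils::head(above, -1) & utils::tail(above, -1)))
}

#' Phospho-SMAD2 dose-response curve
#'
#' Total phosphorylated SMAD2 at a fixed evaluation time after TGF-beta
#' treatment, over a dose grid, normalized to the maximum over the set.
#'
#' @param net a `reaction_network`.
#' @param doses_ng_ml non-empty numeric vector of doses (ng/ml).
#' @param t_eval evaluation time (min), default 60.
#' @return data.frame with `dose_ng_ml`, `psmad2_um`, `normalized`.
#' @export
psmad2_dose_response <- function(net, doses_ng_ml, t_eval = 60) {
  if (!length(doses_ng_ml)) stop("empty dose list", call. = FALSE)
  vals <- vapply(doses_ng_ml, function(d) {
    tr <- simulate_tgfb(net, d, duration = max(t_eval * 2, 120),
                        times = seq(0, max(t_eval * 2, 120), length.out = 121))
    stats::approx(tr$times, psmad_total(tr, "SMAD2"), xout = t_eval)$y
  }, numeric(1))
  data.frame(dose_ng_ml = doses_ng_ml, psmad2_um = vals,
             normalized = vals / max(vals))
}

#' SMAD7 feedback experiment
#'
#' Paired simulations of a TGF-beta stimulation with SMAD7 synthesis intact
#' versus blocked (vm32 = 0), summarizing the late "tail" of nuclear
#' phospho-SMAD-SMAD4 signal and the activation AUC.
#'
#' @param net a `reaction_network`.
#' @param dose_ng_ml TGF-beta dose (> 0).
#' @param duration minutes, default 2880 (48 h).
#' @return list with both trajectories and a summary (AUCs over 24 h, late
#'   tail prominence after 20 h, minimum total SMAD4).
#' @export
smad7_feedback_experiment <- function(net, dose_ng_ml, duration = 2880) {
  stopifnot(dose_ng_ml > 0)
  base <- simulate_tgfb(net, dose_ng_ml, duration)
  blocked <- simulate_protocol(net, simulation_protocol(
    tgfb_ng_ml = dose_ng_ml, duration = duration,
    interventions = list(intervention("synthesis_block", target = "SMAD7"))))
  tail_stat <- function(tr) {
    # secondary late rise: max after 20 h minus the minimum between the
    # primary peak and 20 h
    y <- tr$conc[, "pS2S4_n"] + tr$conc[, "pS1S4_n"]
    t <- tr$times
    pk <- which.max(y)
    mid <- y[t >= t[pk] & t <= 1200]
    late <- y[t >= 1200]
    if (!length(mid) || !length(late)) return(0)
    max(late) - min(mid)
  }
  smad4_total <- function(tr) {
    species_total(tr, c("SMAD4", "SMAD4_n", "pS1S4_c", "pS2S4_c",
                        "pS1S4_n", "pS2S4_n"))
  }
  s4 <- smad4_total(base)
  list(intact = base, blocked = blocked,
       summary = list(
         auc_intact = auc(base, "pS2S4_n", c(0, 1440)),
         auc_blocked = auc(blocked, "pS2S4_n", c(0, 1440)),
         tail_intact = tail_stat(base),
         tail_blocked = tail_stat(blocked),
         smad4_min_over_initial = min(s4) / s4[1]))
}
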