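## Simulation protocols, stiff integration, trajectory readouts.

#' Default solver settings
#'
#' Stiff implicit integration (the network mixes second-scale binding with
#' day-scale gene expression). Tolerances are set so that halving both changes
#' every reported readout by well under 0.1 percent.
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerance (uM).
#' @param method a [deSolve::ode()] method.
#' @return list of solver settings.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-12, method = "lsoda") {
  list(rtol = rtol, atol = atol, method = method)
}

#' Define a simulation protocol
#'
#' A protocol bundles the environmental condition (oxygen tension, TGF-beta
#' dose), the duration and output grid, interventions applied as a step at
#' t = 0, and solver settings. Every protocol starts from the network's
#' normoxic (21 percent O2, no TGF-beta) steady state.
#'
#' @param oxygen_percent ambient oxygen tension, percent O2 in `[0, 21]`.
#' @param tgfb_ng_ml TGF-beta dose in ng/ml (converted internally at
#'   4e-5 uM per ng/ml).
#' @param duration simulated time in minutes (> 0).
#' @param times optional explicit output grid (minutes, strictly increasing,
#'   starting at 0); defaults to 481 evenly spaced points.
#' @param chx logical; cycloheximide treatment (zeroes every
#'   translation-tagged protein-synthesis rate for the whole run).
#' @param interventions list of [intervention()] objects.
#' @param solver [solver_settings()].
#' @return a `simulation_protocol` object.
#' @export
simulation_protocol <- function(oxygen_percent = 21, tgfb_ng_ml = 0,
                                duration = 1440, times = NULL, chx = FALSE,
                                interventions = list(),
                                solver = solver_settings()) {
  if (oxygen_percent < 0 || oxygen_percent > 21) {
    stop("oxygen_percent must lie in [0, 21]", call. = FALSE)
  }
  if (tgfb_ng_ml < 0) stop("tgfb_ng_ml must be >= 0", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (is.null(times)) times <- seq(0, duration, length.out = 481)
  if (any(diff(times) <= 0) || times[1] != 0) {
    stop("times must be strictly increasing from 0", call. = FALSE)
  }
  structure(list(oxygen_percent = oxygen_percent, tgfb_ng_ml = tgfb_ng_ml,
                 duration = duration, times = times, chx = chx,
                 interventions = interventions, solver = solver),
            class = "simulation_protocol")
}

## Dissolved-oxygen conversion: linear, 21 % O2 (in vitro normoxia) maps to
## 200 uM dissolved O2.
.O2_UM_PER_PERCENT <- 200 / 21

#' Oxygen condition
#'
#' Linear conversion between percent O2 and dissolved-oxygen concentration;
#' 21 percent (in vitro normoxia) corresponds to 200 uM.
#'
#' @param percent oxygen tension in percent, in `[0, 21]`.
#' @return list with `percent` and `um` (dissolved O2 in uM).
#' @export
oxygen_condition <- function(percent) {
  if (percent < 0 || percent > 21) {
    stop("oxygen percent must lie in [0, 21]", call. = FALSE)
  }
  list(percent = percent, um = percent * .O2_UM_PER_PERCENT)
}

## Stage the compiled network in the C++ module and integrate with the
## native right-hand side (avoids an R round-trip per solver step).
.ode_native <- function(cm, y, times, rtol, atol, method = "lsoda",
                        maxsteps = 5e5) {
  .load_model_cpp(cm$term_k, cm$term_sign, cm$term_rxn, cm$fct_term,
                  cm$fct_kind, cm$fct_s1, cm$fct_s2, cm$fct_par,
                  cm$st_sp, cm$st_rxn, cm$st_coef, cm$clamped,
                  cm$nspec, cm$nrxn)
  deSolve::ode(y = y, times = times, func = "tsp1net_derivs",
               dllname = "tsp1net", initfunc = "tsp1net_initmod",
               parms = numeric(0), method = method, rtol = rtol, atol = atol,
               maxsteps = maxsteps)
}

.ss_cache <- new.env(parent = emptyenv())

.state_key <- function(net) {
  txt <- paste(c(format(net$params, digits = 17),
                 format(net$species$init, digits = 17),
                 net$species$name), collapse = "|")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Solve for a steady state
#'
#' Finds the stationary state of the network under a given oxygen tension and
#' TGF-beta dose by damped long-time integration (staged horizons up to 1e6
#' minutes) followed by a residual check
#' `max_i |dx_i/dt| / max(|x_i|, 1e-9) < tol` (per minute). The normoxic
#' steady state (21 percent O2, no TGF-beta) is the default initial condition
#' of every simulation protocol.
#'
#' @param net a `reaction_network`.
#' @param oxygen_percent,tgfb_ng_ml the ambient condition.
#' @param tol stationarity tolerance (1/min), default 1e-8.
#' @param cache reuse a previously computed state for identical inputs.
#' @return named numeric steady-state vector (uM).
#' @export
find_steady_state <- function(net, oxygen_percent = 21, tgfb_ng_ml = 0,
                              tol = 1e-8, cache = TRUE) {
  net <- .condition_network(net, oxygen_percent, tgfb_ng_ml)
  key <- NULL
  if (cache) {
    key <- .state_key(net)
    hit <- .ss_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  f <- assemble_derivatives(net)
  cm <- compile_network(net)
  y <- initial_state(net)
  free <- which(!net$species$clamped)
  resid <- function(y) {
    dx <- f(0, y)
    max(abs(dx) / pmax(abs(y), 1e-9))
  }
  ## damped Newton with a pseudoinverse step (the network carries several
  ## conservation laws, so the Jacobian is singular along them)
  newton_polish <- function(y) {
    for (it in 1:40) {
      dx <- f(0, y)
      r <- max(abs(dx) / pmax(abs(y), 1e-9))
      if (r < tol) return(y)
      J <- matrix(0, length(free), length(free))
      for (k in seq_along(free)) {
        j <- free[k]
        h <- max(abs(y[j]), 1e-9) * 1e-7
        yp <- y
        yp[j] <- yp[j] + h
        J[, k] <- (f(0, yp)[free] - dx[free]) / h
      }
      sv <- svd(J)
      utdx <- crossprod(sv$u, dx[free])
      lambda <- max(sv$d) * 1e-6
      improved <- FALSE
      pinned <- y[free] == 0 & abs(dx[free]) < 1e-15
      for (trial in 1:10) {
        step <- -sv$v %*% (utdx * sv$d / (sv$d^2 + lambda^2))
        step[pinned] <- 0   # species resting at an exact zero equilibrium
        y2 <- y
        y2[free] <- pmax(y[free] + step, 0)
        if (resid(y2) < r) {
          improved <- TRUE
          break
        }
        lambda <- lambda * 10
      }
      if (!improved) return(y)   # no further progress
      y <- y2
    }
    y
  }
  horizons <- c(2e4, 2e5, 2e6)
  for (tmax in horizons) {
    if (resid(y) < tol) break
    sol <- .ode_native(cm, y, c(0, tmax), rtol = 1e-8, atol = 1e-12)
    y <- stats::setNames(pmax(sol[nrow(sol), -1], 0), names(y))
    y <- newton_polish(y)
  }
  r <- resid(y)
  if (r >= tol) {
    stop(sprintf("steady state did not converge: residual %.3e (tol %.1e)",
                 r, tol), call. = FALSE)
  }
  if (cache) .ss_cache[[key]] <- y
  y
}

## Set clamped oxygen and the free TGF-beta pool for a condition. Networks
## without these environmental species (e.g. toy models) accept only the
## default condition.
.condition_network <- function(net, oxygen_percent, tgfb_ng_ml) {
  init <- c(O2 = oxygen_condition(oxygen_percent)$um,
            TGFb = tgfb_dose_to_concentration(tgfb_ng_ml))
  present <- names(init) %in% net$species$name
  if (!present[1] && oxygen_percent != 21) {
    stop("network has no O2 species; cannot set an oxygen condition",
         call. = FALSE)
  }
  if (!present[2] && tgfb_ng_ml > 0) {
    stop("network has no TGFb species; cannot set a TGF-beta dose",
         call. = FALSE)
  }
  if (!any(present)) return(net)
  set_network(net, init = init[present])
}

#' Run a simulation protocol
#'
#' Equilibrates the network at normoxia without TGF-beta, then applies the
#' protocol condition (oxygen step, TGF-beta dose, interventions,
#' cycloheximide) at t = 0 and integrates the stiff ODE system over the
#' protocol's output grid.
#'
#' @param net a `reaction_network` (default the shipped TSP-1 network).
#' @param protocol a [simulation_protocol()].
#' @param from_state optional explicit initial state (uM), bypassing the
#'   normoxic pre-equilibration (used for chained protocols).
#' @return a `trajectory` object: time grid (min) x species matrix (uM).
#' @export
simulate_protocol <- function(net, protocol, from_state = NULL) {
  stopifnot(inherits(protocol, "simulation_protocol"))
  y0 <- if (is.null(from_state)) {
    find_steady_state(net, 21, 0)
  } else {
    from_state[net$species$name]
  }
  run <- set_network(net, init = y0)
  run <- .condition_network(run, protocol$oxygen_percent, protocol$tgfb_ng_ml)
  st <- initial_state(run)
  for (iv in protocol$interventions) {
    applied <- apply_intervention(run, st, iv)
    run <- applied$network
    st <- applied$state
  }
  if (protocol$chx) {
    applied <- apply_intervention(run, st, intervention("chx"))
    run <- applied$network
    st <- applied$state
  }
  sol <- .ode_native(compile_network(run), st, protocol$times,
                     rtol = protocol$solver$rtol,
                     atol = protocol$solver$atol,
                     method = protocol$solver$method)
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed before reaching the end of the protocol",
         call. = FALSE)
  }
  conc <- sol[, -1, drop = FALSE]
  conc[conc < 0 & conc > -1e-9] <- 0   # numerical floor for trace negatives
  structure(list(times = sol[, 1],
                 conc = conc,
                 species = colnames(sol)[-1],
                 protocol = protocol,
                 baseline = y0),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points (0-%g min), %d species\n",
              length(x$times), max(x$times), length(x$species)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_min = x$times, x$conc, check.names = FALSE)
}

#' Interpolate a species concentration at a time
#'
#' @param traj a `trajectory`.
#' @param species species name.
#' @param t time (min) within the trajectory support.
#' @return concentration in uM (linear interpolation on the output grid).
#' @export
species_at <- function(traj, species, t) {
  if (!species %in% traj$species) stop("unknown species: ", species, call. = FALSE)
  if (t < min(traj$times) || t > max(traj$times)) {
    stop("time outside trajectory support", call. = FALSE)
  }
  stats::approx(traj$times, traj$conc[, species], xout = t)$y
}

#' Fold change of a species relative to a reference level
#'
#' @param traj a `trajectory`.
#' @param species species name.
#' @param t evaluation time (min).
#' @param reference reference concentration (uM), must be positive; defaults
#'   to the pre-stimulus baseline stored with the trajectory.
#' @return dimensionless fold change.
#' @export
fold_change <- function(traj, species, t, reference = NULL) {
  if (is.null(reference)) reference <- unname(traj$baseline[species])
  if (!is.numeric(reference) || is.na(reference) || reference <= 0) {
    stop("reference must be a positive number", call. = FALSE)
  }
  species_at(traj, species, t) / reference
}

#' Area under a species time course
#'
#' Trapezoidal integral of a species (or a precomputed signal) over a time
#' window on the trajectory's output grid, in uM.min.
#'
#' @param traj a `trajectory`.
#' @param species species name, or a numeric vector of the same length as the
#'   time grid (a derived signal such as a phospho-protein total).
#' @param window `c(t0, t1)` in minutes, within the trajectory support.
#' @return the integral in uM.min.
#' @export
auc <- function(traj, species, window = range(traj$times)) {
  if (window[1] < min(traj$times) - 1e-9 || window[2] > max(traj$times) + 1e-9 ||
      window[1] >= window[2]) {
    stop("window outside trajectory support", call. = FALSE)
  }
  y <- if (is.character(species)) {
    if (!species %in% traj$species) stop("unknown species: ", species, call. = FALSE)
    traj$conc[, species]
  } else {
    stopifnot(length(species) == length(traj$times))
    species
  }
  tt <- traj$times
  keep <- tt >= window[1] & tt <= window[2]
  tt2 <- tt[keep]; y2 <- y[keep]
  # close the window edges exactly by interpolation
  if (!any(tt == window[1])) {
    tt2 <- c(window[1], tt2)
    y2 <- c(stats::approx(tt, y, window[1])$y, y2)
  }
  if (!any(tt == window[2])) {
    tt2 <- c(tt2, window[2])
    y2 <- c(y2, stats::approx(tt, y, window[2])$y)
  }
  sum(diff(tt2) * (utils::head(y2, -1) + utils::tail(y2, -1)) / 2)
}

#' Sum of a set of species along a trajectory
#'
#' Convenience for mass totals such as "every species containing
#' phosphorylated SMAD2".
#'
#' @param traj a `trajectory`.
#' @param species character vector of species names.
#' @return numeric vector over the time grid (uM).
#' @export
species_total <- function(traj, species) {
  bad <- setdiff(species, traj$species)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  rowSums(traj$conc[, species, drop = FALSE])
}
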