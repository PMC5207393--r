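## Normalized least-squares calibration against time-course datasets.

#' Normalize a time series
#'
#' @param values non-empty numeric vector (>= 0).
#' @param mode `"peak"` (divide by the maximum) or `"baseline"` (divide by
#'   the value at the first time point).
#' @return normalized values.
#' @export
normalize_series <- function(values, mode = c("peak", "baseline")) {
  mode <- match.arg(mode)
  if (!length(values)) stop("empty series", call. = FALSE)
  div <- if (mode == "peak") max(values) else values[1]
  if (!is.finite(div) || div <= 0) {
    stop("normalization divisor must be positive", call. = FALSE)
  }
  values / div
}

#' Construct a time-course calibration dataset
#'
#' @param species model species name the dataset reports.
#' @param times time points in minutes (non-negative, increasing).
#' @param values normalized measurements (>= 0).
#' @param oxygen_percent,tgfb_ng_ml,chx the experimental condition.
#' @param normalization `"peak"` or `"baseline"` (how both the data and the
#'   matching simulation are scaled before residuals are formed).
#' @param source free-text provenance (e.g. `"synthetic"`).
#' @return a `time_course_dataset` object.
#' @export
time_course_dataset <- function(species, times, values, oxygen_percent = 21,
                                tgfb_ng_ml = 0, chx = FALSE,
                                normalization = c("peak", "baseline"),
                                source = "synthetic") {
  normalization <- match.arg(normalization)
  stopifnot(length(times) == length(values), all(values >= 0),
            all(times >= 0), !is.unsorted(times, strictly = TRUE))
  structure(list(species = species, times = times, values = values,
                 oxygen_percent = oxygen_percent, tgfb_ng_ml = tgfb_ng_ml,
                 chx = chx, normalization = normalization, source = source),
            class = "time_course_dataset")
}

#' @export
as.data.frame.time_course_dataset <- function(x, ...) {
  data.frame(time_min = x$times, value = x$values, species = x$species,
             condition_id = sprintf("o2_%g_tgfb_%g%s", x$oxygen_percent,
                                    x$tgfb_ng_ml, if (x$chx) "_chx" else ""),
             normalization = x$normalization, source = x$source)
}

#' Specify a calibration problem
#'
#' @param parameters character vector of free parameter symbols.
#' @param lower,upper named (or positionally matched) positive bounds.
#' @param datasets list of [time_course_dataset()] objects.
#' @param maxit maximum optimizer iterations.
#' @return a `fit_spec` object.
#' @export
fit_spec <- function(parameters, lower, upper, datasets, maxit = 50) {
  lower <- rep_len(lower, length(parameters))
  upper <- rep_len(upper, length(parameters))
  stopifnot(all(lower > 0), all(lower < upper), length(datasets) >= 1)
  structure(list(parameters = parameters, lower = lower, upper = upper,
                 datasets = datasets, maxit = maxit),
            class = "fit_spec")
}

.simulate_dataset <- function(net, ds, params = NULL) {
  if (!is.null(params)) net <- set_network(net, params = params)
  dur <- max(ds$times, 1)
  times <- sort(unique(c(seq(0, dur, length.out = 97), ds$times)))
  tr <- simulate_protocol(net, simulation_protocol(
    oxygen_percent = ds$oxygen_percent, tgfb_ng_ml = ds$tgfb_ng_ml,
    duration = dur, times = times, chx = ds$chx))
  stats::approx(tr$times, tr$conc[, ds$species], xout = ds$times)$y
}

#' Residual vector of a calibration problem
#'
#' For each dataset the condition is simulated, the simulated species is
#' sampled at the dataset's times, both sides are normalized by the dataset's
#' mode, and the differences are concatenated.
#'
#' @param net a `reaction_network`.
#' @param params named numeric vector of trial parameter values.
#' @param spec a [fit_spec()].
#' @return numeric residual vector (simulation failures yield a large finite
#'   penalty so that optimization can continue, with a warning).
#' @export
calibration_residuals <- function(net, params, spec) {
  unlist(lapply(spec$datasets, function(ds) {
    sim <- tryCatch(.simulate_dataset(net, ds, params), error = function(e) {
      warning("integration failed during calibration: ", conditionMessage(e))
      NULL
    })
    if (is.null(sim) || any(!is.finite(sim))) {
      return(rep(1e3, length(ds$times)))
    }
    tryCatch(normalize_series(sim, ds$normalization) -
               normalize_series(ds$values, ds$normalization),
             error = function(e) rep(1e3, length(ds$times)))
  }))
}

#' Sum-of-squared-errors calibration objective
#'
#' @inheritParams calibration_residuals
#' @return scalar objective (>= 0; zero iff the normalized simulation
#'   interpolates the normalized data).
#' @export
sse_objective <- function(net, params, spec) {
  sum(calibration_residuals(net, params, spec)^2)
}

#' Fit parameters by bounded Levenberg-Marquardt least squares
#'
#' Minimizes the sum of squared errors between normalized simulations and
#' normalized measurements over the free parameters, on a log10 scale within
#' the stated bounds (Levenberg-Marquardt via [minpack.lm::nls.lm()]).
#'
#' Local least-squares fits of stiff ODE models are initialization
#' sensitive, so a seeded Latin-hypercube multi-start (over log-parameter
#' space within the bounds) is built in; the best local optimum is returned.
#'
#' @param net a `reaction_network`.
#' @param spec a [fit_spec()].
#' @param x0 named numeric start values (within bounds).
#' @param n_starts number of starts (1 = local fit from `x0` only; the
#'   additional starts are Latin-hypercube draws between the bounds).
#' @param seed seed for the multi-start draws.
#' @return list with `par` (fitted values), `objective`, `converged`,
#'   `iterations`, `residuals`, `n_starts`.
#' @export
fit_parameters <- function(net, spec, x0, n_starts = 1, seed = 1) {
  stopifnot(all(spec$parameters %in% names(x0)))
  x0 <- x0[spec$parameters]
  if (any(x0 < spec$lower | x0 > spec$upper)) {
    stop("x0 outside bounds", call. = FALSE)
  }
  fn <- function(logp) {
    pars <- stats::setNames(10^logp, spec$parameters)
    calibration_residuals(net, pars, spec)
  }
  starts <- list(log10(x0))
  if (n_starts > 1) {
    set.seed(seed)
    u <- lhs::randomLHS(n_starts - 1, length(spec$parameters))
    lo <- log10(spec$lower)
    hi <- log10(spec$upper)
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- lo + u[i, ] * (hi - lo)
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = st, lower = log10(spec$lower), upper = log10(spec$upper),
      fn = fn, control = minpack.lm::nls.lm.control(maxiter = spec$maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  par <- stats::setNames(10^best$par, spec$parameters)
  list(par = par, objective = best$deviance,
       converged = best$info %in% 1:4, iterations = best$niter,
       residuals = best$fvec, n_starts = n_starts)
}

#' Generate a synthetic calibration dataset from the model
#'
#' Simulates a condition, samples the stated species at the stated times,
#' applies multiplicative log-normal noise with the requested coefficient of
#' variation (seeded), and packages the result as a provenance-tagged
#' synthetic [time_course_dataset()].
#'
#' @param net a `reaction_network`.
#' @param species species name.
#' @param times sampling times (min).
#' @param oxygen_percent,tgfb_ng_ml,chx condition.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0; 0 reproduces the simulation exactly).
#' @param seed integer seed.
#' @param normalization `"peak"` or `"baseline"`.
#' @return a `time_course_dataset` with `source = "synthetic"`.
#' @export
generate_synthetic_dataset <- function(net, species, times,
                                       oxygen_percent = 21, tgfb_ng_ml = 0,
                                       chx = FALSE, noise_cv = 0, seed = 1,
                                       normalization = "peak") {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (!species %in% net$species$name) {
    stop("unknown species: ", species, call. = FALSE)
  }
  ds0 <- time_course_dataset(species, times, rep(0, length(times)),
                             oxygen_percent, tgfb_ng_ml, chx, normalization)
  sim <- .simulate_dataset(net, ds0)
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    sim <- sim * stats::rlnorm(length(sim), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
  }
  ds0$values <- normalize_series(sim, normalization)
  ds0
}
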