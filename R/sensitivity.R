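## Latin-hypercube sampling and partial rank correlation coefficients.

#' Define a global sensitivity design
#'
#' Each parameter is sampled log-uniformly over two orders of magnitude
#' centered on its nominal value (nominal/10 to nominal x 10) with one sample
#' per equal-probability stratum (Latin hypercube). The output functional is
#' the AUC of a species over a time window under a stated condition.
#'
#' @param parameters character vector of parameter symbols to sample.
#' @param nominal named numeric vector of nominal values (defaults to the
#'   network registry at experiment time).
#' @param n sample size (>= 10); 1000 reproduces the reference design size.
#' @param seed integer seed; the design is reproducible bit-for-bit.
#' @param span half-range in orders of magnitude (default 1, i.e. x/10..10x).
#' @param scale `"log"` (log-uniform marginal, default) or `"uniform"`.
#' @param output list with `species`, `window` (min), and a
#'   [simulation_protocol()] as `protocol`.
#' @return a `sensitivity_design` object.
#' @export
sensitivity_design <- function(parameters, nominal = NULL, n = 1000,
                               seed = 1, span = 1, scale = c("log", "uniform"),
                               output = NULL) {
  scale <- match.arg(scale)
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  if (!is.null(nominal)) {
    if (any(nominal[parameters] <= 0)) {
      stop("nominal values must be positive", call. = FALSE)
    }
  }
  structure(list(parameters = parameters, nominal = nominal, n = as.integer(n),
                 seed = as.integer(seed), span = span, scale = scale,
                 output = output),
            class = "sensitivity_design")
}

#' Latin hypercube sample of a sensitivity design
#'
#' @param design a [sensitivity_design()]; `design$nominal` must be set.
#' @return an `n x p` matrix of parameter values, columns named by parameter.
#' @export
lhs_sample <- function(design) {
  stopifnot(inherits(design, "sensitivity_design"))
  nom <- design$nominal[design$parameters]
  if (any(is.na(nom))) stop("nominal value missing for some parameter",
                            call. = FALSE)
  p <- length(design$parameters)
  set.seed(design$seed)
  u <- lhs::randomLHS(design$n, p)
  lo <- nom / 10^design$span
  hi <- nom * 10^design$span
  x <- if (design$scale == "log") {
    exp(sweep(sweep(u, 2, log(hi / lo), `*`), 2, log(lo), `+`))
  } else {
    sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  }
  colnames(x) <- design$parameters
  x
}

#' Partial rank correlation coefficients
#'
#' For each sampled parameter, all columns and the output are rank-transformed
#' (ties get average ranks); the parameter's ranks and the output's ranks are
#' each regressed on the remaining rank-transformed parameters, and the PRCC
#' is the Pearson correlation of the two residual vectors. Significance is the
#' two-sided p-value of the t statistic with `n - 2 - (p - 1)` degrees of
#' freedom. Constant (rank-degenerate) columns are flagged with `NA`.
#'
#' @param samples n x p numeric matrix (columns named by parameter).
#' @param outputs numeric vector of length n (finite).
#' @return data.frame with `parameter`, `prcc`, `p_value`, `degenerate`.
#' @export
prcc <- function(samples, outputs) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  p <- ncol(samples)
  if (n <= p + 2) stop("need n > p + 2 samples", call. = FALSE)
  if (any(!is.finite(outputs))) stop("outputs must be finite", call. = FALSE)
  if (length(outputs) != n) stop("outputs length must match samples", call. = FALSE)
  rx <- apply(samples, 2, rank)
  ry <- rank(outputs)
  degen <- apply(samples, 2, function(col) length(unique(col)) < 2)
  if (length(unique(outputs)) < 2) degen[] <- TRUE
  vals <- pvals <- rep(NA_real_, p)
  dof <- n - 2 - (p - 1)
  for (j in seq_len(p)) {
    if (degen[j]) next
    others <- rx[, -j, drop = FALSE]
    keep <- !apply(others, 2, function(col) length(unique(col)) < 2)
    others <- others[, keep, drop = FALSE]
    res_x <- if (ncol(others)) stats::lm.fit(cbind(1, others), rx[, j])$residuals
             else rx[, j] - mean(rx[, j])
    res_y <- if (ncol(others)) stats::lm.fit(cbind(1, others), ry)$residuals
             else ry - mean(ry)
    r <- suppressWarnings(stats::cor(res_x, res_y))
    vals[j] <- r
    if (is.finite(r) && abs(r) < 1 && dof > 0) {
      tstat <- r * sqrt(dof / (1 - r^2))
      pvals[j] <- 2 * stats::pt(-abs(tstat), df = dof)
    }
  }
  data.frame(parameter = colnames(samples), prcc = vals, p_value = pvals,
             degenerate = degen, row.names = NULL)
}

## Parameter subsets of the four standard sensitivity scenarios.
.scenario_params <- list(
  hif_dimer_hypoxia = c("kf1", "kf2", "kf4", "kf7", "kf8", "kf11", "kf13",
                        "kf18", "kf19", "vm1", "vm2"),
  psmad_tgfb = c("kf66", "kf72", "kf73", "kf74", "kf75", "kf76", "kf77",
                 "kf78", "kf79", "kf82", "kf89", "vm32", "vm34", "vm36"),
  tsp1_myc = c("vm1", "vm2", "vm3", "vm5", "vm6", "vm7", "vm9", "vm11",
               "vm13", "vm18", "vm19", "vm20"),
  tsp1_cli = c("vm1", "vm2", "vm3", "vm5", "vm6", "vm7", "vm11", "vm13",
               "vm20", "vm27", "vm29", "vm32")
)

#' Standard sensitivity scenarios
#'
#' Four preconfigured global-sensitivity experiments: (A) AUC of the nuclear
#' HIF-1 dimer over 48 h at 2 percent O2; (B) AUC of the nuclear activated
#' SMAD2-SMAD4 complex over 24 h at 2.5 ng/ml TGF-beta; (C) AUC of TSP-1
#' protein over 24 h in normoxia with hyperactive Myc; (D) AUC of TSP-1 over
#' 24 h under 2.5 ng/ml TGF-beta plus 2 percent O2. Each samples the
#' module-relevant parameter subset.
#'
#' @param name one of `"hif_dimer_hypoxia"`, `"psmad_tgfb"`, `"tsp1_myc"`,
#'   `"tsp1_cli"`.
#' @param n,seed design size and seed.
#' @return a [sensitivity_design()] with the scenario protocol attached.
#' @export
sensitivity_scenario <- function(name = c("hif_dimer_hypoxia", "psmad_tgfb",
                                          "tsp1_myc", "tsp1_cli"),
                                 n = 1000, seed = 1) {
  name <- match.arg(name)
  out <- switch(name,
    hif_dimer_hypoxia = list(
      species = "HIF1d_n", window = c(0, 2880),
      protocol = simulation_protocol(oxygen_percent = 2, duration = 2880,
                                     times = seq(0, 2880, length.out = 145))),
    psmad_tgfb = list(
      species = "pS2S4_n", window = c(0, 1440),
      protocol = simulation_protocol(tgfb_ng_ml = 2.5, duration = 1440,
                                     times = seq(0, 1440, length.out = 145))),
    tsp1_myc = list(
      species = "TSP1", window = c(0, 1440),
      protocol = simulation_protocol(duration = 1440,
        times = seq(0, 1440, length.out = 145),
        interventions = list(intervention("synthesis_scale", target = "Myc",
                                          factor = 5)))),
    tsp1_cli = list(
      species = "TSP1", window = c(0, 1440),
      protocol = simulation_protocol(oxygen_percent = 2, tgfb_ng_ml = 2.5,
                                     duration = 1440,
                                     times = seq(0, 1440, length.out = 145))))
  sensitivity_design(.scenario_params[[name]], n = n, seed = seed, output = out)
}

#' Run a global sensitivity experiment
#'
#' Draws a Latin hypercube over the design's parameters, re-solves the
#' normoxic steady state for every sampled parameter vector, simulates the
#' design's condition, computes the output AUC, and returns PRCCs. Failed
#' integrations are excluded and counted; more than 10 percent failures
#' aborts the experiment.
#'
#' @param net a `reaction_network`.
#' @param design a [sensitivity_design()] with an `output` entry (see
#'   [sensitivity_scenario()]).
#' @return a `sensitivity_result`: list with the PRCC table (sorted by
#'   `|prcc|` descending, ties by name), outputs, failure count, design.
#' @export
sensitivity_experiment <- function(net, design) {
  stopifnot(inherits(design, "sensitivity_design"), !is.null(design$output))
  if (is.null(design$nominal)) design$nominal <- net$params
  x <- lhs_sample(design)
  out <- design$output
  outputs <- rep(NA_real_, design$n)
  for (i in seq_len(design$n)) {
    outputs[i] <- tryCatch({
      net_i <- set_network(net, params = stats::setNames(x[i, ],
                                                         design$parameters))
      ss <- find_steady_state(net_i, 21, 0, cache = FALSE)
      tr <- simulate_protocol(net_i, out$protocol, from_state = ss)
      auc(tr, out$species, out$window)
    }, error = function(e) NA_real_)
  }
  failed <- sum(!is.finite(outputs))
  if (failed > 0.1 * design$n) {
    stop(sprintf("sensitivity experiment failed in %d/%d runs", failed,
                 design$n), call. = FALSE)
  }
  ok <- is.finite(outputs)
  tab <- prcc(x[ok, , drop = FALSE], outputs[ok])
  ord <- order(-abs(ifelse(is.na(tab$prcc), -Inf, tab$prcc)), tab$parameter)
  structure(list(prcc = tab[ord, ], outputs = outputs, n_failed = failed,
                 design = design),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> n=%d (failed %d), %d parameters\n",
              x$design$n, x$n_failed, length(x$design$parameters)))
  print(x$prcc, row.names = FALSE)
  invisible(x)
}
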