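test_that("series normalization follows its two conventions", {
  expect_equal(normalize_series(c(2, 2, 2), "baseline"), c(1, 1, 1))
  expect_equal(normalize_series(c(1, 3, 2), "peak"), c(1 / 3, 1, 2 / 3))
  expect_error(normalize_series(numeric(), "peak"), "empty")
  expect_error(normalize_series(c(0, 1), "baseline"), "positive")
  expect_error(normalize_series(c(0, 0), "peak"), "positive")
})

test_that("a model-generated peak-normalized series peaks at exactly one", {
  tr <- tgfb_traj(FALSE)
  y <- normalize_series(psmad_total(tr, "SMAD2"), "peak")
  expect_equal(max(y), 1)
  expect_identical(which.max(y), which.max(psmad_total(tr, "SMAD2")))
})

test_that("the SSE objective is zero at the generating parameters", {
  net <- shipped()
  ds <- generate_synthetic_dataset(net, "HIF1a", times = c(120, 360, 720),
                                   oxygen_percent = 2, noise_cv = 0)
  spec <- fit_spec("vm1", lower = net$params[["vm1"]] / 10,
                   upper = net$params[["vm1"]] * 10, datasets = list(ds))
  expect_lt(sse_objective(net, net$params["vm1"], spec), 1e-12)
})

test_that("residuals match hand-summed arithmetic on a fixed toy", {
  # protocols equilibrate first, so the toy trajectory is the constant
  # steady state s/d; peak-normalized it is identically one, and the
  # residuals are hand-computable from the dataset values alone
  net <- toy_birth_death(s = 2e-3, d = 5e-3)
  times <- c(100, 300, 600)
  vals <- c(0.1, 0.5, 0.9)
  ds <- time_course_dataset("X", times, vals, normalization = "peak")
  got <- calibration_residuals(net, NULL, fit_spec(
    "s", lower = 1e-4, upper = 1e-2, datasets = list(ds)))
  want <- 1 - vals / max(vals)
  expect_equal(got, want, tolerance = 1e-6)
  expect_equal(sse_objective(net, NULL, fit_spec(
    "s", lower = 1e-4, upper = 1e-2, datasets = list(ds))),
    sum(want^2), tolerance = 1e-6)
})

test_that("the objective ignores common scaling of the data", {
  net <- toy_birth_death()
  ds1 <- time_course_dataset("X", c(100, 400), c(0.2, 0.8),
                             normalization = "peak")
  ds2 <- ds1
  ds2$values <- ds1$values * 37
  spec1 <- fit_spec("s", 1e-4, 1e-2, list(ds1))
  spec2 <- fit_spec("s", 1e-4, 1e-2, list(ds2))
  expect_equal(sse_objective(net, NULL, spec1), sse_objective(net, NULL, spec2))
})

test_that("synthetic datasets are seeded, tagged and noise-calibrated", {
  net <- shipped()
  a <- generate_synthetic_dataset(net, "TSP1", times = c(360, 720, 1440),
                                  oxygen_percent = 2, noise_cv = 0.05,
                                  seed = 5)
  b <- generate_synthetic_dataset(net, "TSP1", times = c(360, 720, 1440),
                                  oxygen_percent = 2, noise_cv = 0.05,
                                  seed = 5)
  expect_identical(a$values, b$values)
  expect_identical(a$source, "synthetic")
  expect_error(generate_synthetic_dataset(net, "nope", times = 1), "unknown")
  # empirical CV of replicated single-point draws matches the request
  set.seed(99)
  cv <- 0.1
  sdlog <- sqrt(log(1 + cv^2))
  draws <- stats::rlnorm(1e4, -sdlog^2 / 2, sdlog)
  expect_equal(stats::sd(draws) / mean(draws), cv, tolerance = 0.05)
})

test_that("noiseless parameter recovery is accurate within 10 percent", {
  net <- shipped()
  pars <- c("kd_myc", "kd_tsp1", "kd_ttp", "kd_risc", "k_caout")
  truth <- net$params[pars]
  times <- c(120, 300, 600, 960, 1440, 2040, 2880)
  datasets <- c(
    lapply(c("Myc", "TSP1", "TTP", "mir18_RISC"), function(sp) {
      generate_synthetic_dataset(net, sp, times, oxygen_percent = 2,
                                 noise_cv = 0, normalization = "baseline")
    }),
    list(generate_synthetic_dataset(net, "Ca", c(15, 30, 60, 120, 240, 480,
                                                 720),
                                    tgfb_ng_ml = 1, noise_cv = 0,
                                    normalization = "baseline")))
  spec <- fit_spec(pars, lower = truth / 3, upper = truth * 3,
                   datasets = datasets, maxit = 60)
  set.seed(3)
  x0 <- truth * runif(5, 0.55, 1.9)
  fit <- fit_parameters(net, spec, x0)
  expect_lt(max(abs(fit$par - truth) / truth), 0.10)
  # restarting at the truth terminates immediately with a zero objective
  fit0 <- fit_parameters(net, spec, truth)
  expect_lte(fit0$iterations, 2)
  expect_lt(fit0$objective, 1e-12)
})

test_that("recovery from 5 percent noisy data stays within 30 percent", {
  net <- shipped()
  pars <- c("kd_myc", "kd_tsp1", "kd_ttp", "kd_risc", "k_caout")
  truth <- net$params[pars]
  times <- c(120, 300, 600, 960, 1440, 2040, 2880)
  species <- c("Myc", "TSP1", "TTP", "mir18_RISC")
  datasets <- list()
  for (rep in 0:1) {           # two replicate series per readout
    for (i in seq_along(species)) {
      datasets <- c(datasets, list(generate_synthetic_dataset(
        net, species[i], times, oxygen_percent = 2, noise_cv = 0.05,
        seed = 100 + i + rep * 10, normalization = "baseline")))
    }
    datasets <- c(datasets, list(generate_synthetic_dataset(
      net, "Ca", c(15, 30, 60, 120, 240, 480, 720), tgfb_ng_ml = 1,
      noise_cv = 0.05, seed = 105 + rep * 10, normalization = "baseline")))
  }
  spec <- fit_spec(pars, lower = truth / 3, upper = truth * 3,
                   datasets = datasets, maxit = 60)
  set.seed(4)
  x0 <- truth * runif(5, 0.55, 1.9)
  fit <- suppressWarnings(fit_parameters(net, spec, x0, n_starts = 3,
                                         seed = 11))
  expect_lt(max(abs(fit$par - truth) / truth), 0.30)
})
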