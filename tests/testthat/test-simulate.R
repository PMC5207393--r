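test_that("steady-state solver matches closed forms and stays put", {
  net <- toy_birth_death(s = 2e-3, d = 5e-3)
  ss <- find_steady_state(net, cache = FALSE)
  expect_equal(ss[["X"]], 2e-3 / 5e-3, tolerance = 1e-8)
  # shipped network: the packaged initial conditions are the normoxic steady
  # state; re-solving returns them unchanged
  net2 <- shipped()
  ss2 <- normoxic_ss()
  expect_equal(unname(ss2), unname(initial_state(net2)), tolerance = 1e-4)
  # long-time integration from a perturbed (conservation-preserving) start
  # returns to the same fixed point
  f <- assemble_derivatives(net)
  y <- c(X = 10)
  sol <- deSolve::ode(y, c(0, 1e6), function(t, y, p) list(f(t, y)),
                      method = "lsoda", rtol = 1e-10, atol = 1e-14)
  expect_equal(unname(sol[2, "X"]), ss[["X"]], tolerance = 1e-6)
})

test_that("trajectories respect the non-negativity floor", {
  tr <- hypoxia_traj()
  expect_gt(min(tr$conc), -10 * tr$protocol$solver$atol)
})

test_that("AUC reproduces hand-computed integrals and converges", {
  tr <- structure(list(times = seq(0, 10, 0.5),
                       conc = cbind(const = rep(3, 21),
                                    ramp = seq(0, 1, length.out = 21)),
                       species = c("const", "ramp")),
                  class = "trajectory")
  expect_equal(auc(tr, "const"), 30)
  expect_equal(auc(tr, "ramp"), 5)                 # exact for the trapezoid
  expect_equal(auc(tr, "const", c(2, 7)), 15)
  expect_error(auc(tr, "const", c(-1, 5)), "window")
  # trapezoid error on a quadratic shrinks ~4x when the grid is refined 2x
  quad_err <- function(n) {
    t <- seq(0, 1, length.out = n)
    trq <- structure(list(times = t, conc = cbind(q = t^2), species = "q"),
                     class = "trajectory")
    abs(auc(trq, "q") - 1 / 3)
  }
  expect_equal(quad_err(51) / quad_err(101), 4, tolerance = 0.1)
})

test_that("fold change and interpolation behave as ratios", {
  tr <- structure(list(times = c(0, 10, 20),
                       conc = cbind(x = c(2, 4, 8)), species = "x",
                       baseline = c(x = 2)),
                  class = "trajectory")
  expect_equal(fold_change(tr, "x", 0), 1)
  expect_equal(fold_change(tr, "x", 20, reference = 2), 4)
  expect_equal(species_at(tr, "x", 5), 3)          # piecewise linear
  expect_equal(fold_change(tr, "x", 15, reference = 3), 2)
  expect_error(fold_change(tr, "x", 10, reference = 0), "positive")
  expect_error(species_at(tr, "x", 25), "support")
})

test_that("halving the solver tolerances leaves readouts unchanged", {
  net <- shipped()
  readouts <- function(solver) {
    tr <- simulate_protocol(net, simulation_protocol(
      oxygen_percent = 2, duration = 1440, solver = solver))
    c(fold_change(tr, "TSP1", 1440), auc(tr, "HIF1d_n", c(0, 1440)),
      fold_change(tr, "Myc", 1440))
  }
  a <- readouts(solver_settings())
  b <- readouts(solver_settings(rtol = 5e-9, atol = 5e-13))
  expect_lt(max(abs(a - b) / abs(a)), 1e-3)
})

test_that("protocol validation rejects bad inputs", {
  expect_error(simulation_protocol(duration = 0), "positive")
  expect_error(simulation_protocol(tgfb_ng_ml = -1), ">= 0")
  expect_error(simulation_protocol(times = c(5, 10)), "increasing from 0")
})
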