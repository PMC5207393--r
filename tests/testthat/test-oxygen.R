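test_that("oxygen conversion is linear, monotone and bounded", {
  expect_equal(oxygen_condition(21)$um, 200)
  expect_equal(oxygen_condition(0)$um, 0)
  expect_equal(oxygen_condition(7)$um, oxygen_condition(14)$um / 2)
  expect_error(oxygen_condition(25), "\\[0, 21\\]")
  expect_error(oxygen_condition(-1), "\\[0, 21\\]")
  expect_error(simulate_oxygen_shift(shipped(), 30, 60), "\\[0, 21\\]")
})

test_that("the normoxic steady state is a fixed point of the dynamics", {
  net <- shipped()
  tr <- simulate_protocol(net, simulation_protocol(
    oxygen_percent = 21, duration = 2880, times = c(0, 1440, 2880)))
  rel <- abs(tr$conc[3, ] - tr$conc[1, ]) / pmax(abs(tr$conc[1, ]), 1e-9)
  expect_lt(max(rel), 1e-4)
})

test_that("2 percent oxygen reproduces the reported expression directions", {
  tr <- hypoxia_traj()
  up <- c("HIF1a", "HIF2a", "HIF1d_n", "HIF2d_n", "p53", "MXI1", "PSAP",
          "TSP1", "let7")
  down <- c("AGO1", "Dicer", "Myc", "mir18")
  for (s in up) expect_gt(fold_change(tr, s, 1440), 1)
  for (s in down) expect_lt(fold_change(tr, s, 1440), 1)
})

test_that("hydroxylation shuts off without oxygen substrate", {
  net <- shipped()
  ss0 <- find_steady_state(net, 0, 0)
  fl <- reaction_fluxes(net, ss0)
  # oxygen-binding steps and both hydroxylation (catalytic) steps are silent
  for (id in c("v7", "v10", "v12", "v15", "v18", "v21")) {
    expect_lt(abs(fl[[id]]), 1e-12)
  }
  # and HIF-1alpha accumulates relative to normoxia
  expect_gt(ss0["HIF1a"], 2 * normoxic_ss()["HIF1a"])
})

test_that("HIF-1 dimer exposure increases monotonically with hypoxic depth", {
  net <- shipped()
  aucs <- vapply(c(21, 2, 1), function(p) {
    tr <- simulate_oxygen_shift(net, p, 2880)
    auc(tr, "HIF1d_n", c(0, 2880))
  }, numeric(1))
  expect_lt(aucs[1], aucs[2])
  expect_lt(aucs[2], aucs[3])
})

test_that("hydroxylase affinity weakly suppresses and dimerization shapes HIF-1", {
  net <- shipped()
  base <- simulate_oxygen_shift(net, 2, 1440)
  dimer_auc <- auc(base, "HIF1d_n", c(0, 1440))
  # stronger HIF-hydroxylase binding (kf2, kf7) lowers the dimer exposure
  up <- set_network(net, params = net$params[c("kf2", "kf7")] * 3)
  tr2 <- simulate_protocol(up, simulation_protocol(oxygen_percent = 2,
                                                   duration = 1440))
  expect_lt(auc(tr2, "HIF1d_n", c(0, 1440)), dimer_auc)
  # faster dimerization (kf19) raises the dimer but lowers total HIF-1alpha
  # through the TTP feedback
  up19 <- set_network(net, params = net$params["kf19"] * 4)
  tr3 <- simulate_protocol(up19, simulation_protocol(oxygen_percent = 2,
                                                     duration = 1440))
  expect_gt(auc(tr3, "HIF1d_n", c(0, 1440)), dimer_auc)
  tot1a <- function(tr) {
    species_total(tr, c("HIF1a", "HIF1a_n", "HIF1d_n", "HIF1a_FIHc",
                        "HIF1a_PHDc"))
  }
  expect_lt(mean(tot1a(tr3)), mean(tot1a(base)))
})

test_that("oxygen dose response interface validates its inputs", {
  expect_error(tsp1_oxygen_dose_response(shipped(), o2_grid = c(0.1, 5)),
               "0.5")
  expect_error(tsp1_oxygen_dose_response(shipped(), t_eval_h = -2), "positive")
})
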