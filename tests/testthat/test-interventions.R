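test_that("intervention constructors validate their arguments", {
  expect_error(intervention("teleport"), "allowed")
  expect_error(intervention("binding_inhibitor", target = "Myc", dose = 10,
                            units = "mg"), "nM or uM")
  expect_error(intervention("synthesis_scale", target = "Myc", factor = -1))
})

test_that("synthesis scaling multiplies only the target synthesis rate", {
  net <- shipped()
  st <- normoxic_ss()
  out <- apply_intervention(net, st, intervention("synthesis_scale",
                                                  target = "Myc", factor = 5))
  expect_equal(out$network$params[["ktl_myc"]], 5 * net$params[["ktl_myc"]])
  expect_identical(out$network$params[["vm3"]], net$params[["vm3"]])
  expect_identical(out$state, st)
  expect_error(apply_intervention(net, st, intervention("synthesis_scale",
                                                        target = "O2",
                                                        factor = 2)),
               "no synthesis reaction")
})

test_that("cycloheximide zeroes every translation rate and nothing else", {
  net <- shipped()
  out <- apply_intervention(net, normoxic_ss(), intervention("chx"))
  ids <- reactions_with_tag(net, "translation")
  expect_gt(length(ids), 10)
  for (id in ids) {
    k <- net$reactions[[id]]$fwd$k
    expect_identical(unname(out$network$params[[k]]), 0)
  }
  # transcription rates keep running
  expect_gt(out$network$params[["vm20"]], 0)
  expect_gt(out$network$params[["vm3"]], 0)
})

test_that("rate modifiers and initial bumps are applied literally", {
  net <- shipped()
  st <- normoxic_ss()
  out <- apply_intervention(net, st, intervention("rate_modifier",
                                                  target = "vm29",
                                                  factor = 0.3))
  expect_equal(out$network$params[["vm29"]], 0.3 * net$params[["vm29"]])
  out2 <- apply_intervention(net, st, intervention("initial_bump",
                                                   target = "pre_mir18",
                                                   amount = 0.04))
  expect_equal(out2$state[["pre_mir18"]], st[["pre_mir18"]] + 0.04)
  expect_error(apply_intervention(net, st, intervention("rate_modifier",
                                                        target = "zz",
                                                        factor = 1)),
               "unknown parameter")
})

test_that("binding inhibitors follow the equilibrium isotherm", {
  # inert target with no turnover: after the inhibitor equilibrates, the
  # bound fraction must satisfy the quadratic binding isotherm
  net <- build_network(
    data.frame(name = "T", compartment = "cytoplasm", init = 0.05),
    list(), numeric())
  st <- initial_state(net)
  Kd <- 1e-3; dose_um <- 0.2
  out <- apply_intervention(net, st, intervention(
    "binding_inhibitor", target = "T", dose = 200, units = "nM", Kd = Kd))
  expect_true("T_inhibitor" %in% out$network$species$name)
  tr <- simulate_protocol(out$network, simulation_protocol(
    duration = 5000, times = c(0, 5000)), from_state = out$state)
  bound <- unname(tr$conc[2, "T_inhibitor_cplx"])
  # independent oracle: root of b^2 - b(T0 + D + Kd) + T0 D = 0
  T0 <- 0.05
  want <- ((T0 + dose_um + Kd) - sqrt((T0 + dose_um + Kd)^2 -
                                        4 * T0 * dose_um)) / 2
  expect_equal(bound, want, tolerance = 1e-6)
  # dose >> Kd sequesters nearly everything
  expect_gt(bound / T0, 0.98)
})

test_that("the shipped inhibitor species are used for the standard targets", {
  net <- shipped()
  st <- normoxic_ss()
  out <- apply_intervention(net, st, intervention(
    "binding_inhibitor", target = "p53", dose = 200))
  expect_identical(nrow(out$network$species), nrow(net$species))
  expect_equal(out$state[["p53I"]], 0.2)
})

test_that("dose scans recover baseline at dose zero and locate plateaus", {
  net <- shipped()
  proto <- simulation_protocol(duration = 480,
                               times = seq(0, 480, length.out = 49))
  base <- fold_change(simulate_protocol(net, proto), "p53", 480)
  sc <- dose_scan(net, function(d) intervention("binding_inhibitor",
                                                target = "p53", dose = d),
                  c(0, 50, 200, 400, 800, 1600),
                  function(tr) fold_change(tr, "p53", 480), proto,
                  refine = 3)
  expect_equal(sc$readout[1], base)
  expect_true(all(diff(sc$readout) < 1e-6))      # p53 falls with dose
  expect_gt(sc$plateau_dose_nm, 0)
  expect_lt(sc$plateau_dose_nm, 1600)
})
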