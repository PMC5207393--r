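test_that("the transcription function is multiplicative in its activators", {
  net <- shipped()
  ss <- normoxic_ss()
  base <- list(HIF2d_n = ss[["HIF2d_n"]], Myc_n = ss[["Myc_n"]],
               MXI1_n = ss[["MXI1_n"]], pS2S4_n = 1e-4,
               NFATd_n = ss[["NFATd_n"]], p53 = ss[["p53"]])
  rate0 <- tsp1_transcription_rate(net, base)
  pairs <- list(c("HIF2d_n", "p53"), c("NFATd_n", "HIF2d_n"),
                c("p53", "NFATd_n"))
  for (pr in pairs) {
    a <- base; a[[pr[1]]] <- 2 * a[[pr[1]]]
    b <- base; b[[pr[2]]] <- 2 * b[[pr[2]]]
    ab <- base; ab[[pr[1]]] <- 2 * ab[[pr[1]]]; ab[[pr[2]]] <- 2 * ab[[pr[2]]]
    fold_a <- tsp1_transcription_rate(net, a) / rate0
    fold_b <- tsp1_transcription_rate(net, b) / rate0
    fold_ab <- tsp1_transcription_rate(net, ab) / rate0
    expect_equal(fold_a * fold_b, fold_ab, tolerance = 1e-9)
  }
})

test_that("activators lift and Myc weakly represses transcription", {
  net <- shipped()
  zero <- list(HIF2d_n = 0, Myc_n = 0, MXI1_n = 0, pS2S4_n = 0, NFATd_n = 0,
               p53 = 0)
  basal <- tsp1_transcription_rate(net, zero)
  expect_gt(basal, 0)
  for (act in c("HIF2d_n", "pS2S4_n", "NFATd_n", "p53")) {
    up <- zero; up[[act]] <- 1
    expect_gt(tsp1_transcription_rate(net, up), basal)
  }
  myc <- zero; myc$Myc_n <- 0.5
  expect_lt(tsp1_transcription_rate(net, myc), basal)
})

test_that("MXI-1 counteracts Myc on the TSP-1 promoter", {
  net <- shipped()
  zero <- list(HIF2d_n = 0, Myc_n = 0, MXI1_n = 0, pS2S4_n = 0, NFATd_n = 0,
               p53 = 0)
  basal <- tsp1_transcription_rate(net, zero)
  myc <- zero; myc$Myc_n <- 0.5
  repressed <- tsp1_transcription_rate(net, myc)
  both <- myc; both$MXI1_n <- 0.5
  countered <- tsp1_transcription_rate(net, both)
  expect_gt(countered, repressed)
  expect_lt(abs(countered - basal), abs(repressed - basal))
})

test_that("the normoxic steady state balances TSP-1 mRNA production", {
  net <- shipped()
  ss <- normoxic_ss()
  fl <- reaction_fluxes(net, ss)
  # at steady state: transcription = export; export = decay + net repression;
  # net repression = repressed-pool decay
  expect_equal(fl[["v76"]], fl[["v77"]], tolerance = 1e-6)
  expect_equal(fl[["v77"]], fl[["v78"]] + fl[["v79"]], tolerance = 1e-4)
  expect_equal(fl[["v79"]], fl[["v80"]], tolerance = 1e-4)
})

test_that("the Myc axis responds to hypoxia and to HIF clamping", {
  net <- shipped()
  tr <- hypoxia_traj()
  for (s in c("MXI1", "PSAP", "p53")) expect_gt(fold_change(tr, s, 1440), 1)
  expect_lt(fold_change(tr, "Myc", 1440), 1)
  # with HIF-1alpha clamped at zero the HIF-driven Myc degradation vanishes
  ss <- normoxic_ss()
  st0 <- ss; st0["HIF1a"] <- 0
  fx <- myc_p53_axis_fluxes(net, st0)
  expect_equal(fx$value_um_min[fx$flux == "myc_degradation_hif"], 0)
  fx1 <- myc_p53_axis_fluxes(net, ss)
  expect_gt(fx1$value_um_min[fx1$flux == "myc_degradation_hif"], 0)
})

test_that("Myc hyperactivity suppresses TSP-1, less so in hypoxia", {
  net <- shipped()
  hyper <- list(intervention("synthesis_scale", target = "Myc", factor = 5))
  trH <- memo("hyper21", simulate_protocol(net, simulation_protocol(
    duration = 2880, interventions = hyper)))
  expect_lt(fold_change(trH, "TSP1", 1440), 1)
  expect_lt(fold_change(trH, "TSP1", 2880), 1)
  trHh <- memo("hyper2", simulate_protocol(net, simulation_protocol(
    oxygen_percent = 2, duration = 2880, interventions = hyper)))
  hyp_alone <- fold_change(hypoxia_traj(), "TSP1", 2880)
  hyp_hyper <- fold_change(trHh, "TSP1", 2880)
  expect_lt(hyp_hyper, hyp_alone)               # still hinders the induction
  expect_gt(hyp_hyper, 1)                        # but TSP-1 stays induced
  # relative suppression is weaker in hypoxia than in normoxia
  expect_gt(hyp_hyper / hyp_alone, fold_change(trH, "TSP1", 2880))
})
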