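test_that("TGF-beta dose conversion is the printed linear factor", {
  expect_equal(tgfb_dose_to_concentration(1), 4e-5)
  expect_equal(tgfb_dose_to_concentration(0), 0)
  expect_equal(tgfb_dose_to_concentration(2.5), 1e-4)
  expect_error(tgfb_dose_to_concentration(-1), ">= 0")
})

test_that("without ligand the phospho-SMAD signal stays at baseline", {
  tr <- simulate_tgfb(shipped(), 0, 720)
  ps <- psmad_total(tr, "SMAD2")
  expect_lt(max(ps) - min(ps), 1e-9)
})

test_that("cycloheximide prolongs the phospho-SMAD plateaus", {
  t_no <- time_above_half_peak(tgfb_traj(FALSE),
                               psmad_total(tgfb_traj(FALSE), "SMAD2"))
  t_chx <- time_above_half_peak(tgfb_traj(TRUE),
                                psmad_total(tgfb_traj(TRUE), "SMAD2"))
  expect_gt(t_chx, t_no)
  t1_no <- time_above_half_peak(tgfb_traj(FALSE),
                                psmad_total(tgfb_traj(FALSE), "SMAD1"))
  t1_chx <- time_above_half_peak(tgfb_traj(TRUE),
                                 psmad_total(tgfb_traj(TRUE), "SMAD1"))
  expect_gt(t1_chx, t1_no)
  # and the signal itself rises then declines in the untreated arm
  ps <- psmad_total(tgfb_traj(FALSE), "SMAD2")
  expect_gt(max(ps), 2 * ps[length(ps)])
})

test_that("SMAD2 mass is conserved when synthesis and degradation are off", {
  net <- shipped()
  st <- normoxic_ss()
  # strip every synthesis and degradation channel, keep signaling intact
  net$params[c("vm_rsmad", "kd_smad")] <- 0
  applied <- apply_intervention(net, st, intervention("chx"))
  net2 <- applied$network
  st2 <- applied$state
  st2["TGFb"] <- tgfb_dose_to_concentration(1)
  tr <- simulate_protocol(net2, simulation_protocol(
    tgfb_ng_ml = 1, duration = 1440, times = seq(0, 1440, 60)),
    from_state = st2)
  tot <- species_total(tr, c("SMAD2", "pSMAD2", "SMAD2_n", "pSMAD2_n",
                             "pS2S4_c", "pS2S4_n"))
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
})

test_that("receptor mass is conserved without synthesis and degradation", {
  net <- shipped()
  net$params[c("vm_ri", "vm_rii", "kf72", "k_ligdeg", "kd_s7lrc")] <- 0
  tr <- simulate_protocol(net, simulation_protocol(
    tgfb_ng_ml = 1, duration = 720, times = seq(0, 720, 30)),
    from_state = stats::setNames(
      normoxic_ss(), names(normoxic_ss())))
  # type-II receptor total over every containing species
  tot <- species_total(tr, c("RII_s", "RII_e", "TGFb_RII_s", "LRC_s",
                             "LRC_e", "SMAD7_LRC"))
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
})

test_that("phospho-SMAD2 dose response is monotone and saturating", {
  dr <- psmad2_dose_response(shipped(), c(0, 0.01, 0.1, 0.3, 1, 3, 10, 20))
  expect_equal(dr$normalized[which.max(dr$dose_ng_ml)], 1)
  expect_true(all(diff(dr$psmad2_um) > -1e-12))
  expect_equal(which.min(dr$normalized), 1)
  # saturating: the last doubling of dose gains far less than the first
  gain_lo <- dr$psmad2_um[5] / dr$psmad2_um[4]   # 0.3 -> 1 ng/ml
  gain_hi <- dr$psmad2_um[8] / dr$psmad2_um[7]   # 10 -> 20 ng/ml
  expect_gt(gain_lo, 2 * gain_hi)
  expect_error(psmad2_dose_response(shipped(), numeric()), "empty")
})

test_that("SMAD7 feedback produces the late tail and limits activation", {
  ex <- memo("smad7_exp", smad7_feedback_experiment(shipped(), 1, 2880))
  s <- ex$summary
  # blocking SMAD7 synthesis enlarges the activation AUC
  expect_gt(s$auc_blocked, 1.5 * s$auc_intact)
  # a secondary late rise exists with SMAD7 intact and vanishes when blocked
  expect_gt(s$tail_intact, 1e-6)
  expect_equal(s$tail_blocked, 0)
  # total SMAD4 dips below its initial level, then partially recovers
  expect_lt(s$smad4_min_over_initial, 0.9)
  s4 <- species_total(ex$intact, c("SMAD4", "SMAD4_n", "pS1S4_c", "pS2S4_c",
                                   "pS1S4_n", "pS2S4_n"))
  expect_gt(s4[length(s4)], min(s4))
  # with synthesis blocked SMAD7 never exceeds its initial level
  expect_lte(max(ex$blocked$conc[, "SMAD7"]),
             ex$blocked$conc[1, "SMAD7"] * (1 + 1e-9))
})
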