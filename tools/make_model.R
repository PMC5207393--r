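#!/usr/bin/env Rscript
## Builds the shipped TSP-1 regulation network definition
## (inst/extdata/tsp1_network.yaml). Run from the package root:
##   Rscript tools/make_model.R [--no-ss]
## The definition is a curated reconstruction of the endothelial TSP-1
## regulatory network; initial conditions are replaced by the computed
## normoxic steady state before writing unless --no-ss is given.

suppressMessages(pkgload::load_all(".", quiet = TRUE))

sn <- function(x, nm) stats::setNames(x, nm)

## ---------------------------------------------------------------- parameters
params <- c(
  ## global turnover scales (1/min)
  kd_mrna = 1.2e-3, kd_prot = 1.2e-3, kd_mir = 5e-3, ktl = 2.33,
  ## HIF / oxygen sensing
  vm1 = 1.05e-3, vm2 = 4e-4, kd_hif = 1e-3,
  kf3 = 0.01, kr3 = 0.1, kf5 = 0.1, kr5 = 0.1, kf4 = 0.002, kr4 = 0.2,
  kf6 = 0.01, kr6 = 0.1, kf9 = 0.1, kr9 = 0.1, kf8 = 0.002, kr8 = 0.2,
  kf2 = 2, kr2 = 0.2, kf10 = 0.5, kf11 = 1,
  kf7 = 2, kr7 = 0.2, kf12 = 0.5, kf13 = 1,
  kf14 = 10, kr14 = 0.1, kf15 = 0.5, kf17 = 0.2,
  kf1 = 0.2, kr1 = 0.1, kf16 = 0.2, kr16 = 0.1, kf21 = 0.1, kr21 = 0.1,
  kf19 = 2, kr19 = 0.2, kf20 = 2, kr20 = 0.2,
  kf18 = 3.33e-4, K_ttp = 0.012, A_ttp = 4, kd_ttp = 5e-3,
  k_ttpdeg = 0.2, K_ttpr = 0.15, R_ttpr = 12,
  ## Myc / MXI-1 / PSAP / p53 / Lin28B axis
  vm3 = 6e-8, kd_mrna_myc = 0.02, K_mycr = 4e-4, n_mycr = 1, R_mycr = 1.5,
  ktl_myc = 187, kd_myc = 3e-3, k_mychif = 3, kf22 = 0.12, kr22 = 0.1,
  vm6 = 2.1e-5, K_mxi1 = 3.05e-3, n_mxi1 = 3, A_mxi1 = 16, kf23 = 0.12, kr23 = 0.1,
  vm11 = 9.7e-5, K_psap = 0.1, R_psap = 2, K_mxi = 0.02,
  k_p53tx = 6e-8, vm13 = 2.7, kd_p53 = 8e-3,
  K_p53h = 1.72e-3, n_p53h = 3, R_p53h = 5,
  K_p53p = 0.1, n_p53p = 1, R_p53p = 2,
  vm9 = 1.24e-5, K_l28 = 0.05, n_l28 = 1, A_l28 = 1.5, kf24 = 0.12, kr24 = 0.1,
  ## microRNA biogenesis / targeting
  vm5 = 8.5e-6, K_let7 = 5.55e-3, n_let7 = 3, A_let7 = 30,
  k_drosha = 0.03, K_lin = 0.04, n_lin = 2, R_lin = 4,
  k_xpo = 0.2, k_dicer = 0.02, Km_dicer = 0.5, kd_premir = 1e-3,
  kf25 = 0.012, kr_risc = 1e-3, kd_risc = 1e-3,
  vm18 = 3.5e-7, K_ago = 0.0023, n_ago = 3, R_ago = 6,
  vm19 = 2.3e-7, K_dcr = 0.0019, n_dcr = 3, R_dcr = 6,
  vm7 = 2e-4, K_m18 = 0.0465, n_m18 = 1.7, kf26 = 0.012,
  ## TSP-1 gene, mRNA and protein
  vm20 = 9.6e-9,
  K_t1 = 2.45e-3, n_t1 = 4, A_t1 = 0.8,
  K_t2 = 0.045, n_t2 = 1, R_t2 = 0.35,
  K_t3 = 2.5e-4, n_t3 = 1, A_t3 = 0.3,
  K_t4 = 0.03, n_t4 = 3, A_t4 = 4,
  K_t5 = 0.11, n_t5 = 2, A_t5 = 18,
  k_mexp = 0.5, kf27 = 24, kr27 = 1e-3, k_repdeg = 2e-3,
  ktl_tsp1 = 5.71, kd_tsp1 = 2e-3,
  ## TGF-beta receptors and SMADs
  vm_ri = 4.6e-4, vm_rii = 4.6e-4, kf72 = 0.0278,
  ki_r = 0.033, krec_r = 0.033,
  kf73 = 30, kr73 = 0.01, kf28 = 30, kr28 = 0.01, kf66 = 0.1,
  k_ligdeg = 0.002,
  kf74 = 0.08, k_dps = 0.005, kf75 = 32,
  kf77 = 0.8, kr77 = 1, kf78 = 0.2, kf76 = 0.4,
  kf79 = 8e-4, kr79 = 3.5, K_imp = 0.05, kf80 = 50, kr80 = 1, kf82 = 0.6, k_sexp = 0.1,
  vm_rsmad = 4e-5, kd_smad = 2.5e-4,
  vm36 = 1.75e-4, kd_s4 = 3e-4, vm34 = 0.1,
  vm32 = 2e-6, K_s7i = 6e-4, n_s7i = 3, A_s7i = 330, kd_s7 = 4e-3,
  kf89 = 0.6, kr89 = 2e-4, kd_s7lrc = 4e-4,
  ## calcium / calmodulin / calcineurin / NFATc1
  vm27 = 0.05, K_ca = 2e-5, A_ca = 8, k_caout = 0.5,
  kf30 = 10, kr30 = 10, kf31 = 10, kr31 = 2, kf32 = 20, kr32 = 1,
  vm29 = 1, Km_nfat = 1, k_nfkc = 0.5, k_nfimp = 0.1, k_nfkn = 0.05,
  k_nfexp = 0.1,
  ## therapy species (Kd set at application time; kon fixed)
  kon_myci = 10, koff_myci = 0.01, kon_p53i = 10, koff_p53i = 0.01,
  kon_a18 = 10, koff_a18 = 0.01, kon_al7 = 50, koff_al7 = 0.01,
  kd_cplx = 2.5e-4
)

## ------------------------------------------------------------------- species
sp <- function(name, compartment, init, clamped = FALSE, role = "") {
  data.frame(name = name, compartment = compartment, init = init,
             clamped = clamped, role = role, stringsAsFactors = FALSE)
}
species <- rbind(
  ## clamped environmental / housekeeping pools
  sp("O2", "cytoplasm", 200, TRUE, "dissolved oxygen (21% = 200 uM)"),
  sp("Fe", "cytoplasm", 5, TRUE, "iron cofactor pool"),
  sp("DG", "cytoplasm", 100, TRUE, "2-oxoglutarate pool"),
  sp("Drosha", "nucleus", 1, TRUE, "microprocessor"),
  sp("XPO5", "nucleus", 1, TRUE, "pre-miR exportin"),
  sp("GSK3", "cytoplasm", 1, TRUE, "NFAT kinase (cytoplasm)"),
  sp("GSK3_n", "nucleus", 1, TRUE, "NFAT kinase (nucleus)"),
  sp("PPase_n", "nucleus", 1, TRUE, "nuclear SMAD phosphatase"),
  ## HIF oxygen sensing
  sp("HIF1a", "cytoplasm", 2e-3, role = "HIF-1alpha"),
  sp("HIF1a_n", "nucleus", 4e-3),
  sp("HIF2a", "cytoplasm", 1.2e-3, role = "HIF-2alpha"),
  sp("HIF2a_n", "nucleus", 2.4e-3),
  sp("HIF1b_c", "cytoplasm", 0.05, role = "HIF-1beta"),
  sp("HIF1b_n", "nucleus", 0.12),
  sp("HIF1d_n", "nucleus", 6e-3, role = "HIF-1 dimer (TF)"),
  sp("HIF2d_n", "nucleus", 3e-3, role = "HIF-2 dimer (TF)"),
  sp("FIH", "cytoplasm", 0.2, role = "factor inhibiting HIF"),
  sp("FIH_DG", "cytoplasm", 0),
  sp("FIH_DG_Fe", "cytoplasm", 0),
  sp("FIH_DG_Fe_O2", "cytoplasm", 0),
  sp("PHD", "cytoplasm", 0.25, role = "prolyl hydroxylase"),
  sp("PHD_DG", "cytoplasm", 0),
  sp("PHD_DG_Fe", "cytoplasm", 0),
  sp("PHD_DG_Fe_O2", "cytoplasm", 0),
  sp("HIF1a_FIHc", "cytoplasm", 0),
  sp("HIF1aOH_FIH", "cytoplasm", 0),
  sp("HIF2a_FIHc", "cytoplasm", 0),
  sp("HIF2aOH_FIH", "cytoplasm", 0),
  sp("HIF1a_PHDc", "cytoplasm", 0),
  sp("HIF1aOH_PHD", "cytoplasm", 0),
  sp("HIF2a_PHDc", "cytoplasm", 0),
  sp("HIF2aOH_PHD", "cytoplasm", 0),
  sp("HIF1a_OH", "cytoplasm", 0, role = "hydroxylated HIF-1alpha"),
  sp("HIF2a_OH", "cytoplasm", 0),
  sp("VHL", "cytoplasm", 0.3, role = "von Hippel-Lindau E3 ligase"),
  sp("HIF1aOH_VHL", "cytoplasm", 0),
  sp("TTP", "cytoplasm", 0.08, role = "HIF-destabilizing protein"),
  ## Myc axis
  sp("Myc_mRNA", "cytoplasm", 5e-5),
  sp("Myc", "cytoplasm", 0.08, role = "TSP-1 transcriptional repressor"),
  sp("Myc_n", "nucleus", 0.1),
  sp("MXI1", "cytoplasm", 0.02, role = "Myc antagonist"),
  sp("MXI1_n", "nucleus", 0.024),
  sp("PSAP", "cytoplasm", 0.05, role = "prosaposin"),
  sp("p53_mRNA", "cytoplasm", 5e-5),
  sp("p53", "cytoplasm", 0.05, role = "TSP-1 transcriptional activator"),
  sp("Lin28B", "cytoplasm", 0.03, role = "let-7 processing blocker"),
  sp("Lin28B_n", "nucleus", 0.036),
  ## microRNA biogenesis
  sp("pri_let7", "nucleus", 3e-3, role = "miR precursor"),
  sp("pre_let7_n", "nucleus", 6e-5),
  sp("pre_let7", "cytoplasm", 6e-5),
  sp("let7", "cytoplasm", 1e-4, role = "mature hypoxia-responsive miR"),
  sp("AGO1_mRNA", "cytoplasm", 2.6e-5),
  sp("AGO1", "cytoplasm", 0.05, role = "argonaute 1"),
  sp("let7_RISC", "cytoplasm", 0.01, role = "let-7 silencing complex"),
  sp("pri_mir18", "nucleus", 2.4e-3, role = "miR precursor"),
  sp("pre_mir18_n", "nucleus", 1.2e-4),
  sp("pre_mir18", "cytoplasm", 1.2e-4),
  sp("mir18", "cytoplasm", 1e-4, role = "mature TSP-1-targeting miR"),
  sp("mir18_RISC", "cytoplasm", 8e-3, role = "miR-18a silencing complex"),
  sp("Dicer_mRNA", "cytoplasm", 2.6e-5),
  sp("Dicer", "cytoplasm", 0.05, role = "pre-miR ribonuclease"),
  ## TSP-1
  sp("TSP1_mRNA_n", "nucleus", 1e-7),
  sp("TSP1_mRNA", "cytoplasm", 2.8e-5, role = "free (translatable) mRNA"),
  sp("TSP1_mRNA_rep", "cytoplasm", 4.2e-5, role = "miR-repressed mRNA"),
  sp("TSP1", "cytoplasm", 0.08, role = "thrombospondin-1 protein"),
  ## TGF-beta receptors / SMADs
  sp("TGFb", "extracellular", 0, role = "ligand"),
  sp("RI_s", "extracellular", 0.0166, role = "type-I receptor, surface"),
  sp("RI_e", "endosome", 0.0166, role = "type-I receptor, endosome"),
  sp("RII_s", "extracellular", 0.0166, role = "type-II receptor, surface"),
  sp("RII_e", "endosome", 0.0166, role = "type-II receptor, endosome"),
  sp("TGFb_RII_s", "extracellular", 0, role = "ligand-RII complex"),
  sp("LRC_s", "extracellular", 0, role = "ligand-receptor complex, surface"),
  sp("LRC_e", "endosome", 0, role = "signaling receptor complex"),
  sp("SARA", "endosome", 1, TRUE, "SMAD anchor adaptor"),
  sp("PPase_c", "cytoplasm", 1, TRUE, "cytoplasmic SMAD phosphatase"),
  sp("SMAD1", "cytoplasm", 0.16, role = "R-SMAD (BMP branch)"),
  sp("SMAD2", "cytoplasm", 0.16, role = "R-SMAD (TGF-beta branch)"),
  sp("pSMAD1", "cytoplasm", 0),
  sp("pSMAD2", "cytoplasm", 0),
  sp("SMAD1_n", "nucleus", 0),
  sp("SMAD2_n", "nucleus", 0),
  sp("pSMAD1_n", "nucleus", 0),
  sp("pSMAD2_n", "nucleus", 0),
  sp("SMAD4", "cytoplasm", 0.35, role = "co-SMAD"),
  sp("SMAD4_n", "nucleus", 0.35),
  sp("pS1S4_c", "cytoplasm", 0),
  sp("pS2S4_c", "cytoplasm", 0),
  sp("pS1S4_n", "nucleus", 0, role = "active SMAD1-SMAD4 complex"),
  sp("pS2S4_n", "nucleus", 0, role = "active SMAD2-SMAD4 complex (TF)"),
  sp("SMAD7", "cytoplasm", 5e-3, role = "inhibitory SMAD"),
  sp("SMAD7_LRC", "endosome", 0, role = "SMAD7-sequestered receptor complex"),
  ## calcium / NFAT
  sp("Ca", "cytoplasm", 0.1, role = "cytosolic calcium"),
  sp("CaM", "cytoplasm", 5.9371, role = "calmodulin"),
  sp("CaM_Ca2", "cytoplasm", 0),
  sp("CaM_Ca4", "cytoplasm", 0),
  sp("CaN", "cytoplasm", 0.5, role = "calcineurin (inactive)"),
  sp("CaNa", "cytoplasm", 0, role = "active calcineurin"),
  sp("NFATp_c", "cytoplasm", 0.1, role = "phospho-NFATc1 (inactive)"),
  sp("NFATd_c", "cytoplasm", 0),
  sp("NFATd_n", "nucleus", 0, role = "active nuclear NFATc1 (TF)"),
  sp("NFATp_n", "nucleus", 0),
  ## therapy species
  sp("MycI", "cytoplasm", 0, role = "therapy inhibitor"),
  sp("MycI_Myc", "cytoplasm", 0, role = "inert inhibitor complex"),
  sp("p53I", "cytoplasm", 0, role = "therapy inhibitor"),
  sp("p53I_p53", "cytoplasm", 0, role = "inert inhibitor complex"),
  sp("Ant18", "cytoplasm", 0, role = "therapy inhibitor"),
  sp("Ant18_RISC", "cytoplasm", 0, role = "inert inhibitor complex"),
  sp("AntL7", "cytoplasm", 0, role = "therapy inhibitor"),
  sp("AntL7_RISC", "cytoplasm", 0, role = "inert inhibitor complex")
)

## ----------------------------------------------------------------- reactions
deg <- function(id, spn, k, name = paste("degradation of", spn)) {
  reaction(id, name, "mass_action", reactants = sn(1, spn), kf = k,
           tags = "degradation")
}
bind2 <- function(id, a, b, ab, kf, kr, name = paste(a, "binds", b),
                  tags = character()) {
  reaction(id, name, "mass_action", reactants = sn(c(1, 1), c(a, b)),
           products = sn(1, ab), kf = kf, kr = kr, tags = tags)
}
shuttle <- function(id, from, to, kf, kr, name = paste(from, "shuttling")) {
  reaction(id, name, "mass_action", reactants = sn(1, from),
           products = sn(1, to), kf = kf, kr = kr, tags = "transport")
}
conv <- function(id, from, to, k, name, modifiers = character(),
                 factors = NULL, tags = character(), kind = "mass_action") {
  reaction(id, name, kind, reactants = sn(1, from), products = sn(1, to),
           modifiers = modifiers, kf = k, factors = factors, tags = tags)
}

rxns <- list(
  ## --- HIF / oxygen sensing ------------------------------------------------
  reaction("v1", "HIF-1alpha synthesis (destabilized by TTP)",
           "hill_repression", products = sn(1, "HIF1a"), modifiers = "TTP",
           kf = "vm1",
           factors = list(f_fold_rep("TTP", "K_ttpr", 3, "R_ttpr")),
           tags = "translation"),
  reaction("v2", "HIF-2alpha synthesis", "mass_action", products = sn(1, "HIF2a"),
           kf = "vm2", factors = list(), tags = "translation"),
  deg("v3", "HIF1a", "kd_hif", "basal HIF-1alpha degradation"),
  deg("v4", "HIF2a", "kd_hif", "basal HIF-2alpha degradation"),
  bind2("v5", "FIH", "DG", "FIH_DG", "kf3", "kr3"),
  bind2("v6", "FIH_DG", "Fe", "FIH_DG_Fe", "kf5", "kr5"),
  bind2("v7", "FIH_DG_Fe", "O2", "FIH_DG_Fe_O2", "kf4", "kr4",
        "oxygen binds FIH complex"),
  bind2("v8", "PHD", "DG", "PHD_DG", "kf6", "kr6"),
  bind2("v9", "PHD_DG", "Fe", "PHD_DG_Fe", "kf9", "kr9"),
  bind2("v10", "PHD_DG_Fe", "O2", "PHD_DG_Fe_O2", "kf8", "kr8",
        "oxygen binds PHD complex"),
  bind2("v11", "HIF1a", "FIH_DG_Fe_O2", "HIF1a_FIHc", "kf2", "kr2",
        "HIF-1alpha binds FIH complex"),
  conv("v12", "HIF1a_FIHc", "HIF1aOH_FIH", "kf10", "FIH hydroxylates HIF-1alpha"),
  reaction("v13", "HIF1a-OH-FIH dissociation", "mass_action",
           reactants = sn(1, "HIF1aOH_FIH"),
           products = sn(c(1, 1), c("HIF1a_OH", "FIH_DG_Fe")), kf = "kf11"),
  bind2("v14", "HIF1a", "PHD_DG_Fe_O2", "HIF1a_PHDc", "kf7", "kr7",
        "HIF-1alpha binds PHD complex"),
  conv("v15", "HIF1a_PHDc", "HIF1aOH_PHD", "kf12", "PHD hydroxylates HIF-1alpha"),
  reaction("v16", "HIF1a-OH-PHD dissociation", "mass_action",
           reactants = sn(1, "HIF1aOH_PHD"),
           products = sn(c(1, 1), c("HIF1a_OH", "PHD_DG_Fe")), kf = "kf13"),
  bind2("v17", "HIF2a", "FIH_DG_Fe_O2", "HIF2a_FIHc", "kf2", "kr2",
        "HIF-2alpha binds FIH complex"),
  conv("v18", "HIF2a_FIHc", "HIF2aOH_FIH", "kf10", "FIH hydroxylates HIF-2alpha"),
  reaction("v19", "HIF2a-OH-FIH dissociation", "mass_action",
           reactants = sn(1, "HIF2aOH_FIH"),
           products = sn(c(1, 1), c("HIF2a_OH", "FIH_DG_Fe")), kf = "kf11"),
  bind2("v20", "HIF2a", "PHD_DG_Fe_O2", "HIF2a_PHDc", "kf7", "kr7",
        "HIF-2alpha binds PHD complex"),
  conv("v21", "HIF2a_PHDc", "HIF2aOH_PHD", "kf12", "PHD hydroxylates HIF-2alpha"),
  reaction("v22", "HIF2a-OH-PHD dissociation", "mass_action",
           reactants = sn(1, "HIF2aOH_PHD"),
           products = sn(c(1, 1), c("HIF2a_OH", "PHD_DG_Fe")), kf = "kf13"),
  bind2("v23", "HIF1a_OH", "VHL", "HIF1aOH_VHL", "kf14", "kr14"),
  reaction("v24", "VHL-mediated HIF-1alpha destruction", "mass_action",
           reactants = sn(1, "HIF1aOH_VHL"), products = sn(1, "VHL"),
           kf = "kf15", tags = "degradation"),
  deg("v25", "HIF2a_OH", "kf17", "hydroxylated HIF-2alpha destruction"),
  shuttle("v26", "HIF1a", "HIF1a_n", "kf1", "kr1",
          "HIF-1alpha nuclear translocation"),
  shuttle("v27", "HIF2a", "HIF2a_n", "kf16", "kr16",
          "HIF-2alpha nuclear translocation"),
  shuttle("v28", "HIF1b_c", "HIF1b_n", "kf21", "kr21",
          "HIF-1beta nuclear translocation"),
  bind2("v29", "HIF1a_n", "HIF1b_n", "HIF1d_n", "kf19", "kr19",
        "HIF-1alpha binds HIF-1beta"),
  bind2("v30", "HIF2a_n", "HIF1b_n", "HIF2d_n", "kf20", "kr20",
        "HIF-2alpha binds HIF-1beta"),
  reaction("v31", "TTP synthesis (HIF-1 dimer induced)", "hill_activation",
           products = sn(1, "TTP"), modifiers = "HIF1d_n", kf = "kf18",
           factors = list(f_fold_act("HIF1d_n", "K_ttp", 2, "A_ttp")),
           tags = "translation"),
  deg("v32", "TTP", "kd_ttp"),
  reaction("v33", "TTP-promoted HIF-1alpha degradation", "mass_action",
           reactants = sn(1, "HIF1a"), modifiers = "TTP", kf = "k_ttpdeg",
           factors = list(f_pow("HIF1a"), f_pow("TTP")), tags = "degradation"),
  ## --- Myc / MXI-1 / PSAP / p53 / Lin28B axis ------------------------------
  reaction("v34", "Myc transcription (repressed by TGF-beta signal)",
           "hill_repression", products = sn(1, "Myc_mRNA"),
           modifiers = "pS2S4_n", kf = "vm3",
           factors = list(f_fold_rep("pS2S4_n", "K_mycr", "n_mycr", "R_mycr")),
           tags = "transcription"),
  deg("v35", "Myc_mRNA", "kd_mrna_myc"),
  reaction("v36", "Myc translation", "mass_action", products = sn(1, "Myc"),
           modifiers = "Myc_mRNA", kf = "ktl_myc",
           factors = list(f_pow("Myc_mRNA")), tags = "translation"),
  deg("v37", "Myc", "kd_myc", "basal Myc degradation"),
  reaction("v38", "HIF-promoted Myc degradation", "mass_action",
           reactants = sn(1, "Myc"), modifiers = "HIF1a", kf = "k_mychif",
           factors = list(f_pow("Myc"), f_pow("HIF1a")), tags = "degradation"),
  shuttle("v39", "Myc", "Myc_n", "kf22", "kr22"),
  reaction("v40", "MXI-1 synthesis (HIF-1 dimer induced)", "hill_activation",
           products = sn(1, "MXI1"), modifiers = "HIF1d_n", kf = "vm6",
           factors = list(f_fold_act("HIF1d_n", "K_mxi1", "n_mxi1", "A_mxi1")),
           tags = "translation"),
  deg("v41", "MXI1", "kd_prot"),
  shuttle("v42", "MXI1", "MXI1_n", "kf23", "kr23"),
  reaction("v43", "PSAP synthesis (Myc repressed)", "hill_repression",
           products = sn(1, "PSAP"), modifiers = c("Myc_n", "MXI1_n"),
           kf = "vm11",
           factors = list(f_ratio_fold_rep("Myc_n", "MXI1_n", "K_psap",
                                           1, "R_psap", "K_mxi")),
           tags = "translation"),
  deg("v44", "PSAP", "kd_prot"),
  reaction("v45", "p53 transcription", "mass_action",
           products = sn(1, "p53_mRNA"), kf = "k_p53tx", factors = list(),
           tags = "transcription"),
  deg("v46", "p53_mRNA", "kd_mrna"),
  reaction("v47", "p53 translation", "mass_action", products = sn(1, "p53"),
           modifiers = "p53_mRNA", kf = "vm13",
           factors = list(f_pow("p53_mRNA")), tags = "translation"),
  reaction("v48", "p53 degradation (repressed by HIF-1alpha and PSAP)",
           "rule_based", reactants = sn(1, "p53"),
           modifiers = c("HIF1a", "PSAP"), kf = "kd_p53",
           factors = list(f_pow("p53"),
                          f_fold_rep("HIF1a", "K_p53h", "n_p53h", "R_p53h"),
                          f_fold_rep("PSAP", "K_p53p", "n_p53p", "R_p53p")),
           tags = "degradation"),
  reaction("v49", "Lin28B synthesis (Myc induced)", "hill_activation",
           products = sn(1, "Lin28B"), modifiers = c("Myc_n", "MXI1_n"),
           kf = "vm9",
           factors = list(f_ratio_fold_act("Myc_n", "MXI1_n", "K_l28",
                                           "n_l28", "A_l28", "K_mxi")),
           tags = "translation"),
  deg("v50", "Lin28B", "kd_prot"),
  shuttle("v51", "Lin28B", "Lin28B_n", "kf24", "kr24"),
  ## --- microRNA biogenesis -------------------------------------------------
  reaction("v52", "pri-let-7 transcription (HIF-1 dimer induced)",
           "hill_activation", products = sn(1, "pri_let7"),
           modifiers = "HIF1d_n", kf = "vm5",
           factors = list(f_fold_act("HIF1d_n", "K_let7", "n_let7", "A_let7")),
           tags = "transcription"),
  reaction("v53", "pri-let-7 processing (blocked by Lin28B)", "rule_based",
           reactants = sn(1, "pri_let7"), products = sn(1, "pre_let7_n"),
           modifiers = c("Drosha", "Lin28B_n"), kf = "k_drosha",
           factors = list(f_pow("pri_let7"), f_pow("Drosha"),
                          f_fold_rep("Lin28B_n", "K_lin", "n_lin", "R_lin"))),
  conv("v54", "pre_let7_n", "pre_let7", "k_xpo", "pre-let-7 nuclear export",
       modifiers = "XPO5",
       factors = list(f_pow("pre_let7_n"), f_pow("XPO5")), tags = "transport"),
  reaction("v55", "Dicer cleaves pre-let-7", "michaelis_menten",
           reactants = sn(1, "pre_let7"), products = sn(1, "let7"),
           modifiers = "Dicer", kf = "k_dicer",
           factors = list(f_pow("Dicer"), f_sat("pre_let7", "Km_dicer"))),
  deg("v56", "pre_let7", "kd_premir"),
  deg("v57", "let7", "kd_mir"),
  bind2("v58", "let7", "AGO1", "let7_RISC", "kf25", "kr_risc",
        "let-7 loads onto AGO1"),
  deg("v59", "let7_RISC", "kd_risc"),
  reaction("v60", "AGO1 transcription (let-7 repressed)", "hill_repression",
           products = sn(1, "AGO1_mRNA"), modifiers = "let7_RISC", kf = "vm18",
           factors = list(f_fold_rep("let7_RISC", "K_ago", "n_ago", "R_ago")),
           tags = "transcription"),
  deg("v61", "AGO1_mRNA", "kd_mrna"),
  reaction("v62", "AGO1 translation", "mass_action", products = sn(1, "AGO1"),
           modifiers = "AGO1_mRNA", kf = "ktl",
           factors = list(f_pow("AGO1_mRNA")), tags = "translation"),
  deg("v63", "AGO1", "kd_prot"),
  reaction("v64", "Dicer transcription (let-7 repressed)", "hill_repression",
           products = sn(1, "Dicer_mRNA"), modifiers = "let7_RISC",
           kf = "vm19",
           factors = list(f_fold_rep("let7_RISC", "K_dcr", "n_dcr", "R_dcr")),
           tags = "transcription"),
  deg("v65", "Dicer_mRNA", "kd_mrna"),
  reaction("v66", "Dicer translation", "mass_action", products = sn(1, "Dicer"),
           modifiers = "Dicer_mRNA", kf = "ktl",
           factors = list(f_pow("Dicer_mRNA")), tags = "translation"),
  deg("v67", "Dicer", "kd_prot"),
  reaction("v68", "pri-miR-18a transcription (Myc driven)", "hill_activation",
           products = sn(1, "pri_mir18"), modifiers = c("Myc_n", "MXI1_n"),
           kf = "vm7",
           factors = list(f_ratio_hill_act("Myc_n", "MXI1_n", "K_m18",
                                           "n_m18", "K_mxi")),
           tags = "transcription"),
  reaction("v69", "pri-miR-18a processing", "mass_action",
           reactants = sn(1, "pri_mir18"), products = sn(1, "pre_mir18_n"),
           modifiers = "Drosha", kf = "k_drosha",
           factors = list(f_pow("pri_mir18"), f_pow("Drosha"))),
  conv("v70", "pre_mir18_n", "pre_mir18", "k_xpo", "pre-miR-18a nuclear export",
       modifiers = "XPO5",
       factors = list(f_pow("pre_mir18_n"), f_pow("XPO5")), tags = "transport"),
  reaction("v71", "Dicer cleaves pre-miR-18a", "michaelis_menten",
           reactants = sn(1, "pre_mir18"), products = sn(1, "mir18"),
           modifiers = "Dicer", kf = "k_dicer",
           factors = list(f_pow("Dicer"), f_sat("pre_mir18", "Km_dicer"))),
  deg("v72", "pre_mir18", "kd_premir"),
  deg("v73", "mir18", "kd_mir"),
  bind2("v74", "mir18", "AGO1", "mir18_RISC", "kf26", "kr_risc",
        "miR-18a loads onto AGO1"),
  deg("v75", "mir18_RISC", "kd_risc"),
  ## --- TSP-1 gene ----------------------------------------------------------
  reaction("v76", "TSP-1 transcription (multiplicative TF integration)",
           "rule_based", products = sn(1, "TSP1_mRNA_n"),
           modifiers = c("HIF2d_n", "Myc_n", "MXI1_n", "pS2S4_n", "NFATd_n",
                         "p53"),
           kf = "vm20",
           factors = list(
             f_fold_act("HIF2d_n", "K_t1", "n_t1", "A_t1"),
             f_ratio_fold_rep("Myc_n", "MXI1_n", "K_t2", "n_t2", "R_t2",
                              "K_mxi"),
             f_fold_act("pS2S4_n", "K_t3", "n_t3", "A_t3"),
             f_fold_act("NFATd_n", "K_t4", "n_t4", "A_t4"),
             f_fold_act("p53", "K_t5", "n_t5", "A_t5")),
           tags = "transcription"),
  conv("v77", "TSP1_mRNA_n", "TSP1_mRNA", "k_mexp", "TSP-1 mRNA export",
       tags = "transport"),
  deg("v78", "TSP1_mRNA", "kd_mrna"),
  reaction("v79", "cooperative miR-18a RISC repression of TSP-1 mRNA",
           "mass_action",
           reactants = sn(c(1, 2), c("TSP1_mRNA", "mir18_RISC")),
           products = sn(1, "TSP1_mRNA_rep"), kf = "kf27", kr = "kr27"),
  reaction("v80", "decay of repressed TSP-1 mRNA (RISCs recycled)",
           "mass_action", reactants = sn(1, "TSP1_mRNA_rep"),
           products = sn(2, "mir18_RISC"), kf = "k_repdeg",
           tags = "degradation"),
  reaction("v81", "TSP-1 translation", "mass_action", products = sn(1, "TSP1"),
           modifiers = "TSP1_mRNA", kf = "ktl_tsp1",
           factors = list(f_pow("TSP1_mRNA")), tags = "translation"),
  deg("v82", "TSP1", "kd_tsp1"),
  ## --- TGF-beta receptors and SMADs ---------------------------------------
  reaction("v83", "type-I receptor synthesis", "mass_action",
           products = sn(1, "RI_s"), kf = "vm_ri", factors = list(),
           tags = "translation"),
  deg("v84", "RI_s", "kf72", "constitutive type-I receptor degradation"),
  shuttle("v85", "RI_s", "RI_e", "ki_r", "krec_r",
          "type-I receptor internalization/recycling"),
  reaction("v86", "type-II receptor synthesis", "mass_action",
           products = sn(1, "RII_s"), kf = "vm_rii", factors = list(),
           tags = "translation"),
  deg("v87", "RII_s", "kf72", "constitutive type-II receptor degradation"),
  shuttle("v88", "RII_s", "RII_e", "ki_r", "krec_r",
          "type-II receptor internalization/recycling"),
  bind2("v89", "TGFb", "RII_s", "TGFb_RII_s", "kf73", "kr73",
        "TGF-beta binds its receptor"),
  bind2("v90", "TGFb_RII_s", "RI_s", "LRC_s", "kf28", "kr28",
        "receptor complex assembly"),
  conv("v91", "LRC_s", "LRC_e", "kf66", "receptor complex internalization",
       tags = "transport"),
  reaction("v92", "endosomal ligand degradation (receptors recycle)",
           "mass_action", reactants = sn(1, "LRC_e"),
           products = sn(c(1, 1), c("RI_e", "RII_e")), kf = "k_ligdeg",
           tags = "degradation"),
  reaction("v93", "receptor-mediated SMAD1 phosphorylation",
           "michaelis_menten", reactants = sn(1, "SMAD1"),
           products = sn(1, "pSMAD1"), modifiers = c("LRC_e", "SARA"),
           kf = "kf75",
           factors = list(f_pow("LRC_e"), f_pow("SARA"),
                          f_sat("SMAD1", "kf74"))),
  reaction("v94", "receptor-mediated SMAD2 phosphorylation",
           "michaelis_menten", reactants = sn(1, "SMAD2"),
           products = sn(1, "pSMAD2"), modifiers = c("LRC_e", "SARA"),
           kf = "kf75",
           factors = list(f_pow("LRC_e"), f_pow("SARA"),
                          f_sat("SMAD2", "kf74"))),
  reaction("v95", "cytoplasmic dephosphorylation of pSMAD1", "mass_action",
           reactants = sn(1, "pSMAD1"), products = sn(1, "SMAD1"),
           modifiers = "PPase_c", kf = "k_dps",
           factors = list(f_pow("pSMAD1"), f_pow("PPase_c"))),
  reaction("v96", "cytoplasmic dephosphorylation of pSMAD2", "mass_action",
           reactants = sn(1, "pSMAD2"), products = sn(1, "SMAD2"),
           modifiers = "PPase_c", kf = "k_dps",
           factors = list(f_pow("pSMAD2"), f_pow("PPase_c"))),
  bind2("v97", "pSMAD1", "SMAD4", "pS1S4_c", "kf77", "kr77",
        "pSMAD1 binds SMAD4"),
  bind2("v98", "pSMAD2", "SMAD4", "pS2S4_c", "kf77", "kr77",
        "pSMAD2 binds SMAD4"),
  conv("v99", "pS1S4_c", "pS1S4_n", "kf78",
       "pSMAD1-SMAD4 nuclear translocation", tags = "transport"),
  conv("v100", "pS2S4_c", "pS2S4_n", "kf78",
       "pSMAD2-SMAD4 nuclear translocation", tags = "transport"),
  conv("v101", "pSMAD1", "pSMAD1_n", "kf76",
       "pSMAD1 nuclear translocation", tags = "transport"),
  conv("v102", "pSMAD2", "pSMAD2_n", "kf76",
       "pSMAD2 nuclear translocation", tags = "transport"),
  reaction("v103", "carrier-mediated SMAD4 nuclear import/export",
           "michaelis_menten", reactants = sn(1, "SMAD4"),
           products = sn(1, "SMAD4_n"), kf = "kf79", kr = "kr79",
           factors = list(f_sat("SMAD4", "K_imp")), tags = "transport"),
  bind2("v104", "pSMAD1_n", "SMAD4_n", "pS1S4_n", "kf80", "kr80",
        "nuclear pSMAD1 binds SMAD4"),
  bind2("v105", "pSMAD2_n", "SMAD4_n", "pS2S4_n", "kf80", "kr80",
        "nuclear pSMAD2 binds SMAD4"),
  reaction("v106", "nuclear dephosphorylation of SMAD1 complex",
           "mass_action", reactants = sn(1, "pS1S4_n"),
           products = sn(c(1, 1), c("SMAD1_n", "SMAD4_n")),
           modifiers = "PPase_n", kf = "kf82",
           factors = list(f_pow("pS1S4_n"), f_pow("PPase_n"))),
  reaction("v107", "nuclear dephosphorylation of SMAD2 complex",
           "mass_action", reactants = sn(1, "pS2S4_n"),
           products = sn(c(1, 1), c("SMAD2_n", "SMAD4_n")),
           modifiers = "PPase_n", kf = "kf82",
           factors = list(f_pow("pS2S4_n"), f_pow("PPase_n"))),
  conv("v108", "SMAD1_n", "SMAD1", "k_sexp", "SMAD1 nuclear export",
       tags = "transport"),
  conv("v109", "SMAD2_n", "SMAD2", "k_sexp", "SMAD2 nuclear export",
       tags = "transport"),
  reaction("v110", "SMAD1 synthesis", "mass_action", products = sn(1, "SMAD1"),
           kf = "vm_rsmad", factors = list(), tags = "translation"),
  deg("v111", "SMAD1", "kd_smad"),
  reaction("v112", "SMAD2 synthesis", "mass_action", products = sn(1, "SMAD2"),
           kf = "vm_rsmad", factors = list(), tags = "translation"),
  deg("v113", "SMAD2", "kd_smad"),
  reaction("v114", "SMAD4 synthesis", "mass_action", products = sn(1, "SMAD4"),
           kf = "vm36", factors = list(), tags = "translation"),
  deg("v115", "SMAD4", "kd_s4", "basal SMAD4 degradation"),
  reaction("v116", "SMAD7-promoted SMAD4 degradation", "mass_action",
           reactants = sn(1, "SMAD4"), modifiers = "SMAD7", kf = "vm34",
           factors = list(f_pow("SMAD4"), f_pow("SMAD7")),
           tags = "degradation"),
  reaction("v117", "SMAD7 synthesis (TGF-beta induced)", "hill_activation",
           products = sn(1, "SMAD7"), modifiers = "pS2S4_n", kf = "vm32",
           factors = list(f_fold_act("pS2S4_n", "K_s7i", "n_s7i", "A_s7i")),
           tags = "translation"),
  deg("v118", "SMAD7", "kd_s7"),
  bind2("v119", "SMAD7", "LRC_e", "SMAD7_LRC", "kf89", "kr89",
        "SMAD7 sequesters the activated receptor complex"),
  reaction("v120",
           "sequestered-complex turnover (SMAD7 degraded, receptor freed)",
           "mass_action", reactants = sn(1, "SMAD7_LRC"),
           products = sn(1, "LRC_e"), kf = "kd_s7lrc",
           tags = "degradation"),
  ## --- calcium / NFAT ------------------------------------------------------
  reaction("v121", "calcium influx (TGF-beta activated)", "rule_based",
           products = sn(1, "Ca"), modifiers = "LRC_e", kf = "vm27",
           factors = list(f_fold_act("LRC_e", "K_ca", 2, "A_ca"))),
  reaction("v122", "calcium outflux (pump)", "rule_based",
           reactants = sn(1, "Ca"), kf = "k_caout"),
  reaction("v123", "calmodulin binds two calcium ions", "mass_action",
           reactants = sn(c(2, 1), c("Ca", "CaM")),
           products = sn(1, "CaM_Ca2"), kf = "kf30", kr = "kr30"),
  reaction("v124", "calmodulin binds two further calcium ions", "mass_action",
           reactants = sn(c(2, 1), c("Ca", "CaM_Ca2")),
           products = sn(1, "CaM_Ca4"), kf = "kf31", kr = "kr31"),
  bind2("v125", "CaM_Ca4", "CaN", "CaNa", "kf32", "kr32",
        "calmodulin activates calcineurin"),
  reaction("v126", "calcineurin dephosphorylates NFATc1", "michaelis_menten",
           reactants = sn(1, "NFATp_c"), products = sn(1, "NFATd_c"),
           modifiers = "CaNa", kf = "vm29",
           factors = list(f_pow("CaNa"), f_sat("NFATp_c", "Km_nfat"))),
  reaction("v127", "cytoplasmic NFATc1 rephosphorylation", "mass_action",
           reactants = sn(1, "NFATd_c"), products = sn(1, "NFATp_c"),
           modifiers = "GSK3", kf = "k_nfkc",
           factors = list(f_pow("NFATd_c"), f_pow("GSK3"))),
  conv("v128", "NFATd_c", "NFATd_n", "k_nfimp",
       "active NFATc1 nuclear import", tags = "transport"),
  reaction("v129", "nuclear NFATc1 rephosphorylation", "mass_action",
           reactants = sn(1, "NFATd_n"), products = sn(1, "NFATp_n"),
           modifiers = "GSK3_n", kf = "k_nfkn",
           factors = list(f_pow("NFATd_n"), f_pow("GSK3_n"))),
  conv("v130", "NFATp_n", "NFATp_c", "k_nfexp",
       "phospho-NFATc1 nuclear export", tags = "transport"),
  ## --- therapy species -----------------------------------------------------
  bind2("v131", "Myc", "MycI", "MycI_Myc", "kon_myci", "koff_myci",
        "Myc inhibitor sequesters cytoplasmic Myc", tags = "inhibitor_binding"),
  reaction("v132", "degradation of inhibitor-bound Myc", "mass_action",
           reactants = sn(1, "MycI_Myc"), products = sn(1, "MycI"),
           kf = "kd_cplx", tags = "degradation"),
  bind2("v133", "p53", "p53I", "p53I_p53", "kon_p53i", "koff_p53i",
        "p53 inhibitor sequesters cytoplasmic p53", tags = "inhibitor_binding"),
  reaction("v134", "degradation of inhibitor-bound p53", "mass_action",
           reactants = sn(1, "p53I_p53"), products = sn(1, "p53I"),
           kf = "kd_cplx", tags = "degradation"),
  bind2("v135", "mir18_RISC", "Ant18", "Ant18_RISC", "kon_a18", "koff_a18",
        "miR-18a antagonist sequesters the miR-18a RISC",
        tags = "inhibitor_binding"),
  reaction("v136", "decay of the antagonized miR-18a RISC (AGO1 recycled)",
           "mass_action", reactants = sn(1, "Ant18_RISC"),
           products = sn(1, "AGO1"), kf = "kd_cplx", tags = "degradation"),
  bind2("v137", "let7_RISC", "AntL7", "AntL7_RISC", "kon_al7", "koff_al7",
        "let-7 antagonist sequesters the let-7 RISC",
        tags = "inhibitor_binding"),
  reaction("v138", "decay of the antagonized let-7 RISC (AGO1 recycled)",
           "mass_action", reactants = sn(1, "AntL7_RISC"),
           products = sn(1, "AGO1"), kf = "kd_cplx", tags = "degradation")
)

net <- build_network(species, rxns, params,
                     provenance = list(
  source = "curated reconstruction of an endothelial TSP-1 regulation network",
  version = "1.0",
  notes = paste("Initial conditions are the computed normoxic (21% O2,",
                "no TGF-beta) steady state. Parameters are calibrated so the",
                "documented endothelial-cell behaviors (hypoxic induction of",
                "TSP-1, miR-18a de-repression, SMAD7 feedback dynamics,",
                "NFAT activation) emerge; see the package vignette.")))

cnt <- network_counts(net)
cat(sprintf("species=%d reactions=%d parameters=%d\n",
            cnt["species"], cnt["reactions"], cnt["parameters"]))
stopifnot(cnt["species"] == 109L, cnt["reactions"] == 138L,
          cnt["parameters"] == 195L)

args <- commandArgs(trailingOnly = TRUE)
if (!"--no-ss" %in% args) {
  cat("solving normoxic steady state ...\n")
  ss <- find_steady_state(net, 21, 0, cache = FALSE)
  net <- set_network(net, init = ss)
  keysp <- c("HIF1a", "HIF2a", "HIF1d_n", "HIF2d_n", "TTP", "Myc", "Myc_n",
             "MXI1", "PSAP", "p53", "Lin28B", "let7", "let7_RISC", "mir18",
             "mir18_RISC", "AGO1", "Dicer", "TSP1_mRNA", "TSP1_mRNA_rep",
             "TSP1", "SMAD2", "SMAD4", "SMAD7", "Ca", "CaNa", "NFATd_n",
             "NFATp_c")
  print(signif(ss[keysp], 4))
  cat(sprintf("repressed/free mRNA ratio: %.3f\n",
              ss["TSP1_mRNA_rep"] / ss["TSP1_mRNA"]))
}
write_network_definition(net, "inst/extdata/tsp1_network.yaml")
cat("wrote inst/extdata/tsp1_network.yaml (",
    file.size("inst/extdata/tsp1_network.yaml"), "bytes )\n")
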