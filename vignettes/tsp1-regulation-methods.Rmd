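---
title: "Modeling transcriptional and post-transcriptional TSP-1 regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling transcriptional and post-transcriptional TSP-1 regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological problem

Thrombospondin-1 (TSP-1) is a matricellular protein and one of the strongest
endogenous inhibitors of angiogenesis. Endothelial cells raise TSP-1
production under two stresses that matter in ischemic vascular disease and
in tumors: low oxygen and TGF-beta stimulation. The regulation is layered —
transcription responds to a panel of transcription factors (HIF-2 dimer,
Myc/MXI-1, phospho-SMAD2-SMAD4, NFATc1, p53) while the translatable mRNA
pool is additionally controlled by microRNA silencing (miR-18a as the
representative TSP-1-targeting miR). `tsp1net` ships a deterministic,
compartmental ODE model of this network for endothelial cells, together
with the simulation protocols, sensitivity analysis and calibration tooling
needed to interrogate it.

## Model structure

The shipped network (`tsp1_network()`) has 109 species, 138 reactions and
195 kinetic parameters across four 1-pL compartments (cytoplasm, nucleus,
endosome, extracellular/surface). Units are uM and minutes throughout;
per-cell copy numbers convert at `N / (V * N_A)` with V = 1 pL. The model
definition is a YAML document (`inst/extdata/tsp1_network.yaml`) that
round-trips losslessly through `load_network_definition()` /
`write_network_definition()`, and can be exported to SBML Level 3 with
`export_sbml()`.

The definition is a curated reconstruction: the mechanistic wiring and the
anchor constants (the TGF-beta receptor constitutive degradation rate
0.0278 per minute, total calmodulin 5.9371 uM, mRNA decay 1.2e-3 per
minute, miR pools of 1e3 to 1e4 copies per cell, protein pools of 1e4 to
1e6 copies per cell, 1 ng/ml TGF-beta = 4e-5 uM, 21 percent O2 treated as
in vitro normoxia) are taken from the published endothelial literature; the
remaining rate constants were calibrated once so that the documented
cell-biological behaviors emerge (see "Calibration targets" below) and are
not revisited.

Five modules:

* **Oxygen sensing.** FIH and PHD hydroxylases assemble with 2-oxoglutarate,
  iron and dissolved O2; the oxygen-loaded complexes bind HIF-1alpha and
  HIF-2alpha, and the hydroxylated products are destroyed (VHL-mediated for
  HIF-1alpha). Dissolved O2 is a clamped species (an environmental input,
  not a consumed pool), linear in percent O2 with 21 percent = 200 uM;
  hypoxia is a step change at t = 0 with no gas-equilibration lag. Nuclear
  HIF dimers with HIF-1beta act as transcription factors. A HIF-1-dimer-
  induced destabilizing protein (TTP) closes a negative feedback by
  destabilizing HIF-1alpha synthesis and promoting its decay; this is what
  makes faster dimerization raise the HIF-1 dimer while lowering total
  HIF-1alpha.
* **Myc/MXI-1/PSAP/p53 axis.** HIF-1alpha promotes Myc degradation and the
  HIF-1 dimer induces MXI-1, which damps the effective Myc activity
  (`Myc_eff = Myc_n / (1 + MXI1_n / K_mxi)`) uniformly on all Myc target
  genes. Myc represses prosaposin (PSAP); PSAP and HIF-1alpha both repress
  p53 degradation, so hypoxia stabilizes p53 through two routes. TGF-beta
  signaling (nuclear pSMAD2-SMAD4) represses Myc transcription.
* **microRNA biogenesis.** let-7 (HIF-1-induced, Lin28B-blocked processing)
  and miR-18a (Myc-driven) run the full pri -> pre -> mature -> RISC
  pipeline with Drosha, exportin, Dicer (Michaelis-Menten) and AGO1
  loading. let-7 RISC represses AGO1 and Dicer transcription, so hypoxia
  collapses global miR biogenesis capacity; this gate is what keeps
  hyperactive Myc from rebuilding the miR-18a RISC under hypoxia. TSP-1
  mRNA silencing is cooperative (two miR-18a RISC per mRNA, reflecting
  multiple seed sites); the repressed complex is translationally silent,
  may dissociate, and recycles its RISCs when the mRNA decays.
* **TGF-beta/SMAD.** Ligand binds type-II receptors, assembles with type-I
  receptors, internalizes, and the endosomal complex phosphorylates SMAD1
  and SMAD2 (Michaelis-Menten with a SARA-type adaptor; the half-saturation
  constant is the R-SMAD/receptor association constant). Phospho-R-SMADs
  bind SMAD4 in either compartment; SMAD4 nuclear import is
  carrier-mediated (saturable), which makes the import rate — not the
  cytoplasmic SMAD4 supply — the bottleneck for nuclear complex formation.
  SMAD7 is sharply induced by the nuclear signal, sequesters the active
  receptor complex into a depot whose slow turnover degrades SMAD7 and
  re-releases receptors (producing the characteristic late "tail" of
  activation), and promotes SMAD4 degradation (the transient SMAD4 dip
  with slow restoration). Cycloheximide is simulated by zeroing every
  translation-tagged synthesis rate, which removes SMAD7 induction and
  prolongs the phospho-SMAD plateaus.
* **Calcium/NFAT.** The ligand-bound signaling receptor complex drives
  calcium influx through a saturating rule; a first-order pump restores the
  0.1 uM baseline. Calcium loads calmodulin in two 2-ion steps, Ca4-CaM
  activates calcineurin, and active calcineurin dephosphorylates NFATc1
  (Michaelis-Menten), which shuttles into the nucleus, is re-phosphorylated
  and exported. The four NFATc1 pools carry no synthesis or degradation, so
  total NFATc1 is exactly conserved. The VIVIT-class inhibitor is a
  fractional reduction (x 0.3 for the standard dose) of the
  dephosphorylation rate.

TSP-1 transcription multiplies five fold-terms — Hill activation by the
HIF-2 dimer, nuclear pSMAD2-SMAD4, nuclear active NFATc1 and p53, and a
weak Hill repression by MXI-1-damped Myc — on top of a basal rate sized so
the normoxic steady state sustains the reference mRNA level (2.8e-5 uM).
The five terms saturate independently (the independent-saturation choice is
ours; nothing in the biology fixes a shared ceiling).

## Conventions and assumptions

* Only cytoplasmic proteins/miRs (plus surface receptors, which turn over
  constitutively, and endosomal receptor cargo, which is degraded
  lysosomally) carry degradation reactions; nuclear pools exchange but do
  not decay.
* SMAD phosphorylation happens only in the cytoplasm/endosome; nuclear
  dephosphorylation is fast on the transient SMAD4-bound complex and slow
  elsewhere.
* Degradation is encoded as explicit sink reactions, never as a per-species
  decay attribute, so cycloheximide and knockdowns can target synthesis
  without touching decay.
* TGF-beta is a depletable free ligand; signal shutdown combines ligand
  destruction in the endosome with SMAD7 sequestration.
* Therapy semantics: inhibitors/antagonists bind their target (cytoplasmic
  Myc, p53, the let-7 RISC or the miR-18a RISC) reversibly at the stated Kd
  (default 1 nM) into an inert complex; small-molecule inhibitors recycle
  when the captured protein is degraded, miR antagonist complexes decay
  whole. miR mimics bump the corresponding precursor pool's initial
  condition; all interventions step on at t = 0 after normoxic
  pre-equilibration, with no pharmacokinetics.
* Every protocol starts from the normoxic (21 percent O2, no TGF-beta)
  steady state, which is also stored as the definition's initial
  conditions.

## Calibration targets

The parameter set was tuned once, against the behaviors the endothelial
literature reports, and then frozen:

* directions of the hypoxic (2 percent O2) panel: HIF-1alpha/2alpha, p53,
  MXI-1, PSAP, let-7 and TSP-1 up; AGO1, Dicer, Myc and miR-18a down;
* the repressed:free TSP-1 mRNA ratio collapsing by more than tenfold at
  2 percent O2 over 48 h;
* a TSP-1 oxygen dose response (24 h and 48 h) that is monotone in O2 with
  half-maximal induction between 6 and 8 percent;
* phospho-SMAD2 dose response saturating over 0.01-20 ng/ml; cycloheximide
  prolonging the phospho-SMAD plateaus; the SMAD7 tail/AUC phenotypes; the
  SMAD4 dip;
* Myc hyperactivity (x 5 synthesis) suppressing TSP-1 strongly in normoxia
  and weakly in hypoxia, with knockdown to 10 percent of the hyperactive
  rate restoring TSP-1 about fivefold (normoxia) versus about 1.5-fold
  (hypoxia) at 48 h, measured against the hyperactive arm under the same
  oxygen condition;
* miR-18a and let-7 antagonist efficacy plateauing near 40 nM;
* the combined-ischemia condition (2 percent O2 + 2.5 ng/ml TGF-beta)
  exceeding both single stimuli, p53 inhibition beating single NFAT
  inhibition, and the p53+NFAT combination driving TSP-1 to (just below)
  the normoxic baseline at 24 h;
* the global-sensitivity sign structure: R-SMAD phosphorylation (kf75) and
  SMAD4 shuttling (kf79) the top positive controls of the nuclear
  pSMAD2-SMAD4 exposure; oxygen-hydroxylase binding (kf4, kf8) negative
  controls of the HIF-1 dimer exposure.

These are exactly the quantities the test suite and
`scripts/acceptance.R` recompute; the vignette makes no claim the code does
not verify.

## Numerical choices

* **Integration.** Stiff `deSolve::lsoda` through a compiled right-hand
  side (the reaction network is staged into the package's native code, so
  the integrator never crosses back into R). Default tolerances rtol = 1e-8
  and atol = 1e-12 uM; halving both changes the reported readouts by well
  under 0.1 percent, which the suite asserts. Sub-picomolar negative
  excursions (below 1e-9 uM) are floored to zero in trajectory output, and
  rate-law factors treat negative inputs as zero, so fractional Hill powers
  are always defined.
* **Steady states.** Staged long-time integration (2e4 up to 2e6 minutes)
  interleaved with a Tikhonov-damped Newton polish. The network carries
  many exact conservation laws (NFATc1, calmodulin, calcineurin, HIF-1beta,
  hydroxylase and receptor totals), so the Jacobian is singular along those
  directions; the damped pseudoinverse step moves only within the reactive
  subspace, and species resting at an exact zero equilibrium are pinned.
  Convergence is declared at `max |dx_i/dt| / max(|x_i|, 1e-9) < 1e-8` per
  minute.
* **Sensitivity analysis.** Latin hypercube over two orders of magnitude
  per parameter (x/10 to 10x), log-uniform by default (decades weighted
  equally, the standard choice for rate constants; a uniform marginal is a
  switch). PRCC by explicit rank residualization; significance from the
  t statistic with n - 2 - (p - 1) degrees of freedom. The steady state is
  re-solved per sampled vector; failed integrations are excluded and
  counted, with more than 10 percent failures aborting the experiment. The
  scenario designs sample the module-relevant parameter subsets; design
  size 1000 reproduces the reference design, and the packaged checks run at
  n = 100 where only sign/rank structure is asserted.
* **Calibration.** Residuals are formed on normalized scales (peak or
  baseline, matching how time-course blots are quantified), and the bounded
  Levenberg-Marquardt fit works in log10-parameter space. Pure synthesis
  rates are scale parameters and therefore not identifiable from a single
  normalized curve; recovery experiments accordingly target kinetic
  (shape-controlling) parameters. Integration failures during a fit return
  a large finite penalty instead of an exception.

## The synthetic-data generator

`generate_synthetic_dataset()` simulates a stated condition, samples a
species at stated times, applies multiplicative log-normal noise with the
requested coefficient of variation (seeded, mean-one), normalizes, and tags
the result `source = "synthetic"`. It emulates normalized densitometry of
time-course immunoblots: multiplicative noise, a handful of time points,
and loss of absolute scale. It does not emulate blot saturation,
between-experiment batch effects, correlated errors within a lane, or
biological replicate variance — so passing recovery tests demonstrate that
the estimation machinery works, not that real blot data of this size would
constrain the full model.

## Known limitations

* The parameterization is a calibrated reconstruction; absolute
  concentrations and rates are order-of-magnitude estimates anchored to the
  cited reference values, and conclusions should be read at the level of
  directions, ratios and ranked sensitivities.
* Signaling downstream of secreted TSP-1 (CD36/CD47/VEGFR2), the VEGF
  pathway, calcium input into SMAD activation, and direct calcium-TSP-1
  binding are out of scope by design.
* The capture rate of TGF-beta by its receptor (kf73) is close to
  AUC-neutral in this structure (total ligand is conserved through the
  sequential pathway), so its reported weak negative correlation with
  R-SMAD activation is not reproduced; the sign structure asserted by the
  tests is the one the model genuinely exhibits.
* Deterministic ODEs describe mean behavior; no stochastic transcription,
  no spatial oxygen gradients, no pharmacokinetics, no multi-cell coupling.
* miR-18a stands in for all confirmed TSP-1-targeting miRs; there is no
  strand selection, isomiR handling or target-site multiplicity beyond the
  two-site cooperativity of TSP-1 silencing.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run 24-48 h protocols on a
481-point output grid, dose scans of about a dozen doses with bisection
refinement, PRCC scenarios at n = 100, and five-parameter recovery fits
against four-to-five-point synthetic time courses. These sizes were chosen
so a complete check runs comfortably on a laptop; the same functions scale
to the full n = 1000 sensitivity design unchanged.
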