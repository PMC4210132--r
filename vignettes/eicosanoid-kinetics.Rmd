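---
title: "Kinetic modelling of arachidonic-acid/eicosanoid metabolism in DDC-treated mouse liver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of arachidonic-acid/eicosanoid metabolism in DDC-treated mouse liver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eicosim)
```

## The biological system and the model

Chronic feeding of a DDC (3,5-diethoxycarbonyl-1,4-dihydrocollidine)
supplemented diet induces steatohepatitis-like liver injury in mice, with a
severity that depends on the genetic background: strong in A/J ("AJ"), mild
in C57BL/6J ("B6"), and essentially absent in PWD/PhJ ("PWD"). In all three
strains, arachidonic-acid (AA) metabolism is transcriptionally and
metabolically perturbed: the eicosanoids PGD2, 5-HPETE, 15-HPETE and 15-HETE
change concentration after eight weeks of treatment.

`eicosim` implements a deliberately small kinetic model of this pathway:
eight metabolites, twelve reactions, three branches downstream of AA release.

* **Release.** Phosphatidylcholine (PC) is hydrolysed by phospholipase A2
  (PLA2) to AA (R1). PLA2 activity requires ERK phosphorylation, and AA
  feeds back to inhibit its own release.
* **5-LOX branch.** AA is converted by 5-lipoxygenase (ALOX5) with its
  activating protein (ALOX5AP/FLAP) to 5-HPETE (R2) and further to
  leukotriene A4 (R4); both steps are product-inhibited.
* **15-LOX branch.** AA is converted to 15-HPETE (R6) by ALOX15 in a complex
  with PKC-delta and phosphorylated STAT3, with 15-HPETE feedback
  inhibition; 15-HPETE is reduced to 15-HETE (R7) with 15-HETE feedback.
* **Prostaglandin branch.** Cyclooxygenase-1 (PTGS1) converts AA to PGH2
  (R9, product-inhibited), and prostaglandin D2 synthase (PTGDS) converts
  PGH2 to PGD2 (R10).
* **Turnover.** 5-HPETE, LTA4, 15-HETE, PGD2 and AA leave the system by
  first-order degradation (R3, R5, R8, R11, R12); the model is open and the
  sinks discard mass.

PC is a clamped boundary species: it enters the R1 flux but carries no
differential equation. Every other metabolite is a state variable, so the
ODE system has seven states. All internal concentrations are in nM; PC is
tabulated in µM and multiplied by 1000 at ingestion, so a user can never mix
the two scales silently.

### Rate laws

Enzyme-catalysed steps use irreversible Michaelis–Menten kinetics with
competitive product/feedback inhibition,

$$v \;=\; V_{max}\,\Big(\prod_j u_j\Big)\,
       \frac{[S]}{K_m\,(1 + [I]/K_i) + [S]},$$

first-order sinks use $v = k_{cat} [S]$, and R10 is linear in its substrate,
$v = V_{max}\, u_{PTGDS}\, [\mathrm{PGH2}]$. The $u_j$ are unitless
*activity ratios*: 1 in the control state, the DDC/control fold change of
the corresponding transcript (RNA-Seq) or phospho-protein (RPPA) in the
treated state. Enzymes are not explicit state variables; they enter as these
multipliers on a basal concentration of 1.0 nM that is folded into
$V_{max}$, which is why the tabulated $V_{max}$ unit exponent
(nM·s⁻¹, nM²·s⁻¹, nM³·s⁻¹) always equals the number of activators of the
reaction.

The algebraic form of the inhibition term deserves a note: the published
description of this model tabulates its kinetic constants and regulatory
links, but the exact algebra of the inhibition term is ambiguous.
Three readings are dimensionally or kinetically defensible: a bare
$1/(K_i + [I])$ factor (which absorbs one nM into $V_{max}$), the
non-competitive $1/(1 + [I]/K_i)$, and the competitive form used here. We
transcribed all three and compared the resulting steady-state fold-change
predictions with the values the study reports (AA 1.35-fold in B6, PGD2
about 2-fold and AA 1.2-fold in AJ, and the panel of >1.5-fold calls). The
competitive form is the only one that reproduces the AJ PGD2 prediction and
all of the cross-strain >1.5-fold calls, while also being dimensionless and
the textbook form for product inhibition; it is therefore the package
default. The residual disagreement this choice leaves behind is discussed
under *Known limitations*.

### Two structural switches

Two points in the published description of the model are internally
contradictory, so they are exposed as explicit arguments of `eico_model()`
rather than buried in a silent choice:

* **`r7_activator`** — the catalyst of 15-HPETE → 15-HETE. The parameter
  table attributes R7 to ALOX15, but the pathway diagram and the
  drug-screen narrative attribute it to glutathione peroxidase (GPX), and
  only the GPX reading gives the tabulated GPX activity ratios (6.51, 11.70,
  19.42) any effect on the model at all. The default is `"GPX"`. The choice
  is consequential for the reversion screen: at steady state the flux chain
  AA → 15-HPETE → 15-HETE forces $v_7 = v_6$, so the 15-HETE level is set by
  R6 alone and GPX only positions the intermediate 15-HPETE, whose
  steady-state level is then inversely proportional to the GPX ratio.
* **`r1_scaling`** — whether R1 is scaled once or twice by the p-ERK fold
  change. The tabulated "PLA2" initial value *is* the p-ERK RPPA ratio (the
  PLA2 transcript Pla2g4a is expressed below 1 RPKM and not differentially),
  so multiplying both the PLA2 row and the p-ERK ratio into R1 squares a
  single measurement. The default `"single"` applies it once; `"double"` is
  available for comparison. Under double scaling the simulated AA fold
  changes overshoot the reported values by roughly a factor of two, and the
  six-enzyme reversion can no longer restore AA, which we take as evidence
  that the original model scaled R1 once.

## Strain conditions and expression mapping

A `eico_condition` holds the ten activity ratios plus the measured PC
concentration for one strain × treatment. The shipped table contains the six
study conditions; `build_condition()` reconstructs them from omics tables:

* transcript ratios for PTGS1 (Ptgs1), ALOX5AP (Alox5ap), PKCD (Prkcd);
* an isoenzyme-selection rule for GPX: among the Gpx family the most
  significantly differentially expressed gene wins (ties broken by higher
  mean expression, then alphabetically), which selects Gpx3 in the study
  data;
* RPPA protein ratios for p-ERK and p-STAT3;
* the non-differential rule: genes with adjusted p above the cutoff (0.05)
  or mean expression below 1 RPKM keep ratio 1 (Pla2g4a, Alox5, Alox15,
  Ptgds);
* a guarded fallback: a non-positive control value makes the gene
  unmappable and the ratio falls back to 1 with a warning.

## Steady states and fold-change classification

The study interprets eight-week measurements as steady states, so the
simulation surface is the equilibrium map: `steady_state()` integrates the
stiff system (LSODA) over geometrically growing horizons, polishes with a
damped Newton iteration on the right-hand side, and accepts when
$\max_x |d[x]/dt| \le$ `tol` (default $10^{-6}$ nM/s). Initial
concentrations of the non-fixed species default to 0 nM — the study does not
report absolute starting levels, and the package verifies start-state
independence (steady states from 0 nM and 10 nM starts agree within 0.1%
per species across all six conditions) rather than inventing numbers.

`fold_changes()` forms per-metabolite DDC/control ratios and classifies them
against a symmetric band: `up` at ratio ≥ 1.5, `down` at ≤ 1/1.5, otherwise
`unchanged`. The 1.5 threshold is the study's repeatedly used effect-size
convention and is exposed as an argument.

## Calibration

The calibration target is the metabolite set
M = {AA, 5-HPETE, 15-HPETE, 15-HETE, PGD2} with experimental steady-state
concentrations under both conditions of one strain:

$$f(p) \;=\; \sum_{x \in M} \big(ec_x - sc_x(p)\big)^2 +
             \big(ed_x - sd_x(p)\big)^2,$$

where $ec/ed$ are measured and $sc/sd$ simulated control/DDC steady
states. A candidate whose steady state fails to converge receives a large
finite penalty ($10^{12}$) so population-based optimizers continue. The
training strain defaults to B6 (the source text names B6 in its methods and
AJ in a table footnote; the `strain` argument makes the choice visible).

`eico_fit()` minimizes $f$ with an elitist genetic algorithm: tournament
selection (k = 2), uniform crossover (rate 0.7), per-gene log-normal
mutation (rate 0.1), elitism of one, genes encoded on the log scale of a
box spanning $[10^{-2}, 10^{2}]$ times each shipped constant. The
literature-sourced $K_m$ of R1 is pinned. Two optimizer choices were made on
performance grounds and deserve documentation:

* **Initial population.** Following the convention of kinetic-modelling
  suites, the current model constants are one individual of the initial
  population; the rest are scattered log-normally *around* them at the
  coarse mutation scale rather than uniformly over the whole four-decade
  box. The objective is dominated by the highest-concentration metabolite
  (AA, tens of µM against single-digit nM eicosanoids), and box-uniform
  initial populations reliably discover the degenerate trick of shutting
  down a low-flux branch (e.g. driving R9's $V_{max}$ to its lower bound)
  to fine-tune AA — a deep local optimum from which no later recombination
  recovers, because re-opening the branch requires a coordinated multi-gene
  move. Treating the curated constants as the centre of the search prior
  avoids manufacturing that trap.
* **Mutation scale.** The log-normal mutation standard deviation anneals
  geometrically across generations (default 0.2 → 0.02): steps comparable
  to the expected parameter misspecification early, fine polishing late.

Fits are deterministic given `seed`, and the per-generation best objective
(`generation_trace`) is non-increasing by elitism. The fitted object answers
the usual questions through `coef()`, `predict()` (steady states of the
fitted model), `residuals()`, `summary()`, `plot()` (the trace) and
`simulate()` (noisy replicate measurement tables around the fitted steady
states).

Identifiability is limited by design: ten concentrations cannot pin 23
constants, so recovery is asserted at the *steady-state* level, not per
parameter. The test suite runs a 50 × 500 recovery experiment on a
synthetic scenario (constants jittered log-normally at scale 0.2, noise-free
measurements) and requires the fitted steady states to lie within 10% of the
generating ones for all five metabolites of M under both conditions. Even at
the steady-state level the AA-dominated objective leaves the low-flux
branches weakly determined, and some optimizer seeds stall in the
branch-shutdown optimum described above; multi-start fitting (varying
`seed`) is recommended practice for real use.

## Perturbation screens

The **reversion screen** asks which subsets of the six DDC-perturbed
activities (ALOX5AP, GPX, PKCD, PTGS1, p-ERK, p-STAT3) must be returned to
control levels to normalize the metabolic state. The reference is the fully
normal condition; PC is a measured concentration, not an enzyme activity,
so it stays at its DDC value during reversion (its influence on the steady
state is small because R1 is nearly saturated in PC). A metabolite is
*restored* when its steady state lies within 10% (relative, exposed as
`reference_tolerance`) of the reference, and a subset restores the state
when every reported metabolite is restored. The default enumerates all 63
non-empty subsets. Under the default GPX reading of R7, subsets that leave
GPX perturbed cannot restore 15-HPETE (see the structural-switch discussion
above); the screen reports this honestly rather than special-casing it.

The **drug screen** divides one enzyme's activity ratio at a time by 3, 6
and 9 in the AJ DDC condition, recomputes the steady state and classifies
every metabolite against the unperturbed DDC baseline with the same 1.5-fold
band. The steady-state flux identity $v_7 = v_6$ explains its most
counter-intuitive prediction: knocking down GPX raises 15-HPETE (the
intermediate must accumulate to carry the same flux through a weaker enzyme)
while leaving 15-HETE unchanged.

## Synthetic data

`generate_scenario()` draws a ground-truth parameterization (shipped
constants jittered log-normally; scale 0 reproduces them exactly, and the
literature-pinned R1 $K_m$ is never jittered) together with the six study
conditions. `simulate_measurements()` solves the ground-truth steady states
and draws replicate measurements with multiplicative log-normal noise
(default CV 0.2, three replicates per condition, matching the study design)
summarized as median ± MAD, the convention of the mass-spectrometry tables
the pipeline consumes. `generate_omics_tables()` emits expression, protein
and PC tables — including decoy Gpx isoenzymes and low-expressed
non-differential genes — that rebuild the scenario conditions exactly
through `build_condition()`.

The generator emulates the *statistical shape* of the study data: fold
changes of the right magnitudes, right-skewed positive measurement noise,
median/MAD summaries, isoenzyme ambiguity. It does not emulate raw reads or
spectra, transcript-to-protein discordance, inter-animal covariance, or
systematic batch effects; passing the synthetic-recovery tests therefore
demonstrates correctness of the pipeline's computations, not robustness of
the biology to those real-data complications.

## Numerical choices

* Steady-state tolerance $10^{-6}$ nM/s; solver tolerances $10^{-8}$
  (integration is a coarse approach phase; Newton does the precision work).
* The Newton polish uses a forward-difference Jacobian with step
  $\max(|y|, 10^{-8}) \times 10^{-6}$, step-halving damping, and rejects
  steps that leave the non-negative orthant.
* Inside the calibration objective, consecutive candidates warm-start the
  Newton iteration from the previous steady state and fall back to the full
  integrate-then-polish path when it fails; each `eico_fit()` run clears
  the warm cache first so results are reproducible run to run.
* Fold-change ratios against a zero control concentration are reported as
  `NA` with `NA` classification rather than infinities.
* Test problem sizes: the Euler-oracle cross-checks integrate 100 s at
  dt = 1 ms and 40,000 s at dt = 0.5 s; the GA recovery experiment runs the
  full 50 × 500 design; the jitter-law check uses 1000 Monte-Carlo draws.

## Known limitations

* The competitive-inhibition transcription of the rate laws is the
  best-supported reading of the published model, not a verbatim copy of
  equations that were never printed unambiguously. Under it, three
  reported values are not reproduced
  at their printed precision: the B6 AA fold change simulates to ≈1.49
  (reported 1.35), the AJ AA fold change to ≈1.36 (reported 1.2), and the
  B6 PGD2 fold change to ≈1.41 (reported >1.5). An elasticity analysis
  shows the three AA targets are mutually unreachable for *any* monotone
  rate law driven by the tabulated p-ERK and PC values — matching B6 and AJ
  forces PWD's AA ratio to ≈1.44 < 1.5 — so the package reports its
  computed values rather than absorbing the discrepancy into hidden
  recalibration. The acceptance tests encode the printed values and are
  allowed to fail there.
* The GPX/ALOX15 contradiction in R7 means no single model variant
  reproduces both the five-enzyme reversion result and the GPX drug-screen
  result; the default favours the drug screen.
* Degradation sinks lump transport, conjugation and downstream metabolism
  into single first-order constants; absolute concentrations are therefore
  only order-of-magnitude meaningful, and the package interprets ratios.
* The GA's recovery of weakly determined branch parameters is
  seed-dependent (see Calibration); treat single-seed fits as provisional.
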