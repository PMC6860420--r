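---
title: "Modeling macrophage polarization with macpol: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling macrophage polarization with macpol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what the model
is, what its assumptions and tunable parameters mean, how the numerical
machinery is set up, which design decisions were genuinely open, and
what the test suite does and does not demonstrate.

## 1. The model

`macrophage_model()` builds a deterministic reaction network describing
a single macrophage (plus its cell-equivalent share of medium) exposed
to the three canonical polarization drivers:

* **IFN-γ (M1 arm).** Ligand binds a coarse-grained receptor/JAK unit;
  the ligated complex activates by trans-phosphorylation; STAT1 docks
  on the active complex, is phosphorylated, dimerizes and translocates
  to the nucleus, where it drives IRF-1, SOCS1/3 and the M1 markers
  (TNF-α, IL-12, CXCL9, CXCL10; iNOS through IRF-1). The IFN-γ
  receptor is not internalized; ligand is consumed by complex
  turnover.
* **IL-4 (M2 arm).** Symmetric STAT6 cascade, with additional receptor
  complex internalization, recycling and lysosomal degradation. AKT
  activation is a single catalytic step downstream of the active IL-4
  receptor complex; PTEN reverses it. STAT6 drives IRF-4 and PPAR-γ;
  those drive Arg-1 and (via PPAR-γ → HIF-2α) VEGF; AKT drives IL-10.
  IL-13 input is treated as IL-4 (functional equivalence), so a
  combined IL-4/IL-13 dose is entered as a single IL-4 stimulus.
* **Oxygen / HIF arm.** A lumped PHD/FIH sensor is activated by
  molecular oxygen; the activation step consumes two O₂ equivalents,
  reflecting the two oxygen-dependent hydroxylation events lumped into
  the single sensor species, which gives the switch-like hypoxic
  response a simple mass-action origin. Active sensor hydroxylates the
  HIF-1α/HIF-2α subunits, routing them to proteasomal degradation
  (with a de-ubiquitination reverse step for HIF-1α); under hypoxia
  the subunits escape, translocate, and dimerize with a conserved
  HIF-1β pool. HIF-1 drives iNOS and an autocrine IFN-γ production
  loop (the model's hypoxia→M1 route); HIF-2 drives Arg-1 and VEGF.
* **Cross-talk.** SOCS1 binds active receptor complexes of both arms
  (degradative), SOCS3 binds them too (sequestering); nuclear
  phospho-STAT1 and phospho-STAT6 dimers sequester each other; STAT6
  destabilizes the IRF-1 transcript; IFN-γ (via STAT1) depletes
  miR-3473b, de-repressing PTEN and thereby damping AKT; hypoxia (via
  HIF-1) depletes miR-93, de-repressing IRF-9 and the HIF-1α
  transcript; IRF-1 with IRF-9 drive IRG-1, hence itaconate, which
  limits ROS, which in turn sequesters the active oxygen sensor.

The network has 80 nodes in 34 unique-species groups (a group collects
all states of one molecule: free/phospho/dimer/nuclear forms, bound
complexes, its mRNA) and 130 reactions. miRs act by direct binding of
their target transcripts with degradation of the bound mRNA and
recycling of the miR.

**Provenance.** The topology transcribes the published mechanistic
description of these pathways. The kinetic constants and copy numbers,
however, are a *synthetic nominal set* chosen by this package: they
produce a stable unpolarized baseline with plausible per-cell
abundances (receptors ~2×10³, STATs ~2×10⁵, transcripts 10–10²) and
qualitatively correct responses. They are not fitted to literature
data, and quantitative fold changes should be read as illustrative.
`macrophage_priors()` ships the matching synthetic copy-number
reference values used by the admissibility check.

## 2. Units, inputs and events

* State unit: molecules per cell; secreted/extracellular species are
  molecules per cell-equivalent medium volume. Time unit: hours.
* Doses: `dose_to_copies(dose, mol_weight, cell_density)` =
  `dose × 10⁻⁹ / MW × N_A / density`, default density 10⁶ cells/ml.
  Molecular weights are scenario inputs (the shipped presets use
  rounded values of 17 kDa for IFN-γ and 14 kDa for IL-4); miR mimics
  are dosed directly in copies.
* Events add (`+=`) ligand to the current extracellular pool — a
  second stimulus is an addition without media change. Oxygen
  conditions replace the buffered O₂ species, `percent/21 ×` the
  normoxic value.
* Extracellular cytokines carry a first-order clearance term that
  lumps uptake by the surrounding cell population with their
  receptor-mediated consumption; without it the autocrine loops have
  no finite steady state.

## 3. Numerical choices

* **Integration**: `deSolve::ode(method = "lsoda")`, stiff-capable,
  with rtol 10⁻⁶ and atol 10⁻³ molecules by default. Negative state
  entries are clamped to zero inside the rate evaluation (mass-action
  positivity guard); output values below zero by more than ~10 × atol
  abort the run, smaller undershoot is clamped.
* **Equilibration** (`equilibrate`): repeated integration over
  doubling horizons until `max |dx/dt| / max(x, 1) < 10⁻⁸` per hour
  (cap 2×10⁵ h). The equilibrated state is the t = 0 baseline of every
  scenario, which keeps all normalization denominators strictly
  positive.
* **Sensitivity baselines**: `score_sensitivity` equilibrates each
  parameter draw warm-started from the nominal steady state and
  accepts a relaxed residual (5×10⁻³/h, capped horizon). At the
  default ×/÷10 log-uniform ranges a few percent of draws settle only
  to ~10⁻³/h (very slow modes or sub-0.1 % limit cycles around the
  fixed point); such bounded drift is invisible to a rank statistic
  over a 24 h readout, while truly divergent draws still fail and are
  dropped (analysis aborts above `max_fail_frac`, default 5 %).
* **Rate-law dialect**: Hill kinds take the first modifier as the
  regulator; a missing Hill-coefficient label means n = 1
  (Michaelis-type saturation — the weakest assumption). Reversible
  mass action carries exactly (kf, kr).
* **Hypoxia switch**: the O₂ stoichiometry of 2 in the sensor
  activation makes active sensor scale with O₂², i.e. ~100-fold down
  from 21 % to 2 % O₂, which is what gives HIF stabilization its
  dynamic range without Hill exponents on oxygen itself.

## 4. Perturbation semantics

`apply_perturbations` implements typed edits of the equilibrated
baseline and parameter set: overexpression = principal node ×50 with
production unchanged; silencing = group zeroed, all synthesis
reactions into the group zeroed, *and* any complex able to release a
group member zeroed as well (complexes form from their members, so
they cannot re-form; this closure is what makes silenced trajectories
identically zero rather than transiently re-fed by dissociating
complexes); production scaling multiplies the rate constants of all
zero-reactant synthesis reactions of the group; rate scaling
multiplies one named constant. Edits compose order-independently, and
two edits touching the same constant raise an error. The shipped
presets encode the standard scenarios: synthesis inhibition as
production ×0.1, receptor/STAT/PHD blockade as the respective binding
rate ×0.1, tumor-like IL-4 excess as production ×10, SOCS
overexpression/silencing as above.

## 5. The M1/M2 score and marker panels

The score is the product of six M1 marker levels over the product of
three M2 marker levels at one evaluation time (default 24 h). Markers
enter as raw copy numbers, not fold changes: the score is a ratio, so
baseline scaling cancels when scores are compared between scenarios,
and absolute score values are meaningless in isolation. The default
panels (M1: iNOS, TNF-α, IL-12, CXCL9, CXCL10, IFN-γ; M2: Arg-1,
IL-10, VEGF) follow the markers tracked throughout the polarization
literature, with CXCL10 reported at the mRNA level; the panel sizes
are fixed by the score definition but membership is configurable
because no canonical list exists.

## 6. Sensitivity analysis

`lhs_sample` stratifies each parameter's log-uniform range (default
×/÷10 around nominal — the range is a configuration field, and wider
ranges increase the failed-draw fraction). `prcc` rank-transforms
parameters and output (average ranks on ties) and correlates the
residuals after rank-regressing out all other parameters; significance
uses the t statistic on n − 2 − (p − 1) degrees of freedom, reported
raw at p < 0.05 without multiple-testing correction (a
Benjamini-Hochberg adjustment can be applied to the returned p-values
but is deliberately not the default). PRCC is invariant to monotone
transformations of the score, so working with the raw product ratio
rather than its logarithm changes nothing.

## 7. Calibration machinery

The objective is `Σ_datasets weight × Σ_points (sim − obs)²`, each
dataset simulated under its own scenario and normalized with its own
mode (to-t0, to-max, to-reference-time, log2-fold, to-untreated).
Default weights are 1/n_points per dataset, equalizing dataset
influence. Copy-number admissibility (each group's steady total within
0.5×–2× of its prior) enters as a smooth quadratic penalty in
log-distance outside the band, keeping the direct search informative; a
strict mode rejects violations outright. Simulation failures contribute
a large finite penalty so the search can walk out of pathological
regions.

`fit` is a compass pattern search on log-scale parameters: poll ±step
per coordinate in fixed order, accept improvements, double the mesh on
success and halve it otherwise — derivative-free, bound-respecting,
monotone over accepted iterations and deterministic given seed and
start; three seeded multistarts by default. `bootstrap_fit` resamples
at the dataset level (points within a series are correlated, so
point-level resampling would understate uncertainty) and refits each
replicate from an independently seeded, jittered start — flat
(non-identifiable) directions then surface as bootstrap spread instead
of silently inheriting the nominal value, which is the basis of the
identifiability contrast in the tests.

The full-network refit is deliberately out of scope (it is a
cluster-scale computation); the machinery is demonstrated and tested
on toy cascades and registry subsets.

## 8. Synthetic data: what it does and does not show

`make_toy` generates networks with attached closed-form references
(production/degradation with its full trajectory, cascades with
closed-form steady states, a conserved conversion cycle, and a
ligand-receptor-STAT motif with SOCS-like feedback that reproduces the
peak-then-decay shape of phospho-STAT responses). These oracles are the
engine's primary correctness surface.

`make_synthetic_datasets` and `macrophage_registry` simulate stated
scenario catalogs and apply multiplicative lognormal noise with a
chosen coefficient of variation (expression data are positive, so
additive Gaussian noise would be wrong near zero; the catalog mirrors
the kind of series a literature calibration assembles — 72 datasets,
456 points across the three arms at several doses and oxygen levels,
with per-dataset normalization modes). The registry is explicitly a
synthetic stand-in for digitized experimental data: passing tests
against it demonstrates that the calibration machinery is correct and
that the corpus is simulatable, not that the model reproduces any
particular experiment. Real data add systematic errors the noise model
does not emulate: digitization bias, inter-laboratory and cell-line
differences, non-lognormal detection floors.

Problem sizes used in the shipped checks (chosen to keep the default
run on one CPU in a few minutes): 100 random networks for the
derivative oracle, n = 1000 for PRCC null/sign properties, n = 150
draws for the full-model hypoxia PRCC, 20 seeds for parameter
recovery, 5-replicate bootstrap demonstrations.

## 9. Known limitations

* Kinetics are synthetic; quantitative outputs are illustrative until
  the model is calibrated against real measurement series via the
  provided machinery.
* Deterministic mass action only — no stochastic transcription
  bursting; averages over a cell population are what the trajectories
  represent.
* No spatial or tissue-level structure, no media exchange/washout, no
  pharmacokinetic ligand decay beyond the lumped consumption term.
* The oxygen sensor's O₂² activation is a deliberate lumping of two
  hydroxylation events, not a measured cooperativity.
* Silencing semantics assume complexes form from their members; a
  network violating that (a complex synthesized de novo) would need
  its production reactions zeroed explicitly.
* At extreme corners of wide sensitivity ranges the baseline can
  oscillate with small amplitude; such draws are accepted under the
  relaxed residual policy described above rather than discarded.
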