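---
title: "Models and methods: biophysical evolution of whale myoglobin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: biophysical evolution of whale myoglobin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomb)
```

## The scientific problem

Deep-diving whales keep far more myoglobin (Mb) in their myocytes than
terrestrial mammals, and the protein must stay soluble and folded at those
concentrations. Resurrected ancestral Mb sequences make it possible to ask
*when*, along the lineage from a terrestrial ancestor (aMbWp, a
*Pakicetus*-era reconstruction) through the last common whale ancestor
(aMbWb, with aMbWb′ the reconstruction under the alternative cetacean
phylogeny) to extant sperm-whale Mb (swMb), each biophysical property
changed. This package implements the quantitative layer of that analysis:
sequence bookkeeping, five experimental-model fits, and the correlation of
every property with evolutionary distance.

## Lineage reconstruction

Sequences are handled in 1-based mature-chain numbering (position 1 is the
first residue after cleavage of the initiator Met), so the compact token
`"G1V"` refers to the mature N-terminus. The packaged extant sequence is
the canonical 153-residue sperm-whale mature chain; every ancestor is
**derived** by reverse-applying the curated per-branch substitution lists,
never hard-coded. A residue mismatch at any event position is an error:
silent renumbering would corrupt every downstream property.

The curated lists are internally ambiguous about whether the two sites
distinguishing the alternative whale-ancestor reconstruction (positions 1
and 15) lie on the main evolutionary path: the stated per-branch counts
(7 early + 10 late = 17 events) exclude them, while the alternative
reconstruction carries Gly at both positions. We adopt the 17-event
accounting: the main path is aMbWp → aMbWb → swMb, and aMbWb′ is
represented as a two-site variant of aMbWb obtained by reverse-applying
`G1V` and `G15A`. Under this accounting event counts and site differences
disagree by exactly 2 — position 13 is substituted V→I early and reverted
I→V late — which the tests assert explicitly.

Three property conventions are switchable because published values rarely
state them:

* **Formal net charge** counts +1 per Lys/Arg and the N-terminus, −1 per
  Asp/Glu and the C-terminus. His is neutral by default (`his_charge`
  switches it), and the two heme propionates are excluded by default
  (`include_heme` subtracts 2 for the holo-protein).
* **Isoelectric point** is the bisection root of the
  Henderson–Hasselbalch titration charge on pH ∈ [0, 14] (tolerance 1e-4).
  Two pKa tables ship with the package (`"emboss"`, the default, and
  `"lehninger"`); the table name is recorded in every result. Orderings
  along the lineage are stable across tables even though absolute pI
  values differ.
* **Evolutionary distance** is the per-pair Poisson-corrected distance
  d = −ln(1 − p). Published distances come from a maximum-parsimony-style
  tree over a large globin alignment that this package deliberately does
  not rebuild, so absolute values differ from the published axis while the
  taxon ordering is preserved — every downstream correlation uses only the
  joint variation, not the absolute scale.

## Solubility under a polymeric precipitant

PEG sedimentation series follow the log-linear (Cohn-type) law
log₁₀ S = log₁₀ S₀ + β·[PEG], with S₀ the extrapolated solubility in water
and β (negative) the precipitant tolerance. The fit is ordinary least
squares in log₁₀ space — base 10 throughout, matching how such data are
plotted — unweighted by default because published fits state no weights; a
`sigma` column switches to weighted LS. Points below a detection floor
(default 0.01 mg/mL, the practical quantification limit of a
spectrophotometric assay) are dropped with a warning rather than clamped,
because clamping would bias β.

## SAXS virial analysis

Raw profiles are converted to absolute scale with
I(q) = [I_S(q) − (1 − c_p v)·I_B(q)]/f, using v = 0.7425 cm³/g and an
instrument calibration factor f that must be supplied — no water
calibration is implemented. Zero-angle intensities come from Guinier
fits (ln I vs q²) inside a self-consistent window q·R_g ≤ 1.3, the
standard rule for globular proteins; the window is iterated to a fixed
point, and a period-2 oscillation between adjacent windows (possible with
noisy data) also counts as converged. A rising slope aborts the fit: that
is aggregation or a bad buffer, not a statistical fluctuation.

The concentration series is reduced through the linearization
c_p/I(0) = 1/(kM) + (2A₂/k)·c_p with k = v²(Δρ)²/N_A and
Δρ = 2.8×10¹⁰ cm⁻² by default. The linearized route was chosen over a
direct nonlinear fit because it has a closed form and well-understood
standard errors; at the noise levels and concentration ranges used here
the two agree within the reported uncertainties. The hard-sphere
excluded-volume reference A₂ = 4v/M provides the natural comparison line.
Units are strict throughout (q in Å⁻¹, c_p in g/cm³, absolute I in cm⁻¹);
the conversions mg/mL → g/cm³ and nm⁻¹ → Å⁻¹ are exported functions, never
implicit.

## Three-state denaturation

Normalized 222 nm CD melts are fit to the three-state model F ⇌ I ⇌ U with
linear free-energy dependence on denaturant: ΔG₁ = ΔG°₁ + m₁x (folded vs
intermediate) and ΔG₂ = ΔG°₂ + m₂x (intermediate vs unfolded), both in
kcal/mol with R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹ and T = 298.15 K by default.
State fractions are computed from the three Boltzmann weights after
subtracting the common maximum exponent, so they sum to one to 1e-12 and
never overflow, even for |ΔG| ≫ RT. The observable is
y = f_F + γ·f_I, γ ∈ [0, 1] being the intermediate's helical content
relative to the folded state; the unfolded-style trace 1 − y is exposed
for plotting.

The five-parameter fit (ΔG°₁, ΔG°₂, m₁, m₂, γ) uses Levenberg–Marquardt
with box bounds (γ ∈ [0,1], ΔG°ᵢ ∈ [−30, 0], mᵢ ∈ (0, 10]).
Initialization comes from a two-state pre-fit whose total ΔG and m are
split 40/60 between the stages with γ₀ = 0.5; because that surface has a
known local optimum in which one stage collapses (m → 0, γ pinned), a
small deterministic grid of fallback starts built from crude midpoint
reads of the curve is also tried and the best residual sum wins. The fit
is reproducible: every start is deterministic. γ is reported as
unidentifiable when it pins at a bound, when its 2-se interval touches a
bound, or when the covariance is unusable — fitting genuinely two-state
data triggers exactly this flag. Input melts are assumed normalized; a
linear pre/post-baseline helper (`normalize_baselines`) covers raw
ellipticity traces.

## Oxygen equilibrium

Hill analysis regresses log₁₀(Y/(1−Y)) on log₁₀ pO₂. Saturations outside
[0.05, 0.95] are excluded before the transform — the log-ratio variance
explodes near 0 and 1, and those bounds stabilize the regression without
touching the informative mid-range. P₅₀ comes from the x-intercept of the
*unconstrained* line (P₅₀ = 10^(−intercept/slope)), matching standard
Hill-plot practice; an n = 1-constrained estimate is reported alongside.
Plain regression standard errors are reported — the instrument-specific
cumulative-pressure error model of tonometer measurements is not
reconstructed here.

## Ensemble solvation free energy

Per-conformation solvation free energies (from an upstream
integral-equation solver, which is out of scope here) are combined with
the fluctuation-corrected average
ΔG_solv = ⟨ΔG_i⟩ − k_BT·ln⟨exp[−(ΔG_i − ⟨ΔG_i⟩)/k_BT]⟩,
evaluated by log-sum-exp so spreads of hundreds of kcal/mol cannot
overflow. k_BT is written as R·T in kcal/mol: the samples are molar
quantities, so the per-molecule constant would be wrong by Avogadro's
number. Jensen's inequality guarantees ΔG_solv ≤ ⟨ΔG_i⟩, with equality
only for zero spread; for Gaussian samples the correction has the closed
form −σ²/2RT, which the tests verify on 10⁶ draws.

## Correlation structure

The taxon × property table (pI, Z, log S₀, β, ΔG_solv, M_r, A₂, ΔΔG_mut,
ΔG_fold, P₅₀ against distance d) is correlated with plain Pearson r on raw
values — the simplest defensible choice, and the one recorded in the
output. With four taxa, r is descriptive: the module never reports
p-values, and nothing in the package pretends otherwise. Property groups
are formed by single linkage over |r| ≥ 0.9, absolute value because
strongly positive and strongly negative correlations with distance express
the same temporal structure. ΔΔG_mut (structure-based mutational folding
energies) is consumed as an externally supplied column; computing it is
out of scope.

## The synthetic-data generator

Every generator is the exact inverse of its fitter at zero noise, and the
test suite holds that property over 50 random parameter draws. Noise
models are additive Gaussian in the space each fit operates in: log₁₀
space for solubility (σ = 0.05, a realistic replicate error when
extrapolating a 10–40% w/v PEG series back to zero), linear space for CD
melts and saturations (σ = 0.01 each, typical for averaged CD and
spectrophotometric tonometry), multiplicative for SAXS (1%), and Gaussian
conformational spread for the solvation samples (σ = 2 kcal/mol over
5,000 conformations, enough to make the fluctuation term a few kcal/mol
without letting its estimator be dominated by single extreme draws).

The four-taxon truth table encodes the study conditions as stated trends:
β, Z and ΔG_solv change early then plateau; A₂ grows monotonically;
ΔG_fold and the supplied ΔΔG_mut column improve mostly late; P₅₀ values
are the four measured ones (0.42, 0.46, 0.46, 0.52 mmHg). Design grids
follow the experiments: PEG 10–40% w/v in 5% steps, denaturant 0–4 M at 30
points, 12 log-spaced pressures over 0.05–5 mmHg, four SAXS concentrations
between 5 and 40 mg/mL on a 0.01–0.55 Å⁻¹ grid. One master seed fans out
to per-taxon, per-modality child seeds through a deterministic string
hash, so adding a modality never perturbs existing outputs, and the
generators restore the caller's RNG state.

What the generator does *not* emulate: instrument drift and baseline
curvature in CD, inter-particle structure factors and beam smearing in
SAXS, met-Mb autoxidation during tonometry, gel formation in sedimentation
assays, and correlated (non-Gaussian) conformational sampling. Passing
recovery tests on these synthetic data therefore demonstrates correctness
of the estimators under the stated statistical model, not robustness to
every real-data pathology.

## Problem sizes and numerical choices

The default test and pipeline runs use the sizes above (they complete in
well under a minute); Monte-Carlo calibrations use 120–500 replicates,
chosen so sampling error is comfortably below the tolerances being
asserted. Bisection for pI runs to 1e-4 pH; the LM fits run with ftol and
ptol at 1e-15 so zero-noise round-trips sit at numerical precision;
tie-breaks in the correlation clustering are resolved by input column
order, making every output deterministic.

## Known limitations

* Absolute evolutionary distances are per-pair Poisson values, not tree
  distances; only orderings and correlations should be interpreted.
* The label swap between the two whale-ancestor reconstructions in the
  source material is unresolved; the package treats them as
  interchangeable sequence variants and keeps both.
* The formal-charge and pI conventions (His protonation, heme charges)
  are choices; published values may use others, so the switches matter
  when comparing absolute numbers.
* Supplementary fitted values for the wet-lab datasets are not available
  to this package; all recovery claims are against synthetic ground
  truth, with the measured P₅₀ set as the one directly reproducible
  quantity.
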