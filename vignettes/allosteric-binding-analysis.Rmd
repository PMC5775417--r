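---
title: "Allosteric ternary complex analysis of radioligand binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allosteric ternary complex analysis of radioligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atcmfit)
```

## The problem

A negative allosteric modulator (NAM) of a G protein-coupled receptor
binds a site distinct from the orthosteric pocket and reduces the
affinity of orthosteric ligands by a factor α < 1 rather than by direct
competition. In a radioligand binding assay the diagnostic signature is
*partial* displacement: as the modulator concentration grows, specific
binding falls to a plateau set by the cooperativity instead of to zero.
Quantifying a NAM therefore means estimating two parameters — its
equilibrium dissociation constant K~B~ and the cooperativity α with each
orthosteric ligand — from titration curves, across receptor constructs
(wild type and point mutants) and ionic conditions (e.g. physiological
Na^+^ vs a sodium-free buffer with an inert organic cation). This package
implements the full quantitative chain: closed-form equilibrium models,
an exact mass-action solver that checks them, a seeded experiment
simulator, per-experiment nonlinear fits with replicate aggregation,
nested-model comparison, and condition-level statistics and reporting.

## Models and assumptions

All concentrations are carried in molar; dissociation constants as
pK = −log~10~ K and cooperativities as log~10~ α. Four closed forms cover
the assay designs:

* **Saturation**: specific binding B~max~[A]/([A] + K~d~) plus a linear
  nonspecific component ns·[A], fitted jointly on the total and
  nonspecific arms (`saturation_binding()`, `fit_saturation()`).
* **Allosteric ternary complex model (ATCM)**, percent-of-vehicle scale:
  Y = (A/K~A~) / (A/K~A~ + (1 + B/K~B~)/(1 + αB/K~B~))
  (`atcm_occupancy()`, `fit_atcm()`). Its saturating-modulator limit
  (A/K~A~)/(A/K~A~ + 1/α) is exposed as `atcm_plateau()`.
* **Extended three-ligand ATCM** for radioligand + competitor +
  modulator (`extended_atcm_binding()`, `fit_extended_atcm()`), with
  role-named cooperativities `log_alpha_rad` (modulator × radioligand)
  and `log_alpha_comp` (modulator × competitor). Naming by role rather
  than by Greek letter avoids any ambiguity about which α multiplies
  which term. At B = 0 the model reduces to classical one-site
  competition, at I = 0 to the ATCM; both reductions are verified to
  10^−12^ relative in the tests.
* **Four-parameter logistic**: Y = Bottom + (Top − Bottom)/(1 +
  10^(x − logIC50)·n~H~^) (`hill_curve()`, `fit_hill()`), with
  Cheng–Prusoff conversion of IC50 to K~i~. We use the standard
  parameterisation in which the curve equals Bottom at saturating ligand
  for any Bottom — a printed form that places (Top − Bottom) inside the
  numerator sum would fail that limit unless Bottom = 0 — and the
  midpoint property Y(logIC50) = (Top + Bottom)/2 holds exactly.

The closed forms all assume the free ligand concentration equals the
total (no depletion by the receptor) and a single modulator site at
equilibrium. Kinetic (non-equilibrium) models and multi-site or
receptor-dimer mechanisms are out of scope.

Cooperativity bounds deserve a note: log α is restricted to [−4, 2] in
fitting, and α = 0 (log α = −∞) is accepted in the forward models as the
pseudo-competitive boundary, so "assuming complete displacement" fits are
expressible (`fit_atcm(model = "competitive")`, `fit_hill(fixed =
c(bottom = 0))`).

## The mass-action oracle

`solve_equilibrium()` solves the exact equilibrium of receptor R,
radioligand A, modulator B and competitor I — species RA, RB, RI and the
ternary complexes RAB, RIB — from totals, with no free-ligand
approximation. Free concentrations are iterated by a damped fixed point
(geometric-mean damping, which preserves positivity), each update being
the mass balance of one species given the others; the map is monotone in
each free concentration, so the physical root is unique. Convergence
tolerance is 10^−12^ relative with a 10^5^ iteration cap;
non-convergence raises an error carrying the worst mass-balance
residual. The oracle serves two purposes: it is an independent check of
the closed forms (agreement within 1% whenever receptor total ≤ 1% of
each ligand total — asserted over an (A, B, I) grid in the tests), and
it quantifies the ligand-depletion error the closed forms ignore at high
receptor density.

## The synthetic-experiment generator

`simulation_spec()` + `simulate_saturation_experiment()` /
`simulate_interaction_experiment()` emulate the standard assay designs:

* saturation of the radioligand (default 10 points, 2 nM down to
  ~5 pM, factor 1.945) with a paired nonspecific arm;
* competitor or modulator titrations at fixed radioligand (default 12
  half-log points from 30 µM, matching the convention of testing
  modulators up to 30 µM, plus an explicit vehicle point);
* the interaction matrix: competitor titrations (default 1 mM down,
  half-log) at fixed modulator concentrations, default 0/1/3/10 µM.
  The modulator levels deliberately span from ~3× below to ~30× above a
  mid-nanomolar K~B~: with a narrower span (top only ~8× K~B~) the
  competitor cooperativity is not reliably identifiable per experiment
  at realistic noise — the SSR optimum can slide into an
  α′ → 0 / low-pK~B~ trade-off basin — whereas the wider span pins it
  with a per-experiment SEM of a few hundredths of a log unit, the
  precision such interaction studies actually report.

Noise is multiplicative Gaussian with coefficient of variation
`noise_cv` (default 5%), truncated at zero. The assays count
scintillation events, whose error scales with the signal, and
multiplicative noise is scale-free on the % control scale; the default
CV reproduces the SEM magnitudes typical of three-experiment binding
studies. The default replicate count is 3 individual experiments, the
field's reporting convention. Seeds are mandatory and never
auto-generated; each experiment receives its own reproducible substream
derived from the spec seed, so replicates carry independent noise.

What the generator does **not** emulate: membrane-preparation and
between-day variability (noise is i.i.d. across wells), filtration
losses, radioligand depletion (the oracle covers that analytically),
technical replication within a curve (wells are singlets), and any
systematic error in concentration preparation. Passing recovery tests on
these simulations therefore demonstrates the correctness and calibration
of the estimation pipeline under the stated error model — not robustness
to every artefact of real membrane assays.

`binding_regimes()` ships the literature parameter regimes for the D2
dopamine receptor system this workflow was built around — the
[^3^H]spiperone radioligand, dopamine, and a series of NAMs and
orthosteric fragments at wild-type, D80A and E95A constructs in NaCl or
NMDG buffer — so the generator can be pointed at realistic conditions by
name.

## Fitting

All estimation is Levenberg–Marquardt least squares (via `minpack.lm`)
on the log-parameter scale: pK in [3, 13], log α in [−4, 2], which keeps
parameters positive, roughly symmetrises their sampling distributions,
and matches how binding parameters are reported and compared. Nonlinear
ternary-complex surfaces can be multimodal, so every fit runs a
deterministic multi-start — a 3×3 grid over (pK~B~, log α) spanning the
bounds for the ATCM fits, three logIC50 quartile starts for the
logistic, three pK~d~ offsets for saturation — accepts the lowest SSR,
and breaks ties by the smallest first parameter. Identical data and
start grid therefore give bit-identical results. Convergence uses
relative SSR and parameter tolerances of 10^−10^ (up to 500 iterations
per start); zero-noise simulated data are recovered to better than
10^−4^ on the log scale in all identifiable regimes, which the tests
assert.

Workflow conventions, chosen where the field's practice is the natural
default:

* pK~A~ of the radioligand is fixed in ternary-complex fits, taken from
  saturation fits of the same construct × ion condition; refitting it
  jointly is deliberately not the default, since the titration designs
  carry almost no information about it.
* Experiments are fitted individually and aggregated as mean ± SEM
  (`aggregate_replicates()`, n ≥ 2), not pooled into one global fit, so
  the reported SEM reflects between-experiment variability.
* Per-fit standard errors come from the inverse-Hessian approximation
  at the optimum and are reported for diagnostics; inference across
  conditions uses the across-experiment SEM.
* A fitted plateau is flagged as poorly identified when the titration
  top is below 10× the fitted K~B~.
* Matrix fits refuse data with fewer than two modulator levels, where
  the competitor cooperativity is structurally unidentifiable.

Model choice between pure competition (α = 0) and the allosteric model
uses the extra-sum-of-squares F test (`compare_models()`); the package
documents the F test as its selection criterion (information criteria
would be an alternative with no practical difference at these designs).
Because the null model sits on the boundary of the cooperativity
parameter space, the test is conservative under the null — its empirical
type-I rate over seeded competitive replicates runs at or below the
nominal 5%, which the acceptance suite checks alongside ≥95% power at a
strong-NAM effect size.

## Statistics and reporting

Between-condition comparisons mirror standard practice: one-way ANOVA
with Tukey's HSD over per-experiment estimates for multi-condition
contrasts (`anova_tukey()`), the classical equal-variance unpaired
t test for two-condition contrasts (`t_test_unpaired()`), both at 0.05.
Inference is performed on the pK / log α scale, not on K: log-scale
estimates are closer to normal across experiments and this is how such
parameters are universally compared; whether any particular published
table did its ANOVA on pK or K is rarely stated, so the log scale is the
package's documented choice.

Reporting helpers render the conventional table cells — pK to two
decimals, back-transformed K to two significant figures in a sensible
unit, `mean ± SEM (K)` — a condition-matrix layout with `"-"` for
missing cells (`report_table()`), and integer fold-change annotations.
Fold changes with `rounding = "display"` are computed from the
2-significant-figure K values and then rounded to the nearest integer,
reproducing how integer folds are quoted from rounded table entries; the
raw ratio is also available. The related `detection_limit_fold()` turns
"no effect detected up to c~max~" into the implied minimum fold loss of
affinity c~max~/K~ref~.

The pipeline drivers `run_simulate()`, `run_fit()`, `run_compare()` and
`run_report()` tie these stages together file-to-file and write a JSON
manifest (config, seed, package version, file checksums) so every
reported number is traceable; with a fixed config the outputs are
byte-reproducible. They are plain R functions taking a config list — the
package is used from R scripts, and these functions are its batch
interface.

## Problem sizes and numerical checks

The test and acceptance suites run entirely on simulated data at the
sizes the workflow targets: 3 experiments per condition; 10-point
two-arm saturation series; 12-point half-log titrations; 4-level × 13
point interaction matrices; 100 seeded replicates for power and
boundary type-I checks of the model comparison and 1000 small-sample
ANOVA replicates for null calibration. Worked-example arithmetic
(fold changes, antilog round-trips, Cheng–Prusoff conversions,
detection-limit bounds) is asserted at printed precision, recovery runs
at the tolerances appropriate to three experiments at 5% noise (±0.1 to
±0.15 log units), and oracle agreement at 1%.

## Known limitations

* Equilibrium only; no association/dissociation kinetics.
* One modulator site; no dimer or multi-site cooperativity models.
* The error model is i.i.d. multiplicative noise — fits use unweighted
  least squares, which is maximum-likelihood only under additive
  homoscedastic error; at CV ≤ 10% the difference is immaterial for
  these designs, but strongly heteroscedastic real data may warrant
  weighting.
* Identifiability degrades predictably at the edges: cooperativity and
  affinity trade off when the titration stops short of the plateau
  (flagged), and a NAM with very strong negative cooperativity at low
  radioligand occupancy is indistinguishable from a competitive ligand —
  raising the radioligand concentration, as the assay designs here do,
  is the remedy.
* The F test's boundary conservatism under the competitive null means
  "prefer the full model" decisions are, if anything, slightly
  under-called at the nominal level.
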