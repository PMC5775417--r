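# atcmfit

Quantitative analysis of radioligand binding at G protein-coupled
receptors when an allosteric modulator is in play. The package is written
for receptor pharmacologists who run saturation, competition and
interaction (modulator titration / competitor-by-modulator matrix) binding
assays and need to estimate modulator affinity and cooperativity by
nonlinear regression, compare parameters across receptor constructs and
ionic conditions, and simulate the same assay designs to validate the
whole workflow.

## Models

Concentrations are molar throughout; dissociation constants are carried as
pK = −log10 K and cooperativities as log10 α.

**Saturation** (total and nonspecific arms fitted jointly):

    Y = Bmax·[A] / ([A] + K_d)  +  ns·[A]

**Allosteric ternary complex model (ATCM)** for a radioligand A and
modulator B, on the percent-of-vehicle scale:

    Y = (A/K_A) / ( A/K_A + (1 + B/K_B) / (1 + α·B/K_B) )

α < 1 is negative cooperativity: the modulator partially displaces the
radioligand down to a plateau (A/K_A)/(A/K_A + 1/α) instead of to zero,
the signature that distinguishes a negative allosteric modulator (NAM)
from a competitive ligand. α = 0 is the pseudo-competitive boundary
(complete displacement).

**Extended three-ligand ATCM** for radioligand A, orthosteric competitor I
and modulator B, with separate cooperativities α (radioligand) and α′
(competitor):

    Y = Bmax·[A] / ( [A] + (K_A·K_B / (α[B] + K_B)) ·
          (1 + [I]/K_I + [B]/K_B + α′[I][B]/(K_I·K_B)) )

At B = 0 this reduces to classical one-site competition; at I = 0 it is
the ATCM. Competition curves are also summarised by the four-parameter
logistic (Hill) equation, with IC50 converted to K_i by Cheng–Prusoff:
K_i = IC50 / (1 + [A]/K_A).

Fitting is Levenberg–Marquardt least squares on the log-parameter scale
with a deterministic multi-start grid; replicate experiments are fitted
individually and aggregated as mean ± SEM; nested models (competitive vs
allosteric) are compared by the extra-sum-of-squares F test. An exact
mass-action equilibrium solver (no free-ligand approximation) is included
as an independent oracle for the closed forms. A seeded generator
simulates all assay designs with multiplicative noise, so every stage of
the pipeline can be verified end to end without any experimental data.

## Worked example

Simulate three interaction experiments for a high-cooperativity NAM
(generating K_B ≈ 30 nM, α = 0.01) titrated against 0.5 nM radioligand,
fit the ATCM per experiment with the radioligand pK_A fixed at 10.45, and
aggregate:

```r
library(atcmfit)

spec <- simulation_spec(
  design = "interaction_modulator",
  params = atcm_params(pKA = 10.45, pKB = 7.52, log_alpha_rad = -1.90,
                       Bmax = 237),
  radioligand_conc = 0.5e-9,
  titration = list(top = 30e-6, factor = 10^0.5, n = 12),
  n_experiments = 3, noise_cv = 0.05, seed = 20)
ds <- simulate_interaction_experiment(spec)

res <- fit_experiments(ds, fit_atcm, pKA = 10.45)
print(res$fits[["1"]])
#> Fit result (allosteric ternary complex): converged, SSR 433.6 on 13 obs
#>               estimate std_error
#> pKB              7.669   0.09646
#> log_alpha_rad   -1.874   0.12200
#>   fixed: pKA = 10.45

print(res$aggregates$pKB)
#> pKB = 7.629 +/- 0.028 (mean +/- SEM, n = 3)
print(res$aggregates$log_alpha_rad)
#> log_alpha_rad = -1.901 +/- 0.017 (mean +/- SEM, n = 3)
```

The aggregate pKB of 7.63 ± 0.03 corresponds to K_B ≈ 23 nM
(`format_estimate_cell(7.629, 0.028, unit = "nM")` renders the
table-style cell `"7.63 ± 0.03 (23)"`), recovering the generating value of
30 nM within the scatter expected from three experiments at 5% noise; the
aggregate log α of −1.90 ± 0.02 recovers the generating cooperativity
exactly to two decimals. The extra-sum-of-squares test confirms the data
could not be explained by simple competition:

```r
compare_models(fit_atcm(ds, pKA = 10.45, model = "competitive"),
               res$fits[["1"]])
#> Extra-sum-of-squares F(1, 11) = 15.451, p = 0.002349 -> full model
```

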