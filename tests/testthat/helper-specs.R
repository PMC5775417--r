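# shared builders for simulated assay regimes (all concentrations molar)

spiperone_pKA <- 10.45

# wild-type/NaCl saturation regime: Kd 0.0355 nM (pKd 10.45), Bmax 237,
# nonspecific ~2% of Bmax at the top of the series
wt_saturation_spec <- function(seed, n_experiments = 3, noise_cv = 0.05,
                               ns_slope = 1e10) {
  simulation_spec(
    design = "saturation",
    params = saturation_params(pKd = 10.45, Bmax = 237, ns_slope = ns_slope),
    titration = list(top = 2e-9, factor = 1.945, n = 10L),
    n_experiments = n_experiments, noise_cv = noise_cv, seed = seed)
}

# high-negative-cooperativity modulator regime at 0.5 nM radioligand
# (pKB 7.52, log alpha -1.90)
mips1726_spec <- function(seed, n_experiments = 3, noise_cv = 0.05) {
  simulation_spec(
    design = "interaction_modulator",
    params = atcm_params(pKA = spiperone_pKA, pKB = 7.52,
                         log_alpha_rad = -1.90, Bmax = 237),
    radioligand_conc = 0.5e-9,
    titration = list(top = 30e-6, factor = 10^0.5, n = 12L),
    n_experiments = n_experiments, noise_cv = noise_cv, seed = seed)
}

# moderate-cooperativity modulator regime at 0.15 nM radioligand
# (pKB 7.00, log alpha -1.45)
mips1868_spec <- function(seed, n_experiments = 3, noise_cv = 0.05) {
  simulation_spec(
    design = "interaction_modulator",
    params = atcm_params(pKA = spiperone_pKA, pKB = 7.00,
                         log_alpha_rad = -1.45, Bmax = 237),
    radioligand_conc = 0.15e-9,
    titration = list(top = 30e-6, factor = 10^0.5, n = 12L),
    n_experiments = n_experiments, noise_cv = noise_cv, seed = seed)
}

# weak NAM interaction matrix: KB 355 nM, cooperativity 0.35 with the
# radioligand and 0.29 with dopamine (pKI 5.59); dopamine titrated
# 1 nM - 1 mM at four fixed modulator concentrations
sb_matrix_spec <- function(seed, n_experiments = 3, noise_cv = 0.05) {
  simulation_spec(
    design = "interaction_dopamine_matrix",
    params = atcm_params(pKA = spiperone_pKA, pKB = k_to_pk(355e-9),
                         pKI = 5.59, log_alpha_rad = log10(0.35),
                         log_alpha_comp = log10(0.29), Bmax = 237),
    radioligand_conc = 0.15e-9,
    titration = list(top = 1e-3, factor = 10^0.5, n = 12L),
    modulator_concs = c(0, 1e-6, 3e-6, 10e-6),
    n_experiments = n_experiments, noise_cv = noise_cv, seed = seed)
}

# orthosteric competitor regime (pKi 5.90) at 0.15 nM radioligand
mips1071_spec <- function(seed, n_experiments = 3, noise_cv = 0.05,
                          pKI = 5.90) {
  simulation_spec(
    design = "competition",
    params = atcm_params(pKA = spiperone_pKA, pKB = 5, pKI = pKI,
                         Bmax = 237),
    radioligand_conc = 0.15e-9,
    titration = list(top = 100e-6, factor = 10^0.5, n = 12L),
    n_experiments = n_experiments, noise_cv = noise_cv, seed = seed)
}

# competitive (complete displacement) modulator data for null calibration
competitive_spec <- function(seed, pKB = 7.52, n_experiments = 1,
                             noise_cv = 0.05) {
  simulation_spec(
    design = "interaction_modulator",
    params = atcm_params(pKA = spiperone_pKA, pKB = pKB,
                         log_alpha_rad = -Inf, Bmax = 237),
    radioligand_conc = 0.5e-9,
    titration = list(top = 30e-6, factor = 10^0.5, n = 12L),
    n_experiments = n_experiments, noise_cv = noise_cv, seed = seed)
}
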