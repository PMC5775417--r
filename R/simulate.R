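#' Specification of a synthetic binding experiment
#'
#' Describes one of the standard radioligand assay designs so it can be
#' simulated reproducibly:
#' \describe{
#'   \item{saturation}{radioligand titration with paired total and
#'     nonspecific arms (nonspecific defined by a saturating unlabelled
#'     competitor)}
#'   \item{competition}{titration of an orthosteric competitor I at fixed
#'     radioligand concentration}
#'   \item{interaction_modulator}{titration of an allosteric modulator B at
#'     fixed radioligand concentration}
#'   \item{interaction_dopamine_matrix}{competitor titrations at each of
#'     several fixed modulator concentrations, sharing one radioligand
#'     concentration (the design that identifies both cooperativities)}
#' }
#'
#' Noise is multiplicative Gaussian with coefficient of variation
#' `noise_cv`, truncated at zero — the error structure of scintillation
#' counting, and scale-free on the % control scale. The default replicate
#' count is 3 individual experiments, the field's standard; the seed is
#' mandatory so every simulated dataset is reproducible.
#'
#' @param design assay design, see above.
#' @param params generating parameters: a [saturation_params()] for the
#'   saturation design, an [atcm_params()] otherwise.
#' @param radioligand_conc fixed radioligand concentration, molar
#'   (typically 0.15e-9 or 0.5e-9; unused for the saturation design).
#' @param titration list with `top` (molar), `factor` (dilution factor
#'   > 1) and `n` (number of nonzero points >= 4); a zero/vehicle point is
#'   always appended. Defaults: modulator/competitor 30 uM down in half-log
#'   steps over 12 points; saturation 2 nM down by factor 1.9 over 10
#'   points.
#' @param modulator_concs for the matrix design, the fixed modulator
#'   concentrations (molar, typically including 0).
#' @param n_experiments number of independent experiments.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed; required.
#' @param construct,ion condition labels carried into the dataset.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(design = c("saturation", "competition",
                                       "interaction_modulator",
                                       "interaction_dopamine_matrix"),
                            params,
                            radioligand_conc = 0.15e-9,
                            titration = NULL,
                            modulator_concs = NULL,
                            n_experiments = 3,
                            noise_cv = 0.05,
                            seed,
                            construct = "WT", ion = "NaCl") {
  design <- match.arg(design)
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("'seed' is mandatory for simulation specs", call. = FALSE)
  seed <- as.integer(seed)
  if (design == "saturation") {
    stopifnot(inherits(params, "saturation_params"))
  } else {
    stopifnot(inherits(params, "atcm_params"))
  }
  if (is.null(titration)) {
    titration <- if (design == "saturation") {
      list(top = 2e-9, factor = 1.9, n = 10L)
    } else {
      list(top = 30e-6, factor = 10^0.5, n = 12L)
    }
  }
  stopifnot(is.list(titration),
            all(c("top", "factor", "n") %in% names(titration)))
  if (titration$n < 4)
    stop("titrations need at least 4 points", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  if (n_experiments < 1) stop("'n_experiments' must be >= 1", call. = FALSE)
  if (design == "interaction_dopamine_matrix") {
    if (is.null(modulator_concs))
      modulator_concs <- c(0, 1e-6, 3e-6, 10e-6)
    check_conc(modulator_concs, "modulator_concs")
  }
  structure(
    list(design = design, params = params,
         radioligand_conc = radioligand_conc, titration = titration,
         modulator_concs = modulator_concs,
         n_experiments = as.integer(n_experiments),
         noise_cv = noise_cv, seed = seed,
         construct = construct, ion = ion),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("Simulation spec: %s design, %d experiment(s), noise CV %.0f%%, seed %d\n",
              x$design, x$n_experiments, 100 * x$noise_cv, x$seed))
  invisible(x)
}

#' Geometric dilution series
#'
#' Descending geometric series from `top` with the given dilution factor,
#' plus an explicit zero (vehicle) point, as prepared on a dilution plate.
#'
#' @param top highest concentration, molar, > 0.
#' @param factor dilution factor between adjacent points, > 1.
#' @param n number of nonzero points, >= 2.
#' @return Numeric vector of length `n + 1`, descending, ending in 0.
#' @examples
#' make_dilution_series(30e-6, 10^0.5, 12)  # half-log series down from 30 uM
#' @export
make_dilution_series <- function(top, factor, n) {
  if (!is.numeric(top) || top <= 0) stop("'top' must be > 0", call. = FALSE)
  if (!is.numeric(factor) || factor <= 1)
    stop("'factor' must be > 1", call. = FALSE)
  if (!is.numeric(n) || n < 2) stop("'n' must be >= 2", call. = FALSE)
  c(top / factor^(seq_len(n) - 1), 0)
}

# per-experiment substream seed: distinct experiments get distinct,
# reproducible noise streams from the one spec seed
experiment_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * i) %% 2147483647)
}

apply_noise <- function(mu, cv) {
  if (cv == 0) return(mu)
  pmax(0, mu * stats::rnorm(length(mu), mean = 1, sd = cv))
}

#' Simulate a saturation binding experiment
#'
#' Paired total and nonspecific arms over the radioligand series. The
#' noiseless total-arm mean is [saturation_binding()] with the nonspecific
#' component; the nonspecific arm is the linear component alone.
#'
#' @param spec a [simulation_spec()] with `design = "saturation"`.
#' @return A [binding_dataset()] with responses in fmol/mg.
#' @export
simulate_saturation_experiment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$design != "saturation")
    stop("spec design must be 'saturation'", call. = FALSE)
  p <- spec$params
  A <- make_dilution_series(spec$titration$top, spec$titration$factor,
                            spec$titration$n)
  A <- A[A > 0]  # a zero-radioligand well carries no signal in either arm
  rows <- list()
  for (e in seq_len(spec$n_experiments)) {
    set.seed(experiment_seed(spec$seed, e))
    total <- apply_noise(saturation_binding(A, p, include_ns = TRUE),
                         spec$noise_cv)
    ns <- apply_noise(p$ns_slope * A, spec$noise_cv)
    rows[[e]] <- data.frame(
      experiment_id = e,
      construct = spec$construct, ion = spec$ion,
      conc_radioligand_M = c(A, A),
      conc_competitor_M = 0,
      conc_modulator_M = 0,
      response = c(total, ns),
      response_units = "fmol/mg",
      is_nonspecific = rep(c(FALSE, TRUE), each = length(A))
    )
  }
  binding_dataset(do.call(rbind, rows), design = "saturation")
}

#' Simulate a competition or interaction binding experiment
#'
#' Titration designs at fixed radioligand concentration, with the noiseless
#' mean given by [extended_atcm_binding()]:
#' * `competition`: competitor I series, no modulator;
#' * `interaction_modulator`: modulator B series, no competitor;
#' * `interaction_dopamine_matrix`: competitor series repeated at each
#'   fixed modulator concentration.
#' Each experiment includes its vehicle well (the zero point of the
#' series), so [normalize_dataset()] can convert to % control.
#'
#' @param spec a [simulation_spec()] with a non-saturation design.
#' @return A [binding_dataset()] with responses in fmol/mg.
#' @export
simulate_interaction_experiment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$design == "saturation")
    stop("use simulate_saturation_experiment() for the saturation design",
         call. = FALSE)
  p <- spec$params
  A <- spec$radioligand_conc
  series <- make_dilution_series(spec$titration$top, spec$titration$factor,
                                 spec$titration$n)
  grid <- switch(spec$design,
    competition = data.frame(I = series, B = 0),
    interaction_modulator = data.frame(I = 0, B = series),
    # each curve keeps its own I = 0 well; the B = 0 curve's is the vehicle
    interaction_dopamine_matrix = expand.grid(I = series,
                                              B = spec$modulator_concs))
  mu <- extended_atcm_binding(A, grid$B, grid$I, p)
  rows <- list()
  for (e in seq_len(spec$n_experiments)) {
    set.seed(experiment_seed(spec$seed, e))
    rows[[e]] <- data.frame(
      experiment_id = e,
      construct = spec$construct, ion = spec$ion,
      conc_radioligand_M = A,
      conc_competitor_M = grid$I,
      conc_modulator_M = grid$B,
      response = apply_noise(mu, spec$noise_cv),
      response_units = "fmol/mg",
      is_nonspecific = FALSE
    )
  }
  binding_dataset(do.call(rbind, rows), design = spec$design)
}

#' Reference parameter regimes for the D2L receptor system
#'
#' Literature parameter estimates (log scale, with the K value they imply)
#' for [3H]spiperone, dopamine and a series of negative allosteric
#' modulators / orthosteric fragments at wild-type and mutant (D80A, E95A)
#' human D2L receptors, in sodium-containing (NaCl) and sodium-free (NMDG)
#' buffer. These are the regimes the synthetic-data generator reproduces:
#' `pK` is pKd for the radioligand, pKi for competitive ligands and pKB for
#' modulators; `log_alpha_rad` is the modulator/[3H]spiperone cooperativity
#' (NA where not applicable or not determined), `Bmax` in fmol/mg, and
#' `radioligand_conc_M` the assay radioligand concentration. `NA` in `pK`
#' marks conditions where no inhibition was detected or no experiment was
#' performed.
#'
#' @return A data.frame, one row per ligand x construct x ion condition.
#' @export
binding_regimes <- function() {
  rg <- rbind(
    data.frame(ligand = "spiperone",
               construct = rep(c("WT", "D80A", "E95A"), each = 2),
               ion = rep(c("NaCl", "NMDG"), 3),
               role = "radioligand",
               pK = c(10.45, 10.31, 9.94, 10.24, 10.21, 10.10),
               pK_sem = c(0.06, 0.12, 0.11, 0.14, 0.09, 0.03),
               log_alpha_rad = NA_real_, log_alpha_rad_sem = NA_real_,
               Bmax = c(237.0, 216.1, 215.4, 192.4, 225.5, 196.6),
               radioligand_conc_M = NA_real_),
    data.frame(ligand = "dopamine",
               construct = rep(c("WT", "D80A", "E95A"), each = 2),
               ion = rep(c("NaCl", "NMDG"), 3),
               role = "competitor",
               pK = c(5.59, 5.29, 5.58, 5.14, 5.50, 5.34),
               pK_sem = c(0.06, 0.16, 0.06, 0.16, 0.06, 0.09),
               log_alpha_rad = NA_real_, log_alpha_rad_sem = NA_real_,
               Bmax = NA_real_, radioligand_conc_M = 0.15e-9),
    data.frame(ligand = "MIPS1071",
               construct = rep(c("WT", "D80A", "E95A"), each = 2),
               ion = rep(c("NaCl", "NMDG"), 3),
               role = "competitor",
               pK = c(5.90, 4.92, 5.03, 5.14, 5.90, 5.12),
               pK_sem = c(0.07, 0.07, 0.07, 0.06, 0.09, 0.23),
               log_alpha_rad = NA_real_, log_alpha_rad_sem = NA_real_,
               Bmax = NA_real_, radioligand_conc_M = 0.15e-9),
    data.frame(ligand = "MIPS1059",
               construct = rep(c("WT", "D80A", "E95A"), each = 2),
               ion = rep(c("NaCl", "NMDG"), 3),
               role = "competitor",
               pK = c(6.56, 5.76, 5.82, 5.83, 5.94, 5.32),
               pK_sem = c(0.06, 0.07, 0.07, 0.07, 0.07, 0.10),
               log_alpha_rad = NA_real_, log_alpha_rad_sem = NA_real_,
               Bmax = NA_real_, radioligand_conc_M = 0.15e-9),
    data.frame(ligand = "SB269652",
               construct = rep(c("WT", "D80A", "E95A"), each = 2),
               ion = rep(c("NaCl", "NMDG"), 3),
               role = "modulator",
               pK = c(6.45, NA, NA, NA, 5.65, NA),
               pK_sem = c(0.09, NA, NA, NA, 0.10, NA),
               log_alpha_rad = c(-0.48, NA, NA, NA, -0.25, NA),
               log_alpha_rad_sem = c(0.08, NA, NA, NA, 0.06, NA),
               Bmax = NA_real_, radioligand_conc_M = 0.15e-9),
    data.frame(ligand = "MIPS1726",
               construct = rep(c("WT", "D80A", "E95A"), each = 2),
               ion = rep(c("NaCl", "NMDG"), 3),
               role = "modulator",
               pK = c(7.52, 6.40, 6.50, NA, 6.91, 6.09),
               pK_sem = c(0.05, 0.06, 0.06, NA, 0.06, 0.08),
               log_alpha_rad = c(-1.90, -2.26, -2.13, NA, -1.91, -1.89),
               log_alpha_rad_sem = c(0.08, 0.39, 0.27, NA, 0.12, 0.31),
               Bmax = NA_real_, radioligand_conc_M = 0.5e-9),
    data.frame(ligand = "MIPS1868",
               construct = rep(c("WT", "D80A", "E95A"), each = 2),
               ion = rep(c("NaCl", "NMDG"), 3),
               role = "modulator",
               pK = c(7.00, 6.20, 6.20, 6.33, 6.67, 6.21),
               pK_sem = c(0.07, 0.08, 0.10, 0.09, 0.03, 0.12),
               log_alpha_rad = c(-1.45, -1.48, -0.62, -0.87, -1.39, -1.24),
               log_alpha_rad_sem = c(0.12, 0.12, 0.06, 0.12, 0.11, 0.16),
               Bmax = NA_real_, radioligand_conc_M = 0.15e-9)
  )
  rg$K_M <- pk_to_k(rg$pK)
  rownames(rg) <- NULL
  rg
}

#' Look up one reference regime
#'
#' Convenience accessor over [binding_regimes()].
#'
#' @param ligand,construct,ion condition selectors.
#' @return The single matching row as a list.
#' @export
regime <- function(ligand, construct = "WT", ion = "NaCl") {
  rg <- binding_regimes()
  row <- rg[rg$ligand == ligand & rg$construct == construct & rg$ion == ion, ]
  if (nrow(row) != 1L)
    stop("no unique regime for ", ligand, "/", construct, "/", ion,
         call. = FALSE)
  as.list(row)
}
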