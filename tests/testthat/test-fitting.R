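test_that("saturation fit recovers generating parameters", {
  # noiseless: essentially exact recovery
  ds0 <- simulate_saturation_experiment(wt_saturation_spec(1, 1, 0))
  f0 <- fit_saturation(ds0)
  expect_true(f0$converged)
  expect_equal(f0$estimates$pKd, 10.45, tolerance = 1e-6)
  expect_equal(f0$estimates$Bmax, 237, tolerance = 1e-6)
  expect_equal(f0$estimates$ns_slope, 1e10, tolerance = 1e-6)
  # 5% noise, 3 experiments: aggregate pKd lands near truth
  ds <- simulate_saturation_experiment(wt_saturation_spec(101))
  r <- fit_experiments(ds, fit_saturation, params = c("pKd", "Bmax"))
  expect_lt(abs(r$aggregates$pKd$mean - 10.45), 0.1)
  expect_lt(abs(r$aggregates$Bmax$mean - 237) / 237, 0.1)
  # a dataset without the nonspecific arm refuses
  only_total <- binding_dataset(as.data.frame(ds)[!ds$is_nonspecific, ],
                                design = "saturation")
  expect_error(fit_saturation(only_total), "nonspecific")
})

test_that("logistic fit recovers a clean competition curve exactly", {
  spec <- mips1071_spec(1, 1, 0)
  ds <- simulate_interaction_experiment(spec)
  f <- fit_hill(ds)
  # classical competition is exactly logistic with unit Hill slope
  expect_equal(f$estimates$nH, 1, tolerance = 1e-5)
  expect_equal(f$estimates$top, 100, tolerance = 1e-5)
  expect_equal(f$estimates$bottom, 0, tolerance = 1e-4)
  expect_equal(10^f$estimates$logIC50,
               pk_to_k(5.90) * (1 + 0.15e-9 / pk_to_k(10.45)),
               tolerance = 1e-5)
})

test_that("competition fit plus Cheng-Prusoff recovers the competitor pKi", {
  ds <- simulate_interaction_experiment(mips1071_spec(202))
  pkis <- vapply(1:3, function(e) {
    f <- fit_hill(ds, fixed = c(bottom = 0), experiment = e)
    k_to_pk(cheng_prusoff_ki(10^f$estimates$logIC50, 0.15e-9, 10.45))
  }, numeric(1))
  expect_lt(abs(mean(pkis) - 5.90), 0.1)
})

test_that("assuming complete displacement raises the apparent IC50", {
  # partial-displacement (allosteric) data: floor well above zero
  ds <- normalize_dataset(
    simulate_interaction_experiment(mips1868_spec(7, 1, 0.02)))
  free_fit <- fit_hill(ds, ligand = "modulator")
  forced <- fit_hill(ds, fixed = c(bottom = 0), ligand = "modulator")
  expect_gt(free_fit$estimates$bottom, 5)
  expect_gt(forced$estimates$logIC50, free_fit$estimates$logIC50)
})

test_that("degenerate logistic inputs are refused", {
  ds <- simulate_interaction_experiment(mips1071_spec(1, 1, 0))
  flat <- as.data.frame(ds)
  flat$response <- 100
  flat <- binding_dataset(flat, design = "competition")
  expect_error(fit_hill(flat), "identical")
})

test_that("ternary-complex fit identifies affinity and cooperativity", {
  # noiseless: recovery to the optimizer's precision
  ds0 <- simulate_interaction_experiment(mips1726_spec(1, 1, 0))
  f0 <- fit_atcm(ds0, pKA = 10.45)
  expect_equal(f0$estimates$pKB, 7.52, tolerance = 1e-4)
  expect_equal(f0$estimates$log_alpha_rad, -1.90, tolerance = 1e-4)
  expect_true(f0$converged)
  # 5% noise, 3 experiments
  ds <- simulate_interaction_experiment(mips1726_spec(303))
  r <- fit_experiments(ds, fit_atcm, pKA = 10.45)
  expect_lt(abs(r$aggregates$pKB$mean - 7.52), 0.15)
  expect_lt(abs(r$aggregates$log_alpha_rad$mean + 1.90), 0.15)
})

test_that("neutral-cooperativity data yield a flat fitted curve", {
  spec <- simulation_spec(
    "interaction_modulator",
    params = atcm_params(pKA = 10.45, pKB = 6.5, log_alpha_rad = 0,
                         Bmax = 237),
    radioligand_conc = 0.15e-9, n_experiments = 1, noise_cv = 0.02,
    seed = 31)
  ds <- simulate_interaction_experiment(spec)
  f <- fit_atcm(ds, pKA = 10.45)
  # whatever (KB, alpha) pair the fit lands on, it must predict no
  # modulation across the tested range
  r <- 0.15e-9 / pk_to_k(10.45)
  b <- ds$conc_modulator_M / pk_to_k(f$estimates$pKB)
  alpha <- 10^f$estimates$log_alpha_rad
  pred <- 100 * (r + 1) / (r + (1 + b) / (1 + alpha * b))
  expect_true(all(abs(pred - 100) < 3))
})

test_that("short titrations flag a poorly identified plateau", {
  spec <- simulation_spec(
    "interaction_modulator",
    params = atcm_params(pKA = 10.45, pKB = 5.0, log_alpha_rad = -1.5,
                         Bmax = 237),
    radioligand_conc = 0.15e-9,
    titration = list(top = 3e-6, factor = 10^0.5, n = 8L),
    n_experiments = 1, noise_cv = 0, seed = 5)
  f <- fit_atcm(simulate_interaction_experiment(spec), pKA = 10.45)
  expect_match(f$flags, "plateau", all = FALSE)
})

test_that("global matrix fit recovers all shared parameters", {
  ds0 <- simulate_interaction_experiment(sb_matrix_spec(1, 1, 0))
  f0 <- fit_extended_atcm(ds0, pKA = 10.45)
  expect_equal(f0$estimates$pKB, k_to_pk(355e-9), tolerance = 1e-4)
  expect_equal(f0$estimates$pKI, 5.59, tolerance = 1e-4)
  expect_equal(f0$estimates$log_alpha_rad, log10(0.35), tolerance = 1e-4)
  expect_equal(f0$estimates$log_alpha_comp, log10(0.29), tolerance = 1e-4)
  expect_equal(f0$estimates$Bmax, 237, tolerance = 1e-4)
  # 5% noise, 3 experiments: competitor cooperativity near log10(0.29)
  ds <- simulate_interaction_experiment(sb_matrix_spec(404))
  r <- fit_experiments(ds, fit_extended_atcm, pKA = 10.45,
                       params = c("pKB", "log_alpha_comp"))
  expect_lt(abs(r$aggregates$log_alpha_comp$mean + 0.54), 0.15)
  expect_lt(abs(r$aggregates$pKB$mean - k_to_pk(355e-9)), 0.15)
})

test_that("matrices without modulator variation are refused", {
  spec <- sb_matrix_spec(2, 1, 0)
  ds <- simulate_interaction_experiment(spec)
  b0only <- binding_dataset(as.data.frame(ds)[ds$conc_modulator_M == 0, ],
                            design = "interaction_dopamine_matrix")
  expect_error(fit_extended_atcm(b0only, pKA = 10.45), "unidentifiable")
})

test_that("fits are invariant to a joint concentration/pK-grid rescaling", {
  spec <- mips1726_spec(55, 1, 0.03)
  ds <- simulate_interaction_experiment(spec)
  f <- fit_atcm(ds, pKA = 10.45)
  scaled <- as.data.frame(ds)
  scaled$conc_radioligand_M <- scaled$conc_radioligand_M * 10
  scaled$conc_modulator_M <- scaled$conc_modulator_M * 10
  f_scaled <- fit_atcm(binding_dataset(scaled, "interaction_modulator"),
                       pKA = 10.45 - 1)
  expect_equal(f_scaled$estimates$pKB, f$estimates$pKB - 1,
               tolerance = 1e-6)
  expect_equal(f_scaled$estimates$log_alpha_rad, f$estimates$log_alpha_rad,
               tolerance = 1e-6)
})

test_that("multi-start fitting is deterministic", {
  ds <- simulate_interaction_experiment(mips1726_spec(66, 1))
  f1 <- fit_atcm(ds, pKA = 10.45)
  f2 <- fit_atcm(ds, pKA = 10.45)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$ssr, f2$ssr)
  expect_equal(f1$n_starts_used, 9)
})

# a copy of a fit posing as a fuller model with one more (useless) free
# parameter and the same SSR, for the F = 0 edge case
full_with_extra_df <- function(f) {
  g <- unclass(f)
  g$estimates <- c(g$estimates, list(dummy = 0))
  g$n_free <- g$n_free + 1
  g$df_residual <- g$n_obs - g$n_free
  class(g) <- "fit_result"
  g
}

test_that("nested-model comparison behaves at its extremes", {
  ds <- simulate_interaction_experiment(mips1726_spec(77, 1))
  full <- fit_atcm(ds, pKA = 10.45)
  restricted <- fit_atcm(ds, pKA = 10.45, model = "competitive")
  cmp <- compare_models(restricted, full)
  expect_gt(cmp$F, 0)
  expect_lt(cmp$p_value, 0.05)   # strongly allosteric data
  # identical fits: F = 0, p = 1
  same <- compare_models(full, full_with_extra_df(full))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)
  # mismatched data refused
  other <- fit_atcm(simulate_interaction_experiment(mips1726_spec(78, 1)),
                    pKA = 10.45)
  expect_error(compare_models(restricted, other), "identical data")
  expect_error(compare_models(full, restricted), "fewer free parameters")
})

test_that("replicate aggregation reports mean and SEM on the log scale", {
  fits <- lapply(c(7.4, 7.5, 7.6), function(v) {
    fit_result(list(pKB = v), list(pKB = 0.1), ssr = 1, n_obs = 10,
               converged = TRUE, n_starts_used = 9)
  })
  agg <- aggregate_replicates(fits, "pKB")
  expect_equal(agg$mean, 7.5)
  expect_equal(agg$sem, 0.1 / sqrt(3), tolerance = 1e-10)
  expect_equal(agg$n, 3)
  identical_fits <- fits[c(1, 1)]
  expect_equal(aggregate_replicates(identical_fits, "pKB")$sem, 0)
  expect_error(aggregate_replicates(fits[1], "pKB"), ">= 2")
  bad <- fits
  bad[[2]]$converged <- FALSE
  expect_error(aggregate_replicates(bad, "pKB"), "converged")
})

test_that("estimator bias shrinks with the noise level", {
  bias_at_cv <- vapply(c(0.10, 0.02), function(cv) {
    ests <- vapply(1:6, function(s) {
      ds <- simulate_interaction_experiment(mips1726_spec(900 + s, 1, cv))
      fit_atcm(ds, pKA = 10.45)$estimates$pKB
    }, numeric(1))
    abs(mean(ests) - 7.52)
  }, numeric(1))
  expect_lt(bias_at_cv[2], bias_at_cv[1] + 0.02)
  expect_lt(bias_at_cv[2], 0.05)
})
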