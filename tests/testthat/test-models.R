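pKA_04 <- k_to_pk(0.04e-9)  # Kd 0.04 nM radioligand

test_that("saturation binding follows the rectangular hyperbola", {
  p <- saturation_params(pKd = pKA_04, Bmax = 237)
  expect_equal(saturation_binding(0.04e-9, p), 237 / 2)        # A = Kd
  expect_equal(saturation_binding(0, p), 0)
  expect_equal(saturation_binding(0.15e-9, p), 237 * 0.15 / 0.19,
               tolerance = 1e-12)
  # nonspecific component is linear and additive
  pns <- saturation_params(pKd = pKA_04, Bmax = 237, ns_slope = 1e10)
  expect_equal(saturation_binding(0.15e-9, pns, include_ns = TRUE),
               237 * 0.15 / 0.19 + 1e10 * 0.15e-9)
  # monotone nondecreasing in A
  A <- sort(10^seq(-12, -8, length.out = 40))
  expect_true(all(diff(saturation_binding(A, pns, include_ns = TRUE)) >= 0))
  expect_error(saturation_binding(-1e-9, p), "non-negative")
})

test_that("ternary-complex occupancy matches hand arithmetic and limits", {
  expect_equal(atcm_occupancy(0.15e-9, 0, pKA_04, 6.45, -0.45), 15 / 19,
               tolerance = 1e-12)
  expect_equal(atcm_occupancy(0, 1e-6, pKA_04, 6.45, -0.45), 0)
  # neutral cooperativity: modulator has no effect
  B <- 10^seq(-10, -4, length.out = 13)
  expect_equal(atcm_occupancy(0.15e-9, B, pKA_04, 6.45, 0),
               rep(15 / 19, length(B)), tolerance = 1e-12)
  # KB 355 nM, alpha 0.35, B 1 mM
  expect_equal(atcm_occupancy(0.15e-9, 1e-3, pKA_04, k_to_pk(355e-9),
                              log10(0.35)),
               0.5677, tolerance = 1e-4)
})

test_that("plateau equals the saturating-modulator limit of occupancy", {
  expect_equal(atcm_plateau(0.15e-9, pKA_04, log10(0.35)),
               3.75 / (3.75 + 1 / 0.35), tolerance = 1e-12)
  expect_equal(atcm_plateau(0.15e-9, pKA_04, -Inf), 0)
  pKB <- 6.45
  occ_far <- atcm_occupancy(0.15e-9, 1e5 * pk_to_k(pKB), pKA_04, pKB,
                            log10(0.35))
  expect_equal(occ_far, atcm_plateau(0.15e-9, pKA_04, log10(0.35)),
               tolerance = 1e-2)
})

test_that("extended model reduces to its nested special cases", {
  p <- atcm_params(pKA = pKA_04, pKB = k_to_pk(355e-9), pKI = 5.59,
                   log_alpha_rad = log10(0.35),
                   log_alpha_comp = log10(0.29), Bmax = 237)
  expect_equal(extended_atcm_binding(0.15e-9, 0, 0, p), 237 * 0.15 / 0.19,
               tolerance = 1e-12)
  expect_equal(extended_atcm_binding(0.15e-9, 0, pk_to_k(5.59), p),
               237 * 0.15 / 0.23, tolerance = 1e-12)
  # B = 0: classical one-site competition across an (A, I) grid
  grid <- expand.grid(A = 10^seq(-11, -8.5, length.out = 6),
                      I = c(0, 10^seq(-8, -4, length.out = 5)))
  got <- extended_atcm_binding(grid$A, 0, grid$I, p)
  KA <- pk_to_k(p$pKA); KI <- pk_to_k(p$pKI)
  classical <- 237 * grid$A / (grid$A + KA * (1 + grid$I / KI))
  expect_equal(got, classical, tolerance = 1e-12)
  # I = 0: equals Bmax * two-ligand occupancy across an (A, B) grid
  grid2 <- expand.grid(A = 10^seq(-11, -8.5, length.out = 6),
                       B = c(0, 10^seq(-9, -4, length.out = 5)))
  expect_equal(extended_atcm_binding(grid2$A, grid2$B, 0, p),
               237 * atcm_occupancy(grid2$A, grid2$B, p$pKA, p$pKB,
                                    p$log_alpha_rad),
               tolerance = 1e-12)
  # saturating B at I = 0 approaches Bmax * plateau
  expect_equal(extended_atcm_binding(0.15e-9, 1e5 * pk_to_k(p$pKB), 0, p),
               237 * atcm_plateau(0.15e-9, p$pKA, p$log_alpha_rad),
               tolerance = 1e-2 * 237)
})

test_that("occupancy is monotone in modulator with direction set by alpha", {
  B <- 10^seq(-10, -3, length.out = 30)
  dec <- atcm_occupancy(0.15e-9, B, pKA_04, 6.45, -1)
  inc <- atcm_occupancy(0.15e-9, B, pKA_04, 6.45, 0.8)
  expect_true(all(diff(dec) < 0))
  expect_true(all(diff(inc) > 0))
})

test_that("logistic curve midpoint and slope behave as defined", {
  p <- hill_params(top = 100, bottom = 0, logIC50 = -6, nH = 1)
  expect_equal(hill_curve(-6, p), 50)
  expect_equal(hill_curve(-7, p), 100 / 1.1, tolerance = 1e-12)
  p2 <- hill_params(top = 100, bottom = 0, logIC50 = -6, nH = 2)
  expect_equal(hill_curve(-5.5, p2), 100 / 11, tolerance = 1e-12)
  # zero concentration (x = -Inf) pins the top asymptote
  expect_equal(hill_curve(-Inf, p), 100)
  # midway property holds for arbitrary asymptotes
  p3 <- hill_params(top = 96, bottom = 14, logIC50 = -7.3, nH = 0.8)
  expect_equal(hill_curve(-7.3, p3), (96 + 14) / 2)
})

test_that("Cheng-Prusoff conversion and pK transforms are exact", {
  expect_equal(cheng_prusoff_ki(1e-6, 0, pKA_04), 1e-6)
  expect_equal(cheng_prusoff_ki(1e-6, 0.15e-9, pKA_04), 1e-6 / 4.75,
               tolerance = 1e-12)
  expect_equal(cheng_prusoff_ki(4.75e-9, 0.15e-9, pKA_04), 1e-9,
               tolerance = 1e-12)
  expect_equal(pk_to_k(0), 1)
  expect_equal(pk_to_k(10.45) * 1e9, 0.0355, tolerance = 1e-3)
  expect_equal(pk_to_k(5.59) * 1e6, 2.57, tolerance = 1e-3)
  # round trip to 12 digits over the full pK range
  pks <- seq(3, 13, by = 0.25)
  expect_equal(k_to_pk(pk_to_k(pks)), pks, tolerance = 1e-12)
  expect_error(k_to_pk(0), "positive")
  expect_error(k_to_pk(-1), "positive")
})

test_that("normalization to vehicle rescales to percent control", {
  expect_equal(normalize_to_vehicle(5, 5), 100)
  expect_equal(normalize_to_vehicle(0, 5), 0)
  plateau <- atcm_plateau(0.15e-9, pKA_04, log10(0.35))
  veh <- atcm_occupancy(0.15e-9, 0, pKA_04, 6.45, log10(0.35))
  expect_equal(normalize_to_vehicle(plateau, veh), 71.9, tolerance = 1e-3)
  expect_error(normalize_to_vehicle(1, 0), "positive")
})

test_that("fold changes reproduce the rounded-table convention", {
  expect_equal(fold_change(1.3e-6, 12e-6, rounding = "display"), 9)
  expect_equal(fold_change(1.3e-6, 9.3e-6, rounding = "display"), 7)
  expect_equal(fold_change(2e-6, 2e-6, rounding = "display"), 1)
  # raw folds are reciprocal before rounding
  expect_equal(fold_change(1.3e-6, 12e-6) * fold_change(12e-6, 1.3e-6), 1)
  expect_error(fold_change(0, 1e-6), "positive")
})

test_that("detection-limit fold is the top-concentration / affinity ratio", {
  expect_equal(detection_limit_fold(30e-6, 0.355e-6), 84.5, tolerance = 1e-2)
  expect_gte(detection_limit_fold(30e-6, 0.355e-6), 80)
  expect_equal(detection_limit_fold(1e-6, 1e-6), 1)
  expect_equal(detection_limit_fold(1e-5, 1e-6), 10)
  expect_error(detection_limit_fold(-1, 1), "positive")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(atcm_params(pKA = 2, pKB = 6), "\\[3, 13\\]")
  expect_error(atcm_params(pKA = 10, pKB = 6, log_alpha_rad = 3),
               "\\[-4, 2\\]")
  expect_error(atcm_params(pKA = 10, pKB = 6, Bmax = -5), "positive")
  expect_silent(atcm_params(pKA = 10, pKB = 6, log_alpha_rad = -Inf))
  expect_error(saturation_params(pKd = 10, Bmax = 100, ns_slope = -1),
               "non-negative")
  expect_error(hill_params(top = 10, bottom = 50, logIC50 = -6), "greater")
  expect_error(hill_params(top = 100, bottom = 0, logIC50 = -6, nH = 0),
               "nonzero")
})
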