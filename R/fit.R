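#' Nonlinear least-squares fits of the binding models
#'
#' All fitting is done by Levenberg-Marquardt least squares
#' (`minpack.lm::nls.lm`) on the log-parameter scale (pK in \[3, 13\],
#' log10 cooperativity in \[-4, 2\]) with a deterministic multi-start:
#' every start on a fixed grid is run, the lowest sum of squared residuals
#' wins, and ties are broken by the smallest first parameter. This makes
#' repeated fits of the same data bit-reproducible.
#'
#' @name fitting
#' @keywords internal
NULL

fit_result <- function(estimates, se, ssr, n_obs, converged, n_starts_used,
                       fixed_params = list(), flags = character(),
                       model = "", response = numeric()) {
  structure(
    list(estimates = estimates, standard_errors = se, ssr = ssr,
         n_obs = n_obs, n_free = length(estimates),
         df_residual = n_obs - length(estimates),
         converged = converged, n_starts_used = n_starts_used,
         fixed_params = fixed_params, flags = flags, model = model,
         response = response),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result (%s): %s, SSR %.4g on %d obs\n",
              x$model, if (x$converged) "converged" else "NOT CONVERGED",
              x$ssr, x$n_obs))
  tab <- data.frame(estimate = unlist(x$estimates),
                    std_error = unlist(x$standard_errors)[names(x$estimates)])
  print(signif(tab, 4))
  if (length(x$fixed_params))
    cat("  fixed:", paste(names(x$fixed_params), "=",
                          signif(unlist(x$fixed_params), 4),
                          collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# deterministic multi-start Levenberg-Marquardt; starts is a list of named
# numeric vectors, all sharing names/bounds
ls_engine <- function(resid_fn, starts, lower, upper) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxiter = 500)
  fits <- lapply(starts, function(st) {
    tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("least-squares fit failed from every start", call. = FALSE)
  ssrs <- vapply(fits, stats::deviance, numeric(1))
  best_ssr <- min(ssrs)
  cand <- which(ssrs <= best_ssr * (1 + 1e-9) + 1e-300)
  # tie-break: smallest value of the first parameter
  first_par <- vapply(fits[cand], function(f) f$par[[1]], numeric(1))
  best <- fits[[cand[which.min(first_par)]]]
  list(fit = best, n_starts = length(starts))
}

engine_se <- function(fit) {
  p <- length(fit$par)
  df <- length(fit$fvec) - p
  se <- rep(NA_real_, p)
  if (df > 0) {
    se <- tryCatch(
      sqrt(diag(solve(fit$hessian) * stats::deviance(fit) / df)),
      error = function(e) rep(NA_real_, p))
  }
  stats::setNames(se, names(fit$par))
}

engine_converged <- function(fit) fit$info %in% 1:4

#' Fit the one-site saturation model
#'
#' Joint fit of total and nonspecific arms of a saturation experiment:
#' the total arm follows `Bmax*A/(A+Kd) + ns_slope*A`, the nonspecific arm
#' `ns_slope*A`. Estimates pKd, Bmax and the nonspecific slope. Datasets
#' holding several experiments are accepted via `experiment`; the default
#' fits the first.
#'
#' @param ds a [binding_dataset()] from a saturation design with both arms.
#' @param experiment which `experiment_id` to fit.
#' @return A `fit_result` with estimates `pKd`, `Bmax`, `ns_slope`
#'   (fmol/mg per M).
#' @export
fit_saturation <- function(ds, experiment = NULL) {
  stopifnot(inherits(ds, "binding_dataset"))
  if (is.null(experiment)) experiment <- unique(ds$experiment_id)[1]
  d <- ds[ds$experiment_id == experiment, ]
  if (!any(d$is_nonspecific))
    stop("saturation fit requires a nonspecific arm", call. = FALSE)
  if (!any(!d$is_nonspecific))
    stop("saturation fit requires a total-binding arm", call. = FALSE)
  A <- d$conc_radioligand_M
  if (length(unique(A[!d$is_nonspecific])) < 5)
    stop("saturation fit requires >= 5 radioligand concentrations",
         call. = FALSE)
  y <- d$response
  ns <- d$is_nonspecific

  # ns parameter carried per-nM for conditioning; reported per-M
  model <- function(par) {
    Kd <- 10^(-par[["pKd"]])
    spec <- par[["Bmax"]] * A / (A + Kd)
    ifelse(ns, 0, spec) + par[["ns_nM"]] * A * 1e9
  }
  resid_fn <- function(par) y - model(par)

  ns_start <- max(0, stats::coef(stats::lm(y[ns] ~ 0 + I(A[ns] * 1e9)))[[1]])
  spec_max <- max(y[!ns]) - ns_start * max(A) * 1e9
  pKd0 <- k_to_pk(max(stats::median(A), min(A)))
  starts <- lapply(c(-1, 0, 1), function(sh) {
    c(pKd = min(13, max(3, pKd0 + sh)), Bmax = max(spec_max, 1),
      ns_nM = ns_start)
  })
  res <- ls_engine(resid_fn, starts,
                   lower = c(3, 1e-6, 0), upper = c(13, 1e6, 1e6))
  fit <- res$fit
  est <- list(pKd = fit$par[["pKd"]], Bmax = fit$par[["Bmax"]],
              ns_slope = fit$par[["ns_nM"]] * 1e9)
  se <- engine_se(fit)
  se <- list(pKd = se[["pKd"]], Bmax = se[["Bmax"]],
             ns_slope = se[["ns_nM"]] * 1e9)
  fit_result(est, se, stats::deviance(fit), length(y),
             engine_converged(fit), res$n_starts,
             model = "one-site saturation", response = y)
}

#' Fit the four-parameter logistic inhibition curve
#'
#' Fits `Y = bottom + (top - bottom)/(1 + 10^((x - logIC50) * nH))` to a
#' titration of one ligand (competitor or modulator) at fixed radioligand
#' concentration, on the % control scale. Any of `top`, `bottom`, `nH` can
#' be fixed through `fixed` — fixing `bottom = 0` is the
#' complete-displacement assumption used to estimate affinity from curves
#' that do not visibly reach their floor. The fitted IC50 converts to Ki
#' with [cheng_prusoff_ki()].
#'
#' @param ds a [binding_dataset()]; raw fmol/mg responses are normalized to
#'   % control per experiment first.
#' @param fixed named numeric vector/list of parameters to hold fixed,
#'   among `top`, `bottom`, `nH`.
#' @param ligand `"auto"` picks whichever of competitor/modulator is
#'   titrated.
#' @param experiment which `experiment_id` to fit.
#' @return A `fit_result` with (free subset of) `top`, `bottom`,
#'   `logIC50`, `nH`.
#' @export
fit_hill <- function(ds, fixed = NULL, ligand = c("auto", "competitor",
                                                  "modulator"),
                     experiment = NULL) {
  stopifnot(inherits(ds, "binding_dataset"))
  ligand <- match.arg(ligand)
  ds <- normalize_dataset(ds)
  if (is.null(experiment)) experiment <- unique(ds$experiment_id)[1]
  d <- ds[ds$experiment_id == experiment & !ds$is_nonspecific, ]
  conc <- switch(ligand,
    competitor = d$conc_competitor_M,
    modulator = d$conc_modulator_M,
    auto = if (length(unique(d$conc_competitor_M)) >
               length(unique(d$conc_modulator_M)))
      d$conc_competitor_M else d$conc_modulator_M)
  if (length(unique(conc)) < 5)
    stop("Hill fit requires >= 5 concentrations", call. = FALSE)
  x <- log10(conc)  # vehicle wells map to -Inf and pin the top asymptote
  y <- d$response
  if (stats::sd(y) < 1e-12 * max(abs(y), 1))
    stop("all responses identical; no curve to fit", call. = FALSE)

  fixed <- as.list(fixed)
  par_names <- setdiff(c("top", "bottom", "logIC50", "nH"), names(fixed))
  full_par <- function(par) {
    p <- c(as.list(par), fixed)
    p[c("top", "bottom", "logIC50", "nH")]
  }
  resid_fn <- function(par) {
    p <- full_par(par)
    y - (p$bottom + (p$top - p$bottom) /
           (1 + 10^((x - p$logIC50) * p$nH)))
  }
  xf <- x[is.finite(x)]
  ic50_starts <- stats::quantile(xf, c(0.25, 0.5, 0.75), names = FALSE)
  base <- c(top = max(y), bottom = min(y), logIC50 = 0, nH = 1)
  lower_all <- c(top = -1e3, bottom = -1e3, logIC50 = min(xf) - 3, nH = 0.1)
  upper_all <- c(top = 1e3, bottom = 1e3, logIC50 = max(xf) + 3, nH = 10)
  starts <- lapply(ic50_starts, function(s) {
    st <- base; st[["logIC50"]] <- s
    st[par_names]
  })
  res <- ls_engine(resid_fn, starts, lower = lower_all[par_names],
                   upper = upper_all[par_names])
  fit <- res$fit
  fit_result(as.list(fit$par), as.list(engine_se(fit)),
             stats::deviance(fit), length(y), engine_converged(fit),
             res$n_starts, fixed_params = fixed,
             model = "four-parameter logistic", response = y)
}

#' Fit the allosteric ternary complex model to a modulator titration
#'
#' Fits the % control form of the ternary complex occupancy ratio
#' `Y = 100 * (r + 1) / (r + (1 + b)/(1 + alpha*b))`, `r = A/KA`,
#' `b = B/KB`, with the radioligand pKA fixed (supplied from saturation
#' fits of the same construct/ion condition, the standard workflow).
#' Estimates pKB and the log10 cooperativity with the radioligand.
#' `model = "competitive"` instead fixes alpha = 0 (complete displacement,
#' `Y = 100*(r + 1)/(r + 1 + b)`) and estimates pKB alone — the restricted
#' model for [compare_models()].
#'
#' A 3x3 deterministic start grid spans the pKB and log alpha bounds; if
#' the highest tested modulator concentration is below 10 * the fitted KB
#' the plateau is flagged as poorly identified.
#'
#' @param ds a [binding_dataset()] with a modulator titration at fixed
#'   radioligand concentration.
#' @param pKA fixed radioligand pK.
#' @param model `"allosteric"` (pKB + log alpha) or `"competitive"` (pKB
#'   only, alpha = 0).
#' @param experiment which `experiment_id` to fit.
#' @return A `fit_result` with `pKB` (and `log_alpha_rad`).
#' @export
fit_atcm <- function(ds, pKA, model = c("allosteric", "competitive"),
                     experiment = NULL) {
  stopifnot(inherits(ds, "binding_dataset"))
  model <- match.arg(model)
  check_pk(pKA, "pKA")
  ds <- normalize_dataset(ds)
  if (is.null(experiment)) experiment <- unique(ds$experiment_id)[1]
  d <- ds[ds$experiment_id == experiment & !ds$is_nonspecific, ]
  B <- d$conc_modulator_M
  if (length(unique(B)) < 5)
    stop("ternary-complex fit requires >= 5 modulator concentrations",
         call. = FALSE)
  A <- unique(d$conc_radioligand_M)
  if (length(A) != 1L)
    stop("modulator titration must share one radioligand concentration",
         call. = FALSE)
  y <- d$response
  r <- A / pk_to_k(pKA)

  if (model == "competitive") {
    resid_fn <- function(par) {
      b <- B / 10^(-par[["pKB"]])
      y - 100 * (r + 1) / (r + 1 + b)
    }
    starts <- lapply(c(5.5, 8, 10.5), function(s) c(pKB = s))
    res <- ls_engine(resid_fn, starts, lower = 3, upper = 13)
    fit <- res$fit
    return(fit_result(as.list(fit$par), as.list(engine_se(fit)),
                      stats::deviance(fit), length(y),
                      engine_converged(fit), res$n_starts,
                      fixed_params = list(pKA = pKA, log_alpha_rad = -Inf),
                      model = "competitive displacement", response = y))
  }

  resid_fn <- function(par) {
    b <- B / 10^(-par[["pKB"]])
    alpha <- 10^par[["log_alpha_rad"]]
    y - 100 * (r + 1) / (r + (1 + b) / (1 + alpha * b))
  }
  starts <- unlist(lapply(c(5.5, 8, 10.5), function(pk)
    lapply(c(-2.5, -1, 0.5), function(la)
      c(pKB = pk, log_alpha_rad = la))), recursive = FALSE)
  res <- ls_engine(resid_fn, starts, lower = c(3, -4), upper = c(13, 2))
  fit <- res$fit
  flags <- character()
  if (max(B) < 10 * 10^(-fit$par[["pKB"]]))
    flags <- "plateau poorly identified: titration top < 10 * fitted KB"
  fit_result(as.list(fit$par), as.list(engine_se(fit)),
             stats::deviance(fit), length(y), engine_converged(fit),
             res$n_starts, fixed_params = list(pKA = pKA),
             flags = flags, model = "allosteric ternary complex",
             response = y)
}

#' Global fit of the extended three-ligand ternary complex model
#'
#' Fits [extended_atcm_binding()] to an interaction matrix — competitor
#' titrations at several fixed modulator concentrations, one radioligand
#' concentration — sharing `pKI`, `pKB`, `log_alpha_rad`,
#' `log_alpha_comp` and `Bmax` across all curves of one experiment, with
#' pKA fixed. At least two distinct modulator levels (including one > 0)
#' are required; with fewer, the cooperativities are not identifiable and
#' the fit refuses.
#'
#' @param ds a [binding_dataset()] from the matrix design (raw fmol/mg).
#' @param pKA fixed radioligand pK.
#' @param experiment which `experiment_id` to fit.
#' @return A `fit_result` with `pKI`, `pKB`, `log_alpha_rad`,
#'   `log_alpha_comp`, `Bmax`.
#' @export
fit_extended_atcm <- function(ds, pKA, experiment = NULL) {
  stopifnot(inherits(ds, "binding_dataset"))
  check_pk(pKA, "pKA")
  if (is.null(experiment)) experiment <- unique(ds$experiment_id)[1]
  d <- ds[ds$experiment_id == experiment & !ds$is_nonspecific, ]
  if (any(d$response_units != "fmol/mg"))
    stop("matrix fit expects raw responses in fmol/mg", call. = FALSE)
  Blev <- sort(unique(d$conc_modulator_M))
  if (length(Blev) < 2 || max(Blev) == 0)
    stop(paste("cooperativities are unidentifiable: the interaction matrix",
               "needs >= 2 modulator levels including one > 0"),
         call. = FALSE)
  A <- unique(d$conc_radioligand_M)
  if (length(A) != 1L)
    stop("matrix design must share one radioligand concentration",
         call. = FALSE)
  I <- d$conc_competitor_M
  B <- d$conc_modulator_M
  y <- d$response
  KA <- pk_to_k(pKA)

  model_fn <- function(par) {
    KB <- 10^(-par[["pKB"]]); KI <- 10^(-par[["pKI"]])
    a_rad <- 10^par[["log_alpha_rad"]]; a_comp <- 10^par[["log_alpha_comp"]]
    shift <- (KA * KB / (a_rad * B + KB)) *
      (1 + I / KI + B / KB + a_comp * I * B / (KI * KB))
    par[["Bmax"]] * A / (A + shift)
  }
  resid_fn <- function(par) y - model_fn(par)

  # smart pKI start from the half-fall of the modulator-free curve
  b0 <- d[d$conc_modulator_M == 0 & d$conc_competitor_M > 0, ]
  pKI0 <- if (nrow(b0) >= 3) {
    half <- max(b0$response) / 2
    k_to_pk(max(min(b0$conc_competitor_M[b0$response <= half],
                    max(b0$conc_competitor_M)), min(b0$conc_competitor_M)))
  } else 6
  pKI0 <- min(13, max(3, pKI0))
  Bmax0 <- max(y)
  starts <- unlist(lapply(c(5.5, 8, 10.5), function(pk)
    lapply(c(-2.5, -1, 0.5), function(la)
      c(pKB = pk, pKI = pKI0, log_alpha_rad = la, log_alpha_comp = la,
        Bmax = Bmax0))), recursive = FALSE)
  res <- ls_engine(resid_fn, starts,
                   lower = c(3, 3, -4, -4, 1e-6),
                   upper = c(13, 13, 2, 2, 1e6))
  fit <- res$fit
  fit_result(as.list(fit$par), as.list(engine_se(fit)),
             stats::deviance(fit), length(y), engine_converged(fit),
             res$n_starts, fixed_params = list(pKA = pKA),
             model = "extended allosteric ternary complex", response = y)
}

#' Extra-sum-of-squares comparison of nested fits
#'
#' F test of a restricted model (fewer free parameters) against a full
#' model fitted to the same data:
#' `F = ((SSR_r - SSR_f)/(df_r - df_f)) / (SSR_f/df_f)`.
#' A small p-value favours the full model; 0.05 is the conventional
#' threshold for preferring, e.g., the allosteric model over pure
#' competition.
#'
#' @param fit_restricted,fit_full `fit_result` objects on identical data,
#'   with the restricted model nested in the full one.
#' @return A list with `F`, `df1`, `df2`, `p_value` and
#'   `prefer_full` (at 0.05), of class `model_comparison`.
#' @export
compare_models <- function(fit_restricted, fit_full) {
  stopifnot(inherits(fit_restricted, "fit_result"),
            inherits(fit_full, "fit_result"))
  if (fit_restricted$n_obs != fit_full$n_obs ||
      !isTRUE(all.equal(fit_restricted$response, fit_full$response)))
    stop("model comparison requires fits of identical data", call. = FALSE)
  if (fit_restricted$n_free >= fit_full$n_free)
    stop("restricted model must have fewer free parameters", call. = FALSE)
  df1 <- fit_full$n_free - fit_restricted$n_free
  df2 <- fit_full$df_residual
  if (df2 <= 0) stop("full model has no residual degrees of freedom",
                     call. = FALSE)
  Fstat <- max(0, (fit_restricted$ssr - fit_full$ssr) / df1 /
                 (fit_full$ssr / df2))
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(F = Fstat, df1 = df1, df2 = df2, p_value = p,
                 prefer_full = p < 0.05),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Extra-sum-of-squares F(%d, %d) = %.3f, p = %.4g -> %s model\n",
              x$df1, x$df2, x$F, x$p_value,
              if (x$prefer_full) "full" else "restricted"))
  invisible(x)
}

#' Aggregate per-experiment estimates as mean and SEM
#'
#' Replicate experiments are fitted individually and their parameter
#' estimates aggregated as mean +/- SEM on the log (pK / log alpha) scale,
#' the convention for reporting binding parameters over n individual
#' experiments.
#'
#' @param fits list of converged `fit_result` objects (>= 2).
#' @param param parameter name to aggregate.
#' @return An object of class `aggregate_estimate`: `mean`, `sem`, `n`,
#'   `values`.
#' @export
aggregate_replicates <- function(fits, param) {
  if (!is.list(fits) || length(fits) < 2)
    stop("aggregation requires >= 2 fits", call. = FALSE)
  ok <- vapply(fits, function(f) inherits(f, "fit_result") && f$converged,
               logical(1))
  if (!all(ok)) stop("all fits must be converged fit_result objects",
                     call. = FALSE)
  vals <- vapply(fits, function(f) {
    if (!param %in% names(f$estimates))
      stop("parameter '", param, "' not present in every fit", call. = FALSE)
    f$estimates[[param]]
  }, numeric(1))
  structure(list(param = param, mean = mean(vals),
                 sem = stats::sd(vals) / sqrt(length(vals)),
                 n = length(vals), values = vals),
            class = "aggregate_estimate")
}

#' @export
print.aggregate_estimate <- function(x, ...) {
  cat(sprintf("%s = %.3f +/- %.3f (mean +/- SEM, n = %d)\n",
              x$param, x$mean, x$sem, x$n))
  invisible(x)
}

#' Fit every experiment in a dataset and aggregate
#'
#' Convenience wrapper: applies one of the fit functions per
#' `experiment_id` and returns the per-experiment fits plus aggregates for
#' the requested parameters.
#'
#' @param ds a [binding_dataset()].
#' @param fit_fn fitting function taking `(ds, ..., experiment = id)`.
#' @param params parameter names to aggregate (default: all shared).
#' @param ... passed to `fit_fn`.
#' @return List with `fits` (one per experiment) and `aggregates` (named
#'   list of [aggregate_replicates()] results).
#' @export
fit_experiments <- function(ds, fit_fn, params = NULL, ...) {
  ids <- unique(ds$experiment_id)
  fits <- lapply(ids, function(e) fit_fn(ds, ..., experiment = e))
  names(fits) <- as.character(ids)
  if (is.null(params)) params <- names(fits[[1]]$estimates)
  aggregates <- if (length(ids) >= 2) {
    stats::setNames(lapply(params, function(pp)
      aggregate_replicates(fits, pp)), params)
  } else list()
  list(fits = fits, aggregates = aggregates)
}
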