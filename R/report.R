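#' Display helpers for binding parameters
#'
#' Dissociation constants are carried in molar but reported the way binding
#' tables print them: pK to two decimals, K to two significant figures in a
#' convenient unit (pM/nM/uM/mM).
#'
#' @param K dissociation constant, molar.
#' @param digits significant figures for the K display.
#' @return `format_k()`: e.g. `"0.35 uM"`. `k_display()`: the bare number
#'   in the requested unit.
#' @export
format_k <- function(K, digits = 2) {
  u <- k_unit(K)
  paste(k_display(K, u, digits), u)
}

k_unit <- function(K) {
  if (!is.finite(K)) return("M")
  if (K < 1e-11) "pM" else if (K < 1e-7) "nM" else if (K < 1e-3) "uM"
  else "M"
}

#' @rdname format_k
#' @param unit one of `"pM"`, `"nM"`, `"uM"`, `"mM"`, `"M"`.
#' @export
k_display <- function(K, unit = c("nM", "pM", "uM", "mM", "M"), digits = 2) {
  unit <- match.arg(unit)
  scale <- c(pM = 1e12, nM = 1e9, uM = 1e6, mM = 1e3, M = 1)[[unit]]
  format(signif(K * scale, digits), trim = TRUE, scientific = FALSE)
}

#' Table cell for an aggregated log-scale estimate
#'
#' Renders `mean +/- SEM (K)` with the K display in the chosen unit, e.g.
#' `"6.45 ± 0.09 (0.35)"` for a pK of 6.45 displayed in uM.
#'
#' @param mean,sem aggregated estimate and SEM on the log scale.
#' @param unit display unit for the back-transformed K; `"auto"` picks one.
#' @param is_pk TRUE for pK-type parameters (back-transform `10^-mean`),
#'   FALSE for log-alpha-type (`10^mean`).
#' @return A character cell.
#' @export
format_estimate_cell <- function(mean, sem, unit = "auto", is_pk = TRUE) {
  if (is.na(mean)) return("-")
  val <- if (is_pk) pk_to_k(mean) else 10^mean
  shown <- if (is_pk) {
    if (identical(unit, "auto")) unit <- k_unit(val)
    k_display(val, unit)
  } else {
    format(signif(val, 2), trim = TRUE, scientific = FALSE)
  }
  if (is.na(sem)) sprintf("%.2f (%s)", mean, shown)
  else sprintf("%.2f ± %.2f (%s)", mean, sem, shown)
}

#' Integer fold-change annotation
#'
#' Renders the loss (or gain) of affinity between two conditions as the
#' integer fold quoted from rounded table values, e.g. `"9-fold"` for Ki
#' 1.3 vs 12 uM.
#'
#' @param K_ref,K_alt dissociation constants in a common unit.
#' @return Character annotation.
#' @export
fold_annotation <- function(K_ref, K_alt) {
  sprintf("%d-fold", fold_change(K_ref, K_alt, rounding = "display"))
}

#' Condition-matrix report of aggregated binding parameters
#'
#' Lays out aggregated estimates the way binding-parameter tables are
#' printed: one row per ligand x parameter, one column per construct x ion
#' condition, each cell `mean +/- SEM (K)`; conditions without data render
#' as `"-"`. pK-type rows also get a fold-change annotation of every
#' condition against the reference condition, computed from the
#' 2-significant-figure K displays.
#'
#' @param estimates data.frame with columns `ligand`, `parameter`
#'   (`"pK"`-type names or `"log_alpha_rad"`-type names), `construct`,
#'   `ion`, `mean`, `sem`.
#' @param reference c(construct, ion) reference condition for folds.
#' @return A data.frame of formatted cells, with attribute `"folds"`.
#' @export
report_table <- function(estimates, reference = c("WT", "NaCl")) {
  need <- c("ligand", "parameter", "construct", "ion", "mean", "sem")
  stopifnot(all(need %in% names(estimates)))
  conds <- unique(estimates[c("construct", "ion")])
  cond_names <- paste(conds$construct, conds$ion, sep = "/")
  rows <- unique(estimates[c("ligand", "parameter")])
  out <- data.frame(ligand = rows$ligand, parameter = rows$parameter,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(conds))) out[[cond_names[j]]] <- "-"
  folds <- out[c("ligand", "parameter")]
  for (j in seq_len(nrow(conds))) folds[[cond_names[j]]] <- NA_character_

  for (i in seq_len(nrow(rows))) {
    is_pk <- startsWith(rows$parameter[i], "pK")
    ref <- estimates[estimates$ligand == rows$ligand[i] &
                       estimates$parameter == rows$parameter[i] &
                       estimates$construct == reference[1] &
                       estimates$ion == reference[2], ]
    for (j in seq_len(nrow(conds))) {
      e <- estimates[estimates$ligand == rows$ligand[i] &
                       estimates$parameter == rows$parameter[i] &
                       estimates$construct == conds$construct[j] &
                       estimates$ion == conds$ion[j], ]
      if (nrow(e) == 1 && !is.na(e$mean)) {
        out[i, cond_names[j]] <- format_estimate_cell(e$mean, e$sem,
                                                      is_pk = is_pk)
        if (is_pk && nrow(ref) == 1 && !is.na(ref$mean))
          folds[i, cond_names[j]] <- fold_annotation(pk_to_k(ref$mean),
                                                     pk_to_k(e$mean))
      }
    }
  }
  attr(out, "folds") <- folds
  out
}

#' Pipeline drivers: simulate, fit, compare, report
#'
#' Config-driven entry points tying the modules together. Each takes a
#' plain named list and writes its outputs (CSV datasets, fit tables,
#' comparison tables, report matrices) plus a JSON manifest recording the
#' configuration, seed and package version, so every number in a report is
#' traceable to a seed and spec. Given the same config, outputs are
#' byte-reproducible.
#'
#' `run_simulate()` needs `spec` (a [simulation_spec()]; its mandatory seed
#' is enforced) and `out_dir`. `run_fit()` needs `input` (a dataset CSV),
#' `out_dir`, and for ternary-complex designs `pKA`; optional `fixed` is
#' passed to [fit_hill()]. `run_compare()` needs `groups` (named list of
#' numeric vectors) and `out_dir`. `run_report()` needs `estimates` (a
#' data.frame for [report_table()], or a CSV path) and `out_dir`.
#'
#' @param config named list, see Details.
#' @return Invisibly, a list of output paths (and the main result object).
#' @name pipeline
NULL

write_manifest <- function(out_dir, command, config_record, files) {
  manifest <- list(
    command = command,
    config = config_record,
    package = "atcmfit",
    package_version = as.character(utils::packageVersion("atcmfit")),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' @rdname pipeline
#' @export
run_simulate <- function(config) {
  stopifnot(is.list(config), inherits(config$spec, "simulation_spec"),
            !is.null(config$out_dir))
  spec <- config$spec
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- if (spec$design == "saturation")
    simulate_saturation_experiment(spec)
  else simulate_interaction_experiment(spec)
  csv <- file.path(config$out_dir,
                   sprintf("dataset_%s_seed%d.csv", spec$design, spec$seed))
  write_binding_csv(ds, csv)
  spec_record <- spec
  spec_record$params <- unclass(spec_record$params)
  manifest <- write_manifest(config$out_dir, "simulate",
                             unclass(spec_record), list(csv))
  message(sprintf("simulated %d wells (%s design, seed %d) -> %s",
                  nrow(ds), spec$design, spec$seed, csv))
  invisible(list(dataset = ds, csv = csv, manifest = manifest))
}

#' @rdname pipeline
#' @export
run_fit <- function(config) {
  stopifnot(is.list(config), !is.null(config$input), !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_binding_csv(config$input)
  design <- attr(ds, "design") %||% config$design %||% "competition"
  res <- switch(design,
    saturation = fit_experiments(ds, fit_saturation,
                                 params = c("pKd", "Bmax")),
    competition = fit_experiments(ds, fit_hill, fixed = config$fixed,
                                  params = "logIC50"),
    interaction_modulator = fit_experiments(
      ds, fit_atcm, pKA = config$pKA,
      params = c("pKB", "log_alpha_rad")),
    interaction_dopamine_matrix = fit_experiments(
      ds, fit_extended_atcm, pKA = config$pKA,
      params = c("pKI", "pKB", "log_alpha_rad", "log_alpha_comp")),
    stop("unknown design: ", design, call. = FALSE))

  per_fit <- do.call(rbind, lapply(names(res$fits), function(e) {
    f <- res$fits[[e]]
    data.frame(experiment_id = e, parameter = names(f$estimates),
               estimate = unlist(f$estimates),
               std_error = unlist(f$standard_errors)[names(f$estimates)],
               ssr = f$ssr, n_obs = f$n_obs, converged = f$converged,
               n_starts_used = f$n_starts_used, row.names = NULL)
  }))
  fits_csv <- file.path(config$out_dir, "fits.csv")
  utils::write.csv(per_fit, fits_csv, row.names = FALSE)

  agg <- do.call(rbind, lapply(res$aggregates, function(a)
    data.frame(parameter = a$param, mean = a$mean, sem = a$sem, n = a$n)))
  agg_csv <- file.path(config$out_dir, "aggregates.csv")
  utils::write.csv(agg, agg_csv, row.names = FALSE)

  for (e in names(res$fits)) {
    f <- res$fits[[e]]
    message(sprintf("experiment %s: SSR %.4g, %d starts, %s%s", e, f$ssr,
                    f$n_starts_used,
                    if (f$converged) "converged" else "NOT converged",
                    if (length(f$flags))
                      paste0(" [", paste(f$flags, collapse = "; "), "]")
                    else ""))
  }
  manifest <- write_manifest(config$out_dir, "fit",
                             list(input = config$input, design = design,
                                  pKA = config$pKA),
                             list(fits_csv, agg_csv))
  invisible(list(result = res, fits_csv = fits_csv, aggregates_csv = agg_csv,
                 manifest = manifest))
}

#' @rdname pipeline
#' @export
run_compare <- function(config) {
  stopifnot(is.list(config), is.list(config$groups),
            !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- Map(group_estimates, names(config$groups), config$groups)
  cmp <- anova_tukey(unname(groups))
  out <- file.path(config$out_dir, "comparison.csv")
  utils::write.csv(cbind(cmp$pairs,
                         F_overall = cmp$F, p_overall = cmp$p_overall),
                   out, row.names = FALSE)
  manifest <- write_manifest(config$out_dir, "compare",
                             lapply(config$groups, as.numeric), list(out))
  invisible(list(comparison = cmp, csv = out, manifest = manifest))
}

#' @rdname pipeline
#' @export
run_report <- function(config) {
  stopifnot(is.list(config), !is.null(config$estimates),
            !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  est <- config$estimates
  if (is.character(est)) est <- utils::read.csv(est)
  tab <- report_table(est, reference = config$reference %||% c("WT", "NaCl"))
  out <- file.path(config$out_dir, "report.csv")
  utils::write.csv(tab, out, row.names = FALSE)
  folds_out <- file.path(config$out_dir, "report_folds.csv")
  utils::write.csv(attr(tab, "folds"), folds_out, row.names = FALSE)
  manifest <- write_manifest(config$out_dir, "report",
                             list(rows = nrow(tab)), list(out, folds_out))
  invisible(list(table = tab, csv = out, folds_csv = folds_out,
                 manifest = manifest))
}
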