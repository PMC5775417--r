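#' Binding datasets
#'
#' A `binding_dataset` is a data.frame of per-well records with columns:
#' \describe{
#'   \item{experiment_id}{integer/character replicate experiment label}
#'   \item{construct}{receptor construct, e.g. `"WT"`, `"D80A"`, `"E95A"`}
#'   \item{ion}{ionic condition, e.g. `"NaCl"` or `"NMDG"`}
#'   \item{conc_radioligand_M, conc_competitor_M, conc_modulator_M}{molar
#'     concentrations of radioligand A, orthosteric competitor I and
#'     allosteric modulator B}
#'   \item{response}{measured binding}
#'   \item{response_units}{`"fmol/mg"` or `"pct_control"`}
#'   \item{is_nonspecific}{logical; TRUE for wells run against a saturating
#'     unlabelled competitor to define nonspecific binding}
#' }
#' For competition/interaction designs every experiment must contain a
#' vehicle well (no competitor, no modulator, not nonspecific) so responses
#' can be normalized to % control.
#'
#' @param df a data.frame with the columns above.
#' @param design one of `"saturation"`, `"competition"`,
#'   `"interaction_modulator"`, `"interaction_dopamine_matrix"`; stored as
#'   an attribute and checked where it matters.
#' @return The validated data.frame with class `binding_dataset`.
#' @export
binding_dataset <- function(df, design = NA_character_) {
  stopifnot(is.data.frame(df))
  need <- dataset_columns()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing binding dataset column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cc in c("conc_radioligand_M", "conc_competitor_M", "conc_modulator_M"))
    check_conc(df[[cc]], cc)
  if (any(!is.finite(df$response)))
    stop("all responses must be finite", call. = FALSE)
  if (!is.logical(df$is_nonspecific))
    df$is_nonspecific <- as.logical(df$is_nonspecific)
  # vehicle-record invariant, per experiment, for designs that normalize
  if (!is.na(design) && design != "saturation") {
    for (e in unique(df$experiment_id)) {
      sub <- df[df$experiment_id == e & !df$is_nonspecific, ]
      if (!any(sub$conc_competitor_M == 0 & sub$conc_modulator_M == 0))
        stop(sprintf("experiment '%s' lacks a vehicle (I = 0, B = 0) record",
                     e), call. = FALSE)
    }
  }
  structure(df, class = c("binding_dataset", "data.frame"), design = design)
}

dataset_columns <- function() {
  c("experiment_id", "construct", "ion",
    "conc_radioligand_M", "conc_competitor_M", "conc_modulator_M",
    "response", "response_units", "is_nonspecific")
}

#' @export
print.binding_dataset <- function(x, ...) {
  cat(sprintf("Binding dataset: %d wells, %d experiment(s), design %s\n",
              nrow(x), length(unique(x$experiment_id)),
              attr(x, "design") %||% "unspecified"))
  NextMethod()
}

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
}

#' Read / write binding datasets as CSV
#'
#' The CSV dialect has exactly the `binding_dataset` columns; numeric
#' columns are written with 17 significant digits so datasets round-trip
#' bit-identically through write/read.
#'
#' @param ds a [binding_dataset()].
#' @param path file path.
#' @param design design label to attach on read (written files carry it in
#'   a `# design:` comment line and it is recovered automatically).
#' @return `read_binding_csv()` returns a [binding_dataset()];
#'   `write_binding_csv()` returns `path` invisibly.
#' @export
write_binding_csv <- function(ds, path) {
  stopifnot(inherits(ds, "binding_dataset"))
  out <- as.data.frame(ds)
  for (cc in c("conc_radioligand_M", "conc_competitor_M",
               "conc_modulator_M", "response"))
    out[[cc]] <- sprintf("%.17g", out[[cc]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# design: %s", attr(ds, "design") %||% "unspecified"),
             con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_binding_csv
#' @export
read_binding_csv <- function(path, design = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "# design:")) {
    skip <- 1L
    if (is.null(design)) {
      design <- trimws(sub("^# design:", "", first))
      if (identical(design, "unspecified")) design <- NA_character_
    }
  }
  df <- tryCatch(
    utils::read.csv(path, skip = skip, stringsAsFactors = FALSE),
    error = function(e) stop("malformed binding CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L)
    stop("binding CSV '", path, "' contains no data rows", call. = FALSE)
  missing_cols <- setdiff(dataset_columns(), names(df))
  if (length(missing_cols))
    stop("binding CSV '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cc in c("conc_radioligand_M", "conc_competitor_M",
               "conc_modulator_M", "response")) {
    if (!is.numeric(df[[cc]]))
      stop(sprintf("binding CSV '%s': column '%s' is not numeric",
                   path, cc), call. = FALSE)
    df[[cc]] <- as.numeric(df[[cc]])
  }
  binding_dataset(df, design = design %||% NA_character_)
}

#' Normalize a dataset to percent of vehicle control
#'
#' Divides each experiment's specific-binding responses by the mean of its
#' vehicle wells (no competitor, no modulator) and rescales to percent.
#' Nonspecific wells are left untouched.
#'
#' @param ds a [binding_dataset()] with `response_units == "fmol/mg"`.
#' @return The dataset with responses in `"pct_control"`.
#' @export
normalize_dataset <- function(ds) {
  stopifnot(inherits(ds, "binding_dataset"))
  if (all(ds$response_units == "pct_control")) return(ds)
  for (e in unique(ds$experiment_id)) {
    idx <- ds$experiment_id == e & !ds$is_nonspecific
    veh <- idx & ds$conc_competitor_M == 0 & ds$conc_modulator_M == 0
    if (!any(veh))
      stop(sprintf("experiment '%s' lacks a vehicle record", e),
           call. = FALSE)
    v <- mean(ds$response[veh])
    ds$response[idx] <- normalize_to_vehicle(ds$response[idx], v)
    ds$response_units[idx] <- "pct_control"
  }
  ds
}
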