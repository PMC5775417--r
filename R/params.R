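#' Parameter objects for equilibrium binding models
#'
#' Constructors with validity checks for the parameter sets used throughout
#' the package. All equilibrium dissociation constants are carried as
#' negative log10 molar values (pK), and cooperativity factors as log10
#' values (logalpha), because fitting is performed on those unbounded,
#' well-conditioned scales. Concentrations everywhere in the package are
#' molar; `Bmax` is in fmol/mg membrane protein.
#'
#' @details
#' `atcm_params()` holds the full parameter set of the extended (three
#' ligand) allosteric ternary complex model: a radioligand A, an orthosteric
#' competitor I and an allosteric modulator B. Cooperativities are named by
#' role: `log_alpha_rad` scales the modulator's effect on the radioligand's
#' affinity, `log_alpha_comp` its effect on the competitor's affinity.
#' `log_alpha_rad = -Inf` (alpha = 0) is accepted as the pseudo-competitive
#' boundary, i.e. complete displacement of the radioligand at saturating
#' modulator.
#'
#' @param pKA,pKB,pKI negative log10 molar dissociation constants of the
#'   radioligand, modulator and competitor. Must lie in \[3, 13\].
#' @param log_alpha_rad,log_alpha_comp log10 cooperativity factors
#'   (modulator vs radioligand, modulator vs competitor). Must lie in
#'   \[-4, 2\], or be `-Inf` for the complete-displacement boundary.
#' @param Bmax maximal specific binding, fmol/mg; > 0.
#' @return An object of class `atcm_params` (a named list).
#' @examples
#' p <- atcm_params(pKA = 10.45, pKB = 6.45, pKI = 5.59,
#'                  log_alpha_rad = -0.45, log_alpha_comp = -0.54,
#'                  Bmax = 237)
#' p
#' @export
atcm_params <- function(pKA, pKB, pKI = NA_real_,
                        log_alpha_rad = 0, log_alpha_comp = 0,
                        Bmax = 100) {
  check_pk(pKA, "pKA")
  check_pk(pKB, "pKB")
  if (!is.na(pKI)) check_pk(pKI, "pKI")
  check_logalpha(log_alpha_rad, "log_alpha_rad")
  check_logalpha(log_alpha_comp, "log_alpha_comp")
  if (!is.numeric(Bmax) || length(Bmax) != 1L || !is.finite(Bmax) || Bmax <= 0)
    stop("'Bmax' must be a single positive finite number", call. = FALSE)
  structure(
    list(pKA = pKA, pKB = pKB, pKI = pKI,
         log_alpha_rad = log_alpha_rad, log_alpha_comp = log_alpha_comp,
         Bmax = Bmax),
    class = "atcm_params"
  )
}

#' @rdname atcm_params
#' @param pKd negative log10 molar Kd of the radioligand.
#' @param ns_slope nonspecific binding per unit free radioligand
#'   concentration (fmol/mg per M); >= 0.
#' @return `saturation_params()`: an object of class `saturation_params`.
#' @export
saturation_params <- function(pKd, Bmax, ns_slope = 0) {
  check_pk(pKd, "pKd")
  if (!is.numeric(Bmax) || length(Bmax) != 1L || !is.finite(Bmax) || Bmax <= 0)
    stop("'Bmax' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(ns_slope) || length(ns_slope) != 1L ||
      !is.finite(ns_slope) || ns_slope < 0)
    stop("'ns_slope' must be a single non-negative finite number",
         call. = FALSE)
  structure(list(pKd = pKd, Bmax = Bmax, ns_slope = ns_slope),
            class = "saturation_params")
}

#' @rdname atcm_params
#' @param top,bottom upper and lower asymptotes of the logistic inhibition
#'   curve, in % of vehicle control; `top > bottom`.
#' @param logIC50 log10 molar midpoint concentration.
#' @param nH Hill slope factor; nonzero. Positive `nH` gives a descending
#'   (inhibition) curve under this sign convention.
#' @return `hill_params()`: an object of class `hill_params`.
#' @export
hill_params <- function(top, bottom, logIC50, nH = 1) {
  stopifnot(is.numeric(top), is.numeric(bottom), is.numeric(logIC50),
            is.numeric(nH))
  if (!(top > bottom))
    stop("'top' must be strictly greater than 'bottom'", call. = FALSE)
  if (nH == 0) stop("'nH' must be nonzero", call. = FALSE)
  structure(list(top = top, bottom = bottom, logIC50 = logIC50, nH = nH),
            class = "hill_params")
}

check_pk <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 3 || x > 13)
    stop(sprintf("'%s' must be a single finite value in [3, 13]", name),
         call. = FALSE)
  invisible(x)
}

check_logalpha <- function(x, name) {
  # -Inf allowed: alpha = 0, the complete-displacement boundary
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (is.finite(x) && (x < -4 || x > 2)) || x == Inf)
    stop(sprintf("'%s' must be in [-4, 2] (or -Inf for alpha = 0)", name),
         call. = FALSE)
  invisible(x)
}

check_conc <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be non-negative molar concentration(s)", name),
         call. = FALSE)
  invisible(x)
}

#' @export
print.atcm_params <- function(x, ...) {
  cat("Allosteric ternary complex parameters\n")
  cat(sprintf("  pKA %.2f (KA %s)  pKB %.2f (KB %s)\n",
              x$pKA, format_k(pk_to_k(x$pKA)),
              x$pKB, format_k(pk_to_k(x$pKB))))
  if (!is.na(x$pKI))
    cat(sprintf("  pKI %.2f (KI %s)\n", x$pKI, format_k(pk_to_k(x$pKI))))
  cat(sprintf("  log alpha (radioligand) %.2f  log alpha (competitor) %.2f\n",
              x$log_alpha_rad, x$log_alpha_comp))
  cat(sprintf("  Bmax %.1f fmol/mg\n", x$Bmax))
  invisible(x)
}

#' @export
print.saturation_params <- function(x, ...) {
  cat(sprintf("Saturation parameters: pKd %.2f (Kd %s), Bmax %.1f fmol/mg, ns %.3g fmol/mg/M\n",
              x$pKd, format_k(pk_to_k(x$pKd)), x$Bmax, x$ns_slope))
  invisible(x)
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill parameters: top %.1f, bottom %.1f, logIC50 %.2f (IC50 %s), nH %.2f\n",
              x$top, x$bottom, x$logIC50, format_k(10^x$logIC50), x$nH))
  invisible(x)
}
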