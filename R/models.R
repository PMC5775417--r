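#' One-site saturation binding
#'
#' Specific binding follows the rectangular hyperbola
#' `Bmax * A / (A + Kd)`; with `include_ns = TRUE` a linear nonspecific
#' component `ns_slope * A` is added, mirroring the total-binding arm of a
#' saturation assay run against a nonspecific control defined by a
#' saturating unlabelled competitor.
#'
#' @param A radioligand concentration(s), molar, non-negative.
#' @param p a [saturation_params()] object.
#' @param include_ns add the linear nonspecific component?
#' @return Bound radioligand in the units of `Bmax` (fmol/mg).
#' @examples
#' p <- saturation_params(pKd = -log10(0.04e-9), Bmax = 237)
#' saturation_binding(0.04e-9, p)   # half-saturation: Bmax / 2
#' @export
saturation_binding <- function(A, p, include_ns = FALSE) {
  stopifnot(inherits(p, "saturation_params"))
  check_conc(A, "A")
  Kd <- pk_to_k(p$pKd)
  y <- p$Bmax * A / (A + Kd)
  y[A == 0] <- 0
  if (include_ns) y <- y + p$ns_slope * A
  y
}

#' Allosteric ternary complex occupancy
#'
#' Fractional radioligand occupancy of receptor in the presence of an
#' allosteric modulator B:
#' `Y = (A/KA) / (A/KA + (1 + B/KB) / (1 + alpha * B/KB))`
#' where `alpha` is the cooperativity between modulator and radioligand.
#' `alpha < 1` gives a monotone decrease in occupancy with B (negative
#' allosteric modulation, partial displacement), `alpha > 1` a monotone
#' increase, `alpha = 1` no effect.
#'
#' @param A radioligand concentration(s), molar.
#' @param B modulator concentration(s), molar.
#' @param pKA,pKB negative log10 molar dissociation constants.
#' @param log_alpha_rad log10 cooperativity (modulator vs radioligand);
#'   `-Inf` means complete displacement at saturating B.
#' @return Fractional occupancy in \[0, 1\]. `A = 0` returns 0.
#' @export
atcm_occupancy <- function(A, B, pKA, pKB, log_alpha_rad) {
  check_conc(A, "A"); check_conc(B, "B")
  check_pk(pKA, "pKA"); check_pk(pKB, "pKB")
  check_logalpha(log_alpha_rad, "log_alpha_rad")
  r <- A / pk_to_k(pKA)
  b <- B / pk_to_k(pKB)
  alpha <- 10^log_alpha_rad
  y <- r / (r + (1 + b) / (1 + alpha * b))
  y[A == 0] <- 0
  y
}

#' Limiting occupancy at saturating modulator
#'
#' The B -> Inf limit of [atcm_occupancy()]:
#' `(A/KA) / (A/KA + 1/alpha)`. For `alpha = 0` the plateau is 0
#' (pseudo-competitive behaviour, complete displacement).
#'
#' @inheritParams atcm_occupancy
#' @return Limiting fractional occupancy.
#' @export
atcm_plateau <- function(A, pKA, log_alpha_rad) {
  check_conc(A, "A")
  check_pk(pKA, "pKA")
  check_logalpha(log_alpha_rad, "log_alpha_rad")
  if (log_alpha_rad == -Inf) return(rep(0, length(A)))
  r <- A / pk_to_k(pKA)
  alpha <- 10^log_alpha_rad
  y <- r / (r + 1 / alpha)
  y[A == 0] <- 0
  y
}

#' Extended three-ligand allosteric ternary complex binding
#'
#' Bound radioligand in the simultaneous presence of an orthosteric
#' competitor I and an allosteric modulator B:
#' \deqn{Y = \frac{B_{max}[A]}{[A] + \frac{K_A K_B}{\alpha_{rad}[B]+K_B}
#'   \left(1 + \frac{[I]}{K_I} + \frac{[B]}{K_B} +
#'   \frac{\alpha_{comp}[I][B]}{K_I K_B}\right)}}
#' At `B = 0` this reduces to classical one-site competition
#' `Bmax * A / (A + KA * (1 + I/KI))`; at `I = 0` it reduces (divided by
#' `Bmax`) to [atcm_occupancy()].
#'
#' @param A,B,I radioligand, modulator and competitor concentrations, molar.
#' @param p an [atcm_params()] object (`pKI` required when any `I > 0`).
#' @return Bound radioligand in the units of `Bmax`.
#' @export
extended_atcm_binding <- function(A, B, I, p) {
  stopifnot(inherits(p, "atcm_params"))
  check_conc(A, "A"); check_conc(B, "B"); check_conc(I, "I")
  if (any(I > 0) && is.na(p$pKI))
    stop("'pKI' is required when competitor is present", call. = FALSE)
  KA <- pk_to_k(p$pKA)
  KB <- pk_to_k(p$pKB)
  KI <- if (is.na(p$pKI)) Inf else pk_to_k(p$pKI)
  a_rad <- 10^p$log_alpha_rad
  a_comp <- 10^p$log_alpha_comp
  denom_shift <- (KA * KB / (a_rad * B + KB)) *
    (1 + I / KI + B / KB + a_comp * I * B / (KI * KB))
  y <- p$Bmax * A / (A + denom_shift)
  y[A == 0] <- 0
  y
}

#' Four-parameter logistic (Hill) inhibition curve
#'
#' `Y = bottom + (top - bottom) / (1 + 10^((x - logIC50) * nH))`, so that at
#' `x = logIC50` the response is midway between top and bottom. With a
#' positive Hill slope the curve descends with increasing concentration, the
#' usual shape of a competition binding curve.
#'
#' @param x log10 molar concentration(s); `-Inf` (zero concentration) maps
#'   to `top`.
#' @param p a [hill_params()] object.
#' @return Response in the units of `top`/`bottom` (% control).
#' @export
hill_curve <- function(x, p) {
  stopifnot(inherits(p, "hill_params"), is.numeric(x))
  p$bottom + (p$top - p$bottom) / (1 + 10^((x - p$logIC50) * p$nH))
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + A / KA)` for a competition experiment run at
#' radioligand concentration A against a radioligand of dissociation
#' constant KA.
#'
#' @param IC50 half-inhibition concentration(s), molar, > 0.
#' @param A radioligand concentration, molar, >= 0.
#' @param pKA negative log10 molar radioligand dissociation constant.
#' @return Ki in molar.
#' @export
cheng_prusoff_ki <- function(IC50, A, pKA) {
  if (any(!is.finite(IC50)) || any(IC50 <= 0))
    stop("'IC50' must be positive and finite", call. = FALSE)
  check_conc(A, "A")
  check_pk(pKA, "pKA")
  IC50 / (1 + A / pk_to_k(pKA))
}

#' Normalize responses to vehicle control
#'
#' Expresses raw bound values as percent of a vehicle (no competitor, no
#' modulator) response, the scale on which the allosteric ternary complex
#' model is fitted.
#'
#' @param values numeric bound values.
#' @param vehicle the vehicle-control bound value, > 0.
#' @return `values * 100 / vehicle`.
#' @export
normalize_to_vehicle <- function(values, vehicle) {
  if (!is.numeric(vehicle) || length(vehicle) != 1L ||
      !is.finite(vehicle) || vehicle <= 0)
    stop("'vehicle' must be a single positive value", call. = FALSE)
  values * 100 / vehicle
}

#' pK / K conversions
#'
#' `pk_to_k()` returns `10^(-pK)` in molar; `k_to_pk()` its inverse. The
#' pair round-trips to machine precision.
#'
#' @param pK negative log10 molar dissociation constant(s).
#' @param K dissociation constant(s) in molar, > 0.
#' @return Molar K, or pK, respectively.
#' @export
pk_to_k <- function(pK) {
  stopifnot(is.numeric(pK))
  10^(-pK)
}

#' @rdname pk_to_k
#' @export
k_to_pk <- function(K) {
  if (!is.numeric(K) || any(!is.finite(K)) || any(K <= 0))
    stop("'K' must be positive and finite", call. = FALSE)
  -log10(K)
}

#' Fold change in affinity
#'
#' Ratio `K_alt / K_ref` of two dissociation constants; > 1 is a loss of
#' affinity in the alternative condition. With `rounding = "display"` the
#' fold is computed from the 2-significant-figure K values and rounded to
#' the nearest integer, the convention used when quoting integer folds from
#' a table of rounded constants (e.g. 12 vs 1.3 uM -> 9-fold).
#'
#' @param K_ref,K_alt dissociation constants, molar (or any common unit),
#'   > 0.
#' @param rounding `"none"` for the raw ratio, `"display"` for the
#'   rounded-table convention.
#' @return Dimensionless fold change.
#' @export
fold_change <- function(K_ref, K_alt, rounding = c("none", "display")) {
  rounding <- match.arg(rounding)
  if (any(!is.finite(c(K_ref, K_alt))) || any(c(K_ref, K_alt) <= 0))
    stop("dissociation constants must be positive and finite", call. = FALSE)
  if (rounding == "display") {
    round(signif(K_alt, 2) / signif(K_ref, 2))
  } else {
    K_alt / K_ref
  }
}

#' Detection-limit fold loss
#'
#' When a ligand of reference affinity `K_ref` shows no detectable effect up
#' to the highest tested concentration `c_max`, its dissociation constant in
#' that condition must exceed `c_max`; the implied minimum fold loss of
#' affinity is `c_max / K_ref`.
#'
#' @param c_max highest tested concentration, molar, > 0.
#' @param K_ref reference-condition dissociation constant, molar, > 0.
#' @return Minimum fold loss consistent with no detected effect.
#' @export
detection_limit_fold <- function(c_max, K_ref) {
  if (any(!is.finite(c(c_max, K_ref))) || any(c(c_max, K_ref) <= 0))
    stop("'c_max' and 'K_ref' must be positive and finite", call. = FALSE)
  c_max / K_ref
}
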