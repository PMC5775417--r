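#' Group of per-experiment parameter estimates
#'
#' Labelled set of per-experiment estimates (on the log pK / log alpha
#' scale) for one experimental condition, the unit of the between-condition
#' comparisons.
#'
#' @param label condition label.
#' @param values numeric vector of per-experiment estimates, length >= 2.
#' @return An object of class `group_estimates`.
#' @export
group_estimates <- function(label, values) {
  if (!is.numeric(values) || length(values) < 2 || any(!is.finite(values)))
    stop("each group needs >= 2 finite values", call. = FALSE)
  structure(list(label = as.character(label), values = values),
            class = "group_estimates")
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' The standard inference for comparing a binding parameter across
#' receptor constructs / ionic conditions: one-way ANOVA over the
#' per-experiment estimates, followed by Tukey's honestly-significant-
#' difference test for all pairwise contrasts, at the 0.05 level. All
#' inference is on the log (pK / log alpha) scale.
#'
#' @param groups list of [group_estimates()] objects, length >= 2.
#' @return A list of class `anova_tukey` with `F`, `df`, `p_overall` and a
#'   data.frame `pairs` (columns `pair`, `diff`, `p_adj`, `significant`).
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      !all(vapply(groups, inherits, logical(1), "group_estimates")))
    stop("'groups' must be a list of >= 2 group_estimates", call. = FALSE)
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("group labels must be unique",
                                  call. = FALSE)
  df <- data.frame(
    value = unlist(lapply(groups, `[[`, "values")),
    group = factor(rep(labels,
                       vapply(groups, function(g) length(g$values),
                              integer(1))),
                   levels = labels)
  )
  if (stats::var(df$value) == 0) {
    # perfectly identical data: F = 0 by convention, nothing to compare
    pairs <- utils::combn(labels, 2, paste, collapse = "-")
    return(structure(list(F = 0, df = c(length(groups) - 1,
                                        nrow(df) - length(groups)),
                          p_overall = 1,
                          pairs = data.frame(pair = pairs, diff = 0,
                                             p_adj = 1,
                                             significant = FALSE)),
                     class = "anova_tukey"))
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < 0.05,
                      row.names = NULL)
  structure(list(F = an["group", "F value"],
                 df = c(an["group", "Df"], an["Residuals", "Df"]),
                 p_overall = an["group", "Pr(>F)"],
                 pairs = pairs),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_overall))
  cat("Tukey HSD pairwise comparisons:\n")
  print(transform(x$pairs, diff = signif(diff, 3), p_adj = signif(p_adj, 3)))
  invisible(x)
}

#' Unpaired two-tailed Student's t test
#'
#' Classical equal-variance two-sample t test on per-experiment estimates,
#' used where only two conditions are compared.
#'
#' @param a,b [group_estimates()] objects.
#' @return List with `t`, `df`, `p_value`, `mean_diff`.
#' @export
t_test_unpaired <- function(a, b) {
  stopifnot(inherits(a, "group_estimates"), inherits(b, "group_estimates"))
  if (stats::sd(c(a$values, b$values)) == 0)
    return(list(t = 0, df = length(a$values) + length(b$values) - 2,
                p_value = 1, mean_diff = 0))
  tt <- stats::t.test(a$values, b$values, var.equal = TRUE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_diff = mean(a$values) - mean(b$values))
}
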