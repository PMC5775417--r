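Package: atcmfit
Title: Allosteric Ternary Complex Analysis of Radioligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium models and nonlinear regression tools for
    radioligand binding pharmacology at G protein-coupled receptors.
    Implements closed-form saturation, four-parameter logistic (Hill)
    and allosteric ternary complex models (including the extended
    three-ligand form for radioligand + orthosteric competitor +
    allosteric modulator), Cheng-Prusoff conversion, global
    curve fitting in log-parameter space with deterministic multi-start,
    replicate aggregation as mean +/- SEM of individual experiments,
    extra-sum-of-squares model comparison, ANOVA/Tukey and t-test
    condition comparisons, a seeded synthetic-experiment generator for
    the standard assay designs, and an exact mass-action equilibrium
    solver used as an independent oracle for the closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
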