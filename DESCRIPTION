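Package: dietstat
Title: Stomach-Content Diet Analysis for Pelagic Fish Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative stomach-content analysis of pelagic
    fish surveys. Computes classical diet composition indices (vacuity,
    numerical and gravimetric composition, frequency of occurrence,
    prey-specific abundance and the prey-specific index of relative
    importance, PSIRI) and Amundsen feeding-strategy coordinates; performs
    distance-based multivariate comparisons of diet among years, areas and
    predator length groups (fourth-root transformation, Bray-Curtis
    dissimilarity, UPGMA clustering with Newick export, one-way, two-way
    and pairwise PERMANOVA, Kruskal-Wallis with Dunn's post hoc); and
    ranks additive models of log stomach weight against environmental and
    biological covariates by AIC with Akaike weights and 95% confidence
    sets. Includes a synthetic survey generator with a truth manifest so
    the full pipeline is testable without access to raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
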