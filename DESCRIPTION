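Package: colourpref
Title: Context-Dependent Colour Preference Analysis in CIE LCh Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for unrestricted colour-choice experiments in
    which participants pick their most and least preferred colours for
    several object contexts with a sequential colour-picker tool.  Converts
    device RGB or measured CIE xyY colour records into CIE LCh under an
    explicit reference white, bins hue angles into nine perceptual hue
    categories, and runs the study's statistical battery: multinomial
    bootstrap pairwise comparisons of hue-choice proportions with
    multiplicity-corrected confidence intervals and a compact letter
    display, Stuart-Maxwell marginal-homogeneity tests, Wilcoxon
    signed-rank tests, and 2 x 3 within-subject ANOVAs with
    Greenhouse-Geisser correction and Bonferroni post-hoc comparisons.
    Also ships a headless state-machine re-implementation of the colour
    picker with greedy simulated agents, and a seeded generator of
    synthetic participant datasets so that every pipeline stage is
    testable without access to raw experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
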