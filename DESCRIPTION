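Package: xylemCT
Title: Quantification of Xylem Embolism in MicroCT Stem Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify drought-induced xylem embolism in 2D
    phase-contrast microCT stem cross-sections. Provides segmentation of
    air-filled lumina into vessels and fibers by particle size and
    circularity, percent-embolized-area metrics over the xylem annulus,
    radial distribution profiles with a 95% cumulative-area threshold,
    per-vessel spatial association between embolized vessels and
    air-filled fibers via Euclidean region enlargement, multi-group
    comparisons (ANOVA with Waller-Duncan or Tukey letters,
    Kruskal-Wallis with Dunn/Benjamini-Hochberg), and a synthetic
    cross-section generator with ground-truth masks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
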