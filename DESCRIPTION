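Package: SABGquant
Title: Quantitative In Situ Senescence-Associated Beta-Galactosidase Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Digital image analysis of X-gal stained micrographs for the
    quantification of senescence-associated beta-galactosidase (SABG)
    activity. Computes per-region chromatic staining intensities (CSI, BSI)
    from RGB pixel ratios, standardizes each cell or renal tubule against an
    adjacent background patch, and summarizes staining as the logarithmic
    beta-galactosidase activity value (BGAV). Includes the accompanying
    statistical workflow (Shapiro-Wilk normality assessment, two-sample
    Kolmogorov-Smirnov distribution comparison, one-way ANOVA, Pearson
    chi-square on gamma-H2AX foci count tables, positivity classification of
    tissue tubules against control means), readers and writers for images,
    ImageJ ROI files and a CSV polygon dialect, a seeded synthetic
    stained-image generator with ground truth for end-to-end validation, and
    a batch pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    jpeg,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
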