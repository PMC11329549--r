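Package: frpecect
Title: Fibril-Reinforced Poroelastic Cartilage Models and Contrast-Enhanced CT Partition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward simulation of cartilage stress-relaxation indentation with a
    fibril-reinforced poroelastic (FRPE) material model on an axisymmetric
    displacement/pore-pressure finite-element mesh, inverse identification of the
    five constituent-specific FRPE parameters from measured force-time curves,
    contrast-enhanced micro-CT partition quantification including dual-energy
    material decomposition of cationic tantalum oxide nanoparticle and neutral
    iodixanol mixtures, synthetic-data generators with known ground truth for
    every pipeline input, and nonparametric cohort statistics (Spearman
    correlation, Mann-Whitney U, mean with 95% confidence intervals) with
    publication-style summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    lhs,
    jsonlite,
    RNifti,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
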