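Package: haplarith
Title: Trio-Based Haplarithmisis for Chromosomal Aberration Calling in
    SNP-Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs parental haplarithms from SNP-array data of
    family quartets (mother, father and two tissues of a product of
    conception) and calls chromosomal aberrations annotated with copy
    state, parental origin, segregational origin (meiosis I, meiosis II
    or mitotic) and mosaic fraction.  Parental genotypes are phased with
    the chorionic-villus genotype as a seed, phased B-allele frequencies
    are mirrored and segmented by exact piecewise-constant fitting, and
    the band separations of the paternal (P1/P2) and maternal (M1/M2)
    series are matched against allele-count templates.  Includes a
    synthetic quartet simulator with configurable aberrations, noise and
    maternal-cell contamination, readers and writers for
    GenomeStudio-style final reports and BED/JSON call files, and the
    cohort-level statistics used in pregnancy-loss studies (abnormality
    extrapolation, Welch and rank tests, Wilcoxon sample-size
    calculation and qPCR fold-change arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
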