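Package: subclonemix
Title: Two-Subclone Mixture Deconstruction of ddPCR Allele-Frequency and
    Copy-Number Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deconstructs intratumoral subclonal structure from droplet
    digital PCR (ddPCR) panels of allele frequencies (AF) and absolute
    copy numbers (CN) measured across many samples of the same tumor,
    as arises in patient-derived xenograft (PDX) treatment studies.
    Implements a two-subclone mixture model with integer genotype
    calling, subclone-genotype inference by linear extrapolation to
    anchor allele frequencies, per-sample mixing-fraction estimation,
    median-z-score and perpendicular-distance outlier (population
    bottleneck) detection, cohort-level selection statistics (Welch
    tests with Benjamini-Hochberg correction, correlation matrices,
    volume-change association), and a synthetic-data generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
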