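Package: idrscape
Title: Amyloidogenic and Low-Complexity Region Landscapes of Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and statistical characterization of amyloidogenic
    regions (ARs) and low-complexity regions (LCRs) in intrinsically
    disordered proteins. Provides a SEG-style windowed-entropy detector for
    low-complexity segments, a pluggable position-specific scoring matrix
    (PSSM) scanner for amyloidogenic hexapeptides, 1-based interval algebra
    for region content and overlap statistics, disorder-class stratification
    (PDP/MDP/LDP), amino-acid composition and secondary-structure preference
    profiling, alpha-stable distribution fitting of region lengths and
    contents, bivariate kernel density estimation, negative hyperbolic
    length-content regression, and a seeded synthetic-cohort generator with
    planted ground-truth regions so that every stage is testable without
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
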