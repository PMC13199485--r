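Package: cetime
Title: Timing of Convergence and Extension Morphogenesis from Expression,
    Shape and Cell-Track Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the onset and pace of convergence and
    extension (C&E) cell movements in zebrafish gastrulae and blastoderm
    explants. Implements a stage-resolved screen for "trigger" genes whose
    expression is flat before gastrulation onset and rises sharply at shield
    stage, paired-gene expression-ratio trajectories, explant roundness
    analysis with Boltzmann sigmoid fits (V50, slope) compared by the extra
    sum-of-squares F test, convergence kinetics from nuclear tracks
    (mediolateral displacement curves, hinge changepoint onset, persistence,
    speeds), and small quantification utilities (2^-ddCt relative expression,
    stable-isotope internal-standard disaccharide quantification, pairwise
    protein identity/similarity under BLOSUM62). A synthetic-data module
    generates inputs with the statistical structure each stage assumes, so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    seqinr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
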