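Package: rgcclock
Title: Divergence Dating with Rare Genomic Changes at Conserved Amino Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rare genomic changes associated with conserved amino
    acids (RGC_CAs) in per-gene protein alignments: columns where a unanimous
    prokaryotic outgroup fixes the ancestral state and a subset of eukaryotes
    shares a single derived residue. Detected characters are mapped onto a
    rooted species tree to obtain branch lengths in RGC_CA units with
    homoplasy accounting, and node ages are estimated by strict-clock maximum
    parsimony against fossil calibration points, with calibration
    cross-validation and molecular-clock diagnostics. Includes a synthetic
    sequence-evolution generator with ground-truth records for validating
    the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
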