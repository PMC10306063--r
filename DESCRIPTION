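Package: seqregister
Title: Sequence-Register Validation for Crystallographic Protein Models
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects sequence-assignment errors in protein models built into
    crystallographic electron density. Per-residue residue-type probability
    profiles derived from the map are re-aligned, without gaps, against the
    target sequences; each alignment is scored with a calibrated p-value (the
    probability that an alignment at least as good arises by chance under a
    random-sequence null). Sliding-window scans flag register shifts,
    residue-indexing issues, sequence mismatches and chains that cannot be
    assigned to any target. Includes a reference density-shell residue-type
    classifier, readers for mmCIF/PDB coordinates, FASTA sequences, CCP4/MRC
    maps and MTZ map coefficients, and a synthetic benchmark generator with
    ground-truth scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
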