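Package: cas12array
Title: Design and Analysis of Multiplexed Cas12a CRISPR Arrays with
    AT-Rich Synthetic Separators
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing multiplexed Cas12a CRISPR arrays that
    insulate adjacent guide RNAs with short AT-rich synthetic separators
    (synSeparators) placed upstream of every repeat. Includes sliding-window
    GC-content statistics and window-scan predictive-power analysis of
    spacer libraries, profiling of naturally occurring CRISPR separators
    (3'-anchored stacking, per-column GC, IUPAC consensus), secondary-
    structure interference scoring of spacers in array context through a
    pluggable thermodynamic folding backend, annotated array construction
    with per-site separator policies and post-processing fragment
    prediction, planning of oligonucleotide duplexing-and-ligation assembly
    (unique 4-nt overhangs, pot partitioning, In-Fusion flanks), and
    quantification of Cas12a processing efficiency from electropherogram
    peak tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
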