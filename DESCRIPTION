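Package: duetdap
Title: Differential Seq-DAP-Seq Binding Analysis for Paired Transcription
    Factor Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare genome-wide binding of two related
    transcription-factor complexes assayed by sequential DNA-affinity
    purification sequencing (seq-DAP-seq) in replicate.  The pipeline
    derives replicate-consensus peaks, merges the two complexes' peak
    sets, computes a coverage fold ratio (CFR) to call complex-specific
    regions, builds three classes of binding-site model (position weight
    matrix, first-order positional Markov model, and k-mer set memory)
    and evaluates them by AUROC against GC-, size- and origin-matched
    unbound backgrounds, detects preferred CArG-box intersite spacings,
    and computes gene-level term enrichment.  A synthetic-data generator
    with planted ground truth makes every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
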