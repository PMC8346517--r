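#!/usr/bin/env Rscript
# Generate the synthetic seq-DAP-seq study: a 1 Mb annotated genome with
# 260 shared and 40+40 complex-specific bound regions (CArG-box pairs at
# complex-specific spacings, complex-specific flanking k-mers) and
# triplicate coverage tracks for the reference complex (A) and the
# I-domain-swapped variant complex (B).
suppressPackageStartupMessages(library(duetdap))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 42L

out <- file.path("results", "data")
spec <- synth_spec(seed = seed)
ds <- generate_dataset(spec, out, overwrite = TRUE)

message("genome: ", sum(nchar(ds$genome$seq)), " bp; regions planted: ",
        nrow(ds$truth), " (", sum(ds$truth$class == "common"), " common, ",
        sum(ds$truth$class == "A_only"), " A-specific, ",
        sum(ds$truth$class == "B_only"), " B-specific)")
message("tracks: 2 complexes x ", spec$n_replicates, " replicates -> ", out)
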