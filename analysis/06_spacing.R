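#!/usr/bin/env Rscript
# CArG-box intersite spacing preferences within each complex's specific
# regions, called against a within-region positional-shuffle null.
suppressPackageStartupMessages(library(duetdap))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 42L

data_dir <- file.path("results", "data")
genome <- dap_genome(read_fasta(file.path(data_dir, "genome.fa")))

for (side in c("a", "b")) {
  regions <- read_intervals(file.path("results",
                                      sprintf("specific_%s.bed", side)),
                            "BED6")
  prof <- spacing_profile(regions, genome)
  prof <- call_preferred_spacings(prof, n_shuffles = 100L, z_min = 3,
                                  seed = seed + 30L + match(side, c("a", "b")))
  write.table(as.data.frame(prof),
              file.path("results", sprintf("spacing_%s.tsv", side)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(toupper(side), "-specific regions: preferred spacings ",
          if (length(prof$called)) paste(prof$called, collapse = ", ")
          else "none", " bp")
}
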