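#!/usr/bin/env Rscript
# Per-replicate peak calling, replicate consensus ("present in all
# replicates"), subpeak splitting, summit-centred +-200 bp resizing and
# reads-per-kb-per-million coverage annotation, for each complex.
suppressPackageStartupMessages(library(duetdap))

data_dir <- file.path("results", "data")
genome <- dap_genome(read_fasta(file.path(data_dir, "genome.fa")))

for (cx in c("a", "b")) {
  tracks <- lapply(sprintf("cov_%s_rep%d.bedGraph", cx, 1:3), function(f)
    read_coverage(file.path(data_dir, f), genome))
  peaks <- process_complex(tracks, genome)
  out <- file.path("results", sprintf("peaks_%s.narrowPeak", cx))
  write_intervals(peaks, out, "narrowPeak")
  write.table(peaks, file.path("results", sprintf("peaks_%s.tsv", cx)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(toupper(cx), ": ", nrow(peaks), " consensus peaks, mean width ",
          round(mean(peaks$end - peaks$start)), " bp -> ", out)
}
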