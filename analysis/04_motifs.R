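#!/usr/bin/env Rscript
# Build the three binding-site models per complex from its 600 best-bound
# peaks: width-16 palindromic PWM, first-order positional model, and KSM
# (k-mers 4-20 bp enriched against a GC/size/origin-matched unbound
# discovery background).
suppressPackageStartupMessages(library(duetdap))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 42L

data_dir <- file.path("results", "data")
bed <- read_intervals(file.path(data_dir, "categories.bed"), "BED6")
genome <- dap_genome(read_fasta(file.path(data_dir, "genome.fa")),
                     data.frame(chrom = bed$chrom, start = bed$start,
                                end = bed$end, category = bed$name,
                                stringsAsFactors = FALSE))

for (cx in c("a", "b")) {
  peaks <- read.table(file.path("results", sprintf("peaks_%s.tsv", cx)),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  best <- suppressWarnings(select_best_peaks(peaks, 600L))
  bg <- sample_matched_background(best, genome,
                                  seed = seed + match(cx, c("a", "b")))
  seqs <- vapply(seq_len(nrow(best)), function(i)
    substr(genome$seq[[best$chrom[i]]], best$start[i] + 1L, best$end[i]),
    character(1))
  bg_seqs <- vapply(seq_len(nrow(bg$discovery)), function(i)
    substr(genome$seq[[bg$discovery$chrom[i]]],
           bg$discovery$start[i] + 1L, bg$discovery$end[i]), character(1))

  pwm <- build_pwm(seqs)
  fom <- build_first_order(pwm_align_sites(pwm, seqs),
                           background = pwm$background)
  ksm <- discover_ksm(seqs, bg_seqs)

  mdir <- file.path("results", paste0("models_", cx))
  dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
  write_pwm_meme(pwm, file.path(mdir, "pwm.meme"))
  write_model_json(fom, file.path(mdir, "first_order.json"))
  write_model_json(ksm, file.path(mdir, "ksm.json"))
  cons <- paste(c("A", "C", "G", "T")[apply(pwm$probs, 2, which.max)],
                collapse = "")
  message(toupper(cx), ": trained on ", nrow(best),
          " best peaks; PWM consensus ", cons, "; KSM clusters: ",
          length(ksm$clusters))
}
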