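#!/usr/bin/env Rscript
# Cross-evaluate all six models (3 kinds x 2 complexes) on both specific
# sets against matched evaluation backgrounds; AUROC per cell.
suppressPackageStartupMessages(library(duetdap))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 42L

data_dir <- file.path("results", "data")
bed <- read_intervals(file.path(data_dir, "categories.bed"), "BED6")
genome <- dap_genome(read_fasta(file.path(data_dir, "genome.fa")),
                     data.frame(chrom = bed$chrom, start = bed$start,
                                end = bed$end, category = bed$name,
                                stringsAsFactors = FALSE))

region_seq <- function(df) vapply(seq_len(nrow(df)), function(i)
  substr(genome$seq[[df$chrom[i]]], df$start[i] + 1L, df$end[i]),
  character(1))
models <- function(cx) {
  mdir <- file.path("results", paste0("models_", cx))
  list(pwm = read_pwm_meme(file.path(mdir, "pwm.meme")),
       fom = read_model_json(file.path(mdir, "first_order.json")),
       ksm = read_model_json(file.path(mdir, "ksm.json")))
}
spec_regions <- function(side)
  read_intervals(file.path("results", sprintf("specific_%s.bed", side)),
                 "BED6")

sp_a <- spec_regions("a"); sp_b <- spec_regions("b")
bg_a <- sample_matched_background(sp_a, genome, seed = seed + 21L)
bg_b <- sample_matched_background(sp_b, genome, seed = seed + 22L)

auc <- cross_evaluate(models("a"), models("b"),
                      region_seq(sp_a), region_seq(sp_b),
                      region_seq(bg_a$evaluation),
                      region_seq(bg_b$evaluation))
write.table(auc, file.path("results", "auc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(auc, row.names = FALSE)
ks <- auc[auc$model == "KSM", ]
message("KSM self vs cross: A ",
        round(ks$auc[ks$trained_on == "A" &
                       ks$evaluated_on == "A_specific"], 3), " / ",
        round(ks$auc[ks$trained_on == "A" &
                       ks$evaluated_on == "B_specific"], 3),
        "; B ",
        round(ks$auc[ks$trained_on == "B" &
                       ks$evaluated_on == "B_specific"], 3), " / ",
        round(ks$auc[ks$trained_on == "B" &
                       ks$evaluated_on == "A_specific"], 3))
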