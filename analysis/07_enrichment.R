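#!/usr/bin/env Rscript
# Gene-level term enrichment for the most differentially bound regions
# on each side (nearest TSS within 3 kb of the summit; hypergeometric
# upper tail with BH correction).
suppressPackageStartupMessages(library(duetdap))

data_dir <- file.path("results", "data")
genes <- read_gene_models(file.path(data_dir, "genes.tsv"))
terms <- read_term_map(file.path(data_dir, "terms.tsv"))
merged <- read.table(file.path("results", "merged.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)

top_n <- 60L  # scaled to the demo merged-list size; genome-wide datasets use 250
for (side in c("a", "b")) {
  o <- if (side == "a") order(merged$cfr, merged$start)
       else order(-merged$cfr, merged$start)
  top <- merged[o[seq_len(min(top_n, nrow(merged)))], ]
  hits <- assign_peaks_to_genes(top, genes)
  enr <- term_enrichment(hits, terms, unique(genes$gene))
  write.table(enr, file.path("results", sprintf("enrich_%s.tsv", side)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lead <- enr[1, ]
  message(toupper(side), ": ", length(hits), " genes; top term ",
          lead$term, " fold ", round(lead$fold, 1), ", FDR ",
          signif(lead$fdr, 2))
}
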