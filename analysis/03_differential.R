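#!/usr/bin/env Rscript
# Merge the two complexes' peak sets, compute the coverage fold ratio
# (CFR = variant/reference mean normalised coverage), select the top-15%
# extreme-CFR regions per side, and draw the binding-intensity scatter.
suppressPackageStartupMessages(library(duetdap))

data_dir <- file.path("results", "data")
genome <- dap_genome(read_fasta(file.path(data_dir, "genome.fa")))
tracks <- function(cx) lapply(sprintf("cov_%s_rep%d.bedGraph", cx, 1:3),
                              function(f)
                                read_coverage(file.path(data_dir, f), genome))
ta <- tracks("a"); tb <- tracks("b")
peaks <- function(cx)
  read.table(file.path("results", sprintf("peaks_%s.tsv", cx)),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)

merged <- merge_peak_sets(peaks("a"), peaks("b"), ta, tb)
merged <- compute_cfr(merged)
write.table(merged, file.path("results", "merged.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sp <- select_specific(merged, 0.15)
for (side in c("a", "b")) {
  s <- sp[[paste0(side, "_specific")]]
  write_intervals(data.frame(chrom = s$chrom, start = s$start, end = s$end,
                             name = s$class, score = s$cfr),
                  file.path("results", sprintf("specific_%s.bed", side)),
                  "BED6")
}
message(nrow(merged), " merged regions (",
        sum(merged$class == "common"), " common); ",
        nrow(sp$a_specific), " per specific set")

# binding-intensity comparison, coloured by log10 CFR
if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create(file.path("results", "figures"), showWarnings = FALSE)
  gg <- ggplot2::ggplot(merged,
    ggplot2::aes(log10_intensity_a, log10_intensity_b,
                 colour = log10(cfr))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradient2(low = "darkorange", mid = "grey60",
                                    high = "purple3", midpoint = 0) +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::labs(x = "log10 intensity, complex A",
                  y = "log10 intensity, complex B",
                  colour = "log10 CFR") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path("results", "figures", "intensity_scatter.pdf"),
                  gg, width = 5, height = 4)
  message("figure -> results/figures/intensity_scatter.pdf")
}
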