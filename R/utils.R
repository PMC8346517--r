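#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois rgamma rnorm runif quantile sd phyper p.adjust
#'   setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

## Coordinates are 0-based half-open [start, end) everywhere in this package;
## conversion to/from other conventions happens only at I/O boundaries.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet ACGTN (N maps to N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", stringi::stri_reverse(x))
}

#' GC content of DNA strings
#'
#' Fraction of G+C among non-N bases.  Returns `NA` for sequences that are
#' all N (or empty).
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return numeric vector of GC fractions in \[0, 1\].
#' @export
gc_content <- function(x) {
  gc <- stringi::stri_count_regex(x, "[GCgc]")
  at <- stringi::stri_count_regex(x, "[ATat]")
  ifelse(gc + at == 0L, NA_real_, gc / (gc + at))
}

## bp overlap of [s1,e1) with [s2,e2); vectorised
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

## order a chrom/start/end data.frame by (chrom, start, end)
order_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

is_sorted_intervals <- function(df) {
  o <- order(df$chrom, df$start, df$end)
  identical(o, seq_len(nrow(df)))
}

## Extract a subsequence from a genome; 0-based half-open coordinates.
genome_seq <- function(genome, chrom, start, end) {
  s <- genome$seq[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  substring(s, start + 1L, end)
}

## Extract sequences for a chrom/start/end data.frame.
region_seqs <- function(genome, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    genome_seq(genome, regions$chrom[i], regions$start[i], regions$end[i])
  }, character(1))
}

chrom_length <- function(genome, chrom) {
  s <- genome$seq[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  nchar(s)
}

## Derive a stage seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, stage) {
  (seed * 101L + stage * 7919L) %% 2000000011L %% 2147483647L
}
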