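## Gene-level term enrichment for differentially bound regions: peaks
## are assigned to the gene with the nearest TSS, and term membership is
## tested with the hypergeometric upper tail plus Benjamini-Hochberg
## correction.

#' Assign peaks to genes by nearest TSS
#'
#' Each peak is assigned to the gene whose TSS is nearest to the peak
#' summit (midpoint when no summit is present), provided the distance is
#' at most `max_distance`; exact ties assign all tied genes.  Peaks with
#' no gene in range stay unassigned.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` and optionally
#'   `summit`.
#' @param gene_models data.frame with `gene`, `chrom`, `tss`.
#' @param max_distance maximum summit-TSS distance in bp (default 3000).
#' @return character vector of unique assigned gene ids.
#' @export
assign_peaks_to_genes <- function(peaks, gene_models, max_distance = 3000L) {
  if (nrow(peaks) == 0L) return(character(0))
  summit <- if ("summit" %in% names(peaks) && !all(is.na(peaks$summit)))
    peaks$summit else (peaks$start + peaks$end) %/% 2L
  hits <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- gene_models[gene_models$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) return(character(0))
    dist <- abs(g$tss - summit[i])
    dmin <- min(dist)
    if (dmin > max_distance) return(character(0))
    g$gene[dist == dmin]
  })
  unique(unlist(hits))
}

#' Hypergeometric term enrichment with BH correction
#'
#' For every term with at least one universe gene: `k` study genes in
#' the term out of `n` study genes, against `K` universe genes in the
#' term out of `N`; `fold = (k/n)/(K/N)` and `p = P(X >= k)`
#' (hypergeometric upper tail), BH-adjusted across all tested terms.
#'
#' @param study_genes character vector of study gene ids (must be a
#'   subset of `universe`).
#' @param term_map data.frame with columns `term`, `gene`.
#' @param universe character vector of all gene ids.
#' @return data.frame with `term`, `k`, `n`, `K`, `N`, `fold`, `p`,
#'   `fdr`, sorted by `fdr` then `p`.
#' @export
term_enrichment <- function(study_genes, term_map, universe) {
  study_genes <- unique(study_genes)
  universe <- unique(universe)
  if (!all(study_genes %in% universe))
    stop("study genes must be a subset of the universe")
  term_map <- term_map[term_map$gene %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(study_genes)
  terms <- unique(term_map$term)
  rows <- lapply(terms, function(tm) {
    members <- unique(term_map$gene[term_map$term == tm])
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- sum(study_genes %in% members)
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               fold = (k / n) / (K / N),
               p = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), fold = numeric(0),
                      p = numeric(0), fdr = numeric(0)))
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(out$fdr, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a TSS table
#'
#' Tab-separated with header columns `gene`, `chrom`, `tss` and
#' optionally `strand`.
#'
#' @param path TSV path.
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (!all(c("gene", "chrom", "tss") %in% names(df)))
    stop("gene model table needs columns gene, chrom, tss")
  df
}

#' Read a term-to-gene map
#'
#' Two-column tab-separated file (term, gene), no header.
#'
#' @param path TSV path.
#' @return data.frame with columns `term`, `gene`.
#' @export
read_term_map <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("term", "gene"),
                   stringsAsFactors = FALSE)
  df
}
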