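## Merge the two complexes' peak sets, compute the coverage fold ratio
## (CFR) and select complex-specific regions and best-bound training
## peaks.

#' Merge two complexes' resized peak sets
#'
#' For each overlapping pair the overlap fraction of each peak
#' (overlap / own length) is computed.  Pairs with both fractions > 0.5
#' merge into one `common` entry over the union interval (pairs formed
#' greedily by descending overlap, ties leftmost); `high_confidence`
#' records whether the larger fraction reached 0.8.  Every other peak
#' becomes a set-specific entry (`A_only` / `B_only`) over its own
#' interval (for those, `high_confidence` means its maximal overlap
#' fraction with the other set is <= 0.2).  Mean normalised coverage of
#' both complexes is recomputed over each entry's interval.
#'
#' @param peaks_a,peaks_b annotated peak data.frames (sorted), complexes
#'   A (reference) and B (variant).
#' @param tracks_a,tracks_b replicate track lists used to recompute
#'   coverage over merged intervals.
#' @param common_min both-fraction threshold for a common call (0.5).
#' @param common_high fraction defining high confidence (0.8).
#' @return data.frame of merged peaks with columns `chrom`, `start`,
#'   `end`, `class`, `high_confidence`, `cov_a`, `cov_b`.
#' @export
merge_peak_sets <- function(peaks_a, peaks_b, tracks_a, tracks_b,
                            common_min = 0.5, common_high = 0.8) {
  if (!is_sorted_intervals(peaks_a) || !is_sorted_intervals(peaks_b))
    stop("peak sets must be sorted by (chrom, start, end)")
  na <- nrow(peaks_a); nb <- nrow(peaks_b)
  ## all overlapping pairs
  pairs <- NULL
  if (na > 0L && nb > 0L) {
    pairs <- do.call(rbind, lapply(seq_len(na), function(i) {
      ov <- ifelse(peaks_b$chrom == peaks_a$chrom[i],
                   overlap_bp(peaks_a$start[i], peaks_a$end[i],
                              peaks_b$start, peaks_b$end), 0L)
      j <- which(ov > 0L)
      if (length(j) == 0L) return(NULL)
      data.frame(i = i, j = j, ov = ov[j])
    }))
  }
  used_a <- logical(na); used_b <- logical(nb)
  common <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    pairs$fa <- pairs$ov / (peaks_a$end[pairs$i] - peaks_a$start[pairs$i])
    pairs$fb <- pairs$ov / (peaks_b$end[pairs$j] - peaks_b$start[pairs$j])
    cand <- pairs[pairs$fa > common_min & pairs$fb > common_min, ,
                  drop = FALSE]
    cand <- cand[order(-cand$ov, peaks_a$chrom[cand$i],
                       peaks_a$start[cand$i], peaks_b$start[cand$j]), ,
                 drop = FALSE]
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (used_a[cand$i[r]] || used_b[cand$j[r]]) next
      used_a[cand$i[r]] <- TRUE
      used_b[cand$j[r]] <- TRUE
      keep[r] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) > 0L)
      common <- data.frame(
        chrom = peaks_a$chrom[cand$i],
        start = pmin(peaks_a$start[cand$i], peaks_b$start[cand$j]),
        end = pmax(peaks_a$end[cand$i], peaks_b$end[cand$j]),
        class = "common",
        high_confidence = pmax(cand$fa, cand$fb) >= common_high,
        stringsAsFactors = FALSE)
  }
  max_frac <- function(idx, pairs, col, used) {
    f <- numeric(length(idx))
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      for (r in seq_len(nrow(pairs))) {
        k <- match(pairs[[col]][r], idx)
        if (!is.na(k))
          f[k] <- max(f[k], pairs[[if (col == "i") "fa" else "fb"]][r])
      }
    }
    f
  }
  specific <- function(peaks, used, col, cls) {
    idx <- which(!used)
    if (length(idx) == 0L) return(NULL)
    data.frame(chrom = peaks$chrom[idx], start = peaks$start[idx],
               end = peaks$end[idx], class = cls,
               high_confidence = max_frac(idx, pairs, col, used) <=
                 1 - common_high,
               stringsAsFactors = FALSE)
  }
  merged <- rbind(common,
                  specific(peaks_a, used_a, "i", "A_only"),
                  specific(peaks_b, used_b, "j", "B_only"))
  if (is.null(merged))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), class = character(0),
                      high_confidence = logical(0), cov_a = numeric(0),
                      cov_b = numeric(0)))
  merged <- order_intervals(merged)
  rownames(merged) <- NULL
  merged$cov_a <- mean_normalised_coverage(merged, tracks_a)
  merged$cov_b <- mean_normalised_coverage(merged, tracks_b)
  merged
}

## Mean over replicates of normalised coverage over intervals; the
## complex's "reads mapped in bound regions" total is the per-replicate
## sum over these merged intervals.
mean_normalised_coverage <- function(regions, tracks) {
  covs <- vapply(tracks, function(tr) {
    cnt <- region_counts(tr, regions)
    normalize_counts(cnt, regions$end - regions$start, sum(cnt))
  }, numeric(nrow(regions)))
  rowMeans(matrix(covs, nrow = nrow(regions)))
}

#' Coverage fold ratio (CFR)
#'
#' `cfr = (cov_b + eps) / (cov_a + eps)`: the variant complex's mean
#' normalised coverage over the reference complex's, with a pseudocount
#' guarding zero coverage.  Also fills `log10_intensity_a/_b`.
#'
#' @param merged merged peak data.frame from [merge_peak_sets()].
#' @param pseudocount stabilising pseudocount (default 0.01).
#' @return `merged` with columns `cfr`, `log10_intensity_a`,
#'   `log10_intensity_b`.
#' @export
compute_cfr <- function(merged, pseudocount = 0.01) {
  if (any(merged$cov_a < 0) || any(merged$cov_b < 0))
    stop("negative coverage")
  merged$cfr <- (merged$cov_b + pseudocount) / (merged$cov_a + pseudocount)
  merged$log10_intensity_a <- log10(merged$cov_a + pseudocount)
  merged$log10_intensity_b <- log10(merged$cov_b + pseudocount)
  merged
}

#' Select complex-specific regions by extreme CFR
#'
#' Entries are sorted by CFR; the lowest `ceiling(fraction * N)` (bound
#' more strongly by the reference complex A) form `a_specific` and the
#' highest form `b_specific`.  Ties are broken by larger |log10 CFR|,
#' then leftmost coordinate.
#'
#' @param merged merged peaks with `cfr` computed.
#' @param fraction tail fraction per side, in (0, 0.5] (default 0.15).
#' @return list with `a_specific` and `b_specific` data.frames (disjoint).
#' @export
select_specific <- function(merged, fraction = 0.15) {
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must be in (0, 0.5]")
  if (is.null(merged$cfr)) stop("cfr not computed")
  k <- ceiling(fraction * nrow(merged))
  o_low <- order(merged$cfr, -abs(log10(merged$cfr)), merged$chrom,
                 merged$start)
  o_high <- order(-merged$cfr, -abs(log10(merged$cfr)), merged$chrom,
                  merged$start)
  a_idx <- o_low[seq_len(k)]
  b_idx <- setdiff(o_high, a_idx)[seq_len(min(k, nrow(merged) - k))]
  list(a_specific = merged[a_idx, , drop = FALSE],
       b_specific = merged[b_idx, , drop = FALSE],
       fraction = fraction)
}

#' Select the best-bound peaks of a complex
#'
#' Top `n` peaks by mean normalised coverage (ties leftmost); used as
#' model-training sequences.
#'
#' @param peak_set annotated peak data.frame with `mean_coverage`.
#' @param n number of peaks (default 600).
#' @return data.frame of the selected peaks.
#' @export
select_best_peaks <- function(peak_set, n = 600L) {
  if (n <= 0L) stop("n must be > 0")
  if (n > nrow(peak_set)) {
    warning("fewer than ", n, " peaks; returning all ", nrow(peak_set))
    n <- nrow(peak_set)
  }
  o <- order(-peak_set$mean_coverage, peak_set$chrom, peak_set$start)
  peak_set[o[seq_len(n)], , drop = FALSE]
}
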