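## From per-replicate coverage to consensus, subpeak-split, fixed-width,
## coverage-annotated peaks per complex.  The upstream caller (a
## threshold-run scanner) and the replicate-consensus rule are simple,
## declared stand-ins for a full model-based peak caller and combined
## replicate statistics; everything downstream of them follows the
## analysis exactly.

#' Call peaks on a coverage track by threshold runs
#'
#' A peak is a maximal run of bases with signal >= `min_height` of length
#' >= `min_width`; its summit is the leftmost position of maximum signal.
#'
#' @param track a [dap_track].
#' @param min_height minimum per-base signal (> 0).
#' @param min_width minimum run length in bp.
#' @return data.frame with columns `chrom`, `start`, `end`, `summit`,
#'   `summit_height`, sorted by (chrom, start).
#' @export
call_peaks <- function(track, min_height, min_width = 50L) {
  if (min_height <= 0) stop("min_height must be > 0")
  out <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    r <- rle(v >= min_height)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_width
    if (!any(keep)) return(NULL)
    starts <- starts[keep]; ends <- ends[keep]
    summit <- vapply(seq_along(starts), function(i) {
      w <- v[(starts[i] + 1L):ends[i]]
      starts[i] + which.max(w) - 1L
    }, integer(1))
    data.frame(chrom = ch, start = starts, end = ends, summit = summit,
               summit_height = v[summit + 1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      summit_height = numeric(0))
  order_intervals(out)
}

#' Replicate-consensus peaks
#'
#' A peak from the first replicate is kept iff it overlaps (>= 1 bp) a
#' peak in every other replicate.  The reported entry is the overlapping
#' peak with the highest summit signal among the replicates, so a
#' well-defined summit survives for resizing.
#'
#' @param replicate_peak_lists list (length >= 2) of peak data.frames as
#'   returned by [call_peaks()].
#' @return consensus peak data.frame, same columns as [call_peaks()].
#' @export
consensus_peaks <- function(replicate_peak_lists) {
  if (length(replicate_peak_lists) < 2L)
    stop("need at least 2 replicate peak lists")
  if (any(vapply(replicate_peak_lists, nrow, 0L) == 0L)) {
    warning("a replicate has no peaks; consensus is empty")
    return(replicate_peak_lists[[1]][0, , drop = FALSE])
  }
  ref <- replicate_peak_lists[[1]]
  others <- replicate_peak_lists[-1]
  kept <- lapply(seq_len(nrow(ref)), function(i) {
    group <- ref[i, , drop = FALSE]
    for (other in others) {
      ov <- other$chrom == ref$chrom[i] &
        overlap_bp(ref$start[i], ref$end[i], other$start, other$end) > 0L
      if (!any(ov)) return(NULL)
      group <- rbind(group, other[ov, , drop = FALSE])
    }
    best <- which.max(group$summit_height)  # leftmost listed on ties
    group[best, , drop = FALSE]
  })
  kept <- kept[!vapply(kept, is.null, logical(1))]
  if (length(kept) == 0L) return(ref[0, , drop = FALSE])
  out <- unique(do.call(rbind, kept))
  rownames(out) <- NULL
  order_intervals(out)
}

#' Split a peak at pronounced valleys
#'
#' The peak's signal profile is scanned for local minima lying below
#' `valley_fraction` times the smaller of the two flanking local maxima;
#' the peak is split at every such minimum (leftmost base of the valley)
#' and each part's summit is recomputed.  Unimodal profiles are returned
#' unchanged.
#'
#' @param peak one-row data.frame with `chrom`, `start`, `end`.
#' @param track a [dap_track] covering the peak.
#' @param valley_fraction valley depth threshold (default 0.5).
#' @return data.frame of sub-peaks with `chrom`, `start`, `end`,
#'   `summit`, `summit_height`.
#' @export
split_subpeaks <- function(peak, track, valley_fraction = 0.5) {
  v <- track$values[[peak$chrom]][(peak$start + 1L):peak$end]
  n <- length(v)
  r <- rle(v)
  k <- length(r$values)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths  # 0-based within peak
  ## classify runs as local maxima / minima (plateau-aware)
  kind <- character(k)
  for (j in seq_len(k)) {
    left <- if (j > 1L) r$values[j - 1L] else -Inf
    right <- if (j < k) r$values[j + 1L] else -Inf
    kind[j] <- if (r$values[j] > left && r$values[j] > right) "max"
               else if (r$values[j] < left && r$values[j] < right) "min"
               else "other"
  }
  ## boundary runs flanked on one side only: treat as maxima candidates
  maxima <- which(kind == "max")
  minima <- which(kind == "min")
  cuts <- integer(0)
  for (m in minima) {
    lmax <- maxima[maxima < m]
    rmax <- maxima[maxima > m]
    if (length(lmax) == 0L || length(rmax) == 0L) next
    flank <- min(r$values[max(lmax)], r$values[min(rmax)])
    if (r$values[m] < valley_fraction * flank)
      cuts <- c(cuts, run_start[m])
  }
  bounds <- c(0L, sort(cuts), n)
  out <- lapply(seq_len(length(bounds) - 1L), function(j) {
    lo <- bounds[j]; hi <- bounds[j + 1L]
    w <- v[(lo + 1L):hi]
    s <- lo + which.max(w) - 1L
    data.frame(chrom = peak$chrom, start = peak$start + lo,
               end = peak$start + hi, summit = peak$start + s,
               summit_height = max(w), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Resize peaks to a fixed window around the summit
#'
#' Each interval becomes \[summit - flank, summit + flank + 1), clipped to
#' the chromosome; interior peaks have width `2 * flank + 1` (401 bp at
#' the default).
#'
#' @param peaks peak data.frame with a `summit` column.
#' @param genome a [dap_genome] for clipping.
#' @param flank half-width in bp (default 200).
#' @return the peaks with `start`/`end` replaced.
#' @export
resize_peaks <- function(peaks, genome, flank = 200L) {
  if (nrow(peaks) == 0L) return(peaks)
  len <- vapply(peaks$chrom, function(ch) chrom_length(genome, ch), 0L)
  peaks$start <- pmax(0L, peaks$summit - flank)
  peaks$end <- pmin(len, peaks$summit + flank + 1L)
  order_intervals(peaks)
}

#' Normalise a read count to reads per kb per million
#'
#' `count / ((length/1000) * (total/1e6))` where `total` is the number of
#' reads mapped in bound regions — the per-replicate sum of counts over
#' the complex's final peak list.
#'
#' @param count reads in the region.
#' @param region_length_bp region length (> 0).
#' @param total_reads total reads in bound regions (> 0).
#' @return normalised coverage (reads per kb per million).
#' @export
normalize_counts <- function(count, region_length_bp, total_reads) {
  if (any(region_length_bp <= 0)) stop("region length must be > 0")
  if (any(total_reads <= 0)) stop("total reads must be > 0")
  count / ((region_length_bp / 1000) * (total_reads / 1e6))
}

## Summed coverage of a track over intervals.
region_counts <- function(track, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    v <- track$values[[regions$chrom[i]]]
    sum(v[(regions$start[i] + 1L):regions$end[i]])
  }, 0)
}

#' Annotate peaks with per-replicate normalised coverage
#'
#' For each replicate, read counts over the peaks are summed and
#' normalised to reads per kb per million of reads mapped in bound
#' regions (the peak list itself defines "bound regions").
#'
#' @param peaks resized peak data.frame.
#' @param tracks list of replicate [dap_track] objects.
#' @return the peaks with columns `cov_rep<i>` and `mean_coverage`.
#' @export
annotate_peak_coverage <- function(peaks, tracks) {
  if (nrow(peaks) == 0L) {
    peaks$mean_coverage <- numeric(0)
    return(peaks)
  }
  covs <- vapply(tracks, function(tr) {
    cnt <- region_counts(tr, peaks)
    normalize_counts(cnt, peaks$end - peaks$start, sum(cnt))
  }, numeric(nrow(peaks)))
  covs <- matrix(covs, nrow = nrow(peaks))
  colnames(covs) <- sprintf("cov_rep%d", seq_along(tracks))
  peaks <- cbind(peaks, covs)
  peaks$mean_coverage <- rowMeans(covs)
  peaks
}

#' Full peak-processing stage for one complex
#'
#' Per-replicate threshold peak calling, replicate consensus, subpeak
#' splitting on the replicate-mean track, summit-centred resizing, and
#' coverage annotation.
#'
#' @param tracks list of replicate [dap_track] objects (>= 2).
#' @param genome a [dap_genome].
#' @param min_height,min_width peak-calling thresholds.
#' @param flank resize half-width (default 200).
#' @param valley_fraction subpeak valley threshold.
#' @return annotated peak data.frame (see [annotate_peak_coverage()]).
#' @export
process_complex <- function(tracks, genome, min_height = 5, min_width = 50L,
                            flank = 200L, valley_fraction = 0.5) {
  per_rep <- lapply(tracks, call_peaks, min_height = min_height,
                    min_width = min_width)
  cons <- consensus_peaks(per_rep)
  if (nrow(cons) == 0L) return(annotate_peak_coverage(cons, tracks))
  mean_track <- dap_track(stats::setNames(lapply(names(genome$seq), function(ch)
    Reduce(`+`, lapply(tracks, function(t) t$values[[ch]])) / length(tracks)),
    names(genome$seq)))
  split <- do.call(rbind, lapply(seq_len(nrow(cons)), function(i)
    split_subpeaks(cons[i, , drop = FALSE], mean_track, valley_fraction)))
  resized <- resize_peaks(split, genome, flank)
  annotate_peak_coverage(resized, tracks)
}
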