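## CArG-box detection and intersite-spacing preference analysis.  MADS
## complexes bind pairs of CArG boxes (consensus CC(A/T)6GG, a family
## that is its own reverse complement); cooperative tetramer binding
## shows up as enrichment of particular start-to-start distances between
## the two boxes of a bound region.

#' Find CArG-box sites in a sequence
#'
#' Every 10-bp window is compared against the consensus family
#' CC(A/T)6GG; windows with at most `max_mismatch` deviating positions
#' are reported.  The family is strand-symmetric, so single-strand
#' scanning gives all (unique) site positions; windows containing N
#' never match.
#'
#' @param sequence DNA string over ACGTN.
#' @param max_mismatch maximum mismatches to the consensus (default 1).
#' @return data.frame with `position` (0-based window start) and
#'   `n_mismatch`.
#' @export
find_carg_sites <- function(sequence, max_mismatch = 1L) {
  x <- base_codes(sequence)
  n <- length(x)
  m <- n - 10L + 1L
  empty <- data.frame(position = integer(0), n_mismatch = integer(0))
  if (m < 1L) return(empty)
  idx <- outer(seq_len(m), 0L:9L, `+`)
  M <- matrix(x[idx], nrow = m)
  ## allowed codes per position: 1-2 C(1), 3-8 A(0)/T(3), 9-10 G(2)
  mism <- (M[, 1L] != 1L) + (M[, 2L] != 1L) +
    rowSums(M[, 3:8, drop = FALSE] != 0L & M[, 3:8, drop = FALSE] != 3L) +
    (M[, 9L] != 2L) + (M[, 10L] != 2L)
  mism[is.na(rowSums(M))] <- NA
  hit <- which(!is.na(mism) & mism <= max_mismatch)
  if (length(hit) == 0L) return(empty)
  data.frame(position = hit - 1L, n_mismatch = as.integer(mism[hit]))
}

## distance counts (start-to-start, within d_range) of all site pairs in
## one vector of site positions
pair_distance_counts <- function(positions, d_range) {
  d <- d_range[1]:d_range[2]
  counts <- integer(length(d))
  if (length(positions) >= 2L) {
    dist <- as.vector(dist(positions, method = "manhattan"))
    dist <- dist[dist >= d_range[1] & dist <= d_range[2]]
    if (length(dist))
      counts <- counts + tabulate(dist - d_range[1] + 1L,
                                  nbins = length(d))
  }
  counts
}

#' Intersite-spacing profile of a region set
#'
#' For each region all pairs of detected CArG sites are enumerated; each
#' pair contributes one count at its start-to-start distance if that
#' distance lies within `d_range`.  Pairs never span region boundaries.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param genome a [dap_genome].
#' @param max_mismatch CArG matcher tolerance (default 1).
#' @param d_range inclusive distance range in bp (default c(10, 100)).
#' @return object of class `dap_spacing`: list with `d`, `count`,
#'   `site_counts` (sites per region), `region_lengths`, plus slots
#'   filled by [call_preferred_spacings()].
#' @export
spacing_profile <- function(regions, genome, max_mismatch = 1L,
                            d_range = c(10L, 100L)) {
  d <- d_range[1]:d_range[2]
  count <- integer(length(d))
  site_counts <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- genome_seq(genome, regions$chrom[i], regions$start[i],
                    regions$end[i])
    sites <- find_carg_sites(s, max_mismatch)
    site_counts[i] <- nrow(sites)
    count <- count + pair_distance_counts(sites$position, d_range)
  }
  structure(list(d = d, count = count, site_counts = site_counts,
                 region_lengths = regions$end - regions$start,
                 d_range = d_range, max_mismatch = max_mismatch,
                 expected = NULL, sd = NULL, z = NULL, called = NULL),
            class = "dap_spacing")
}

## +-1 bp moving-average smoothing
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- (c(x[-1], 0) + x + c(0, x[-n]))
  out / c(2, rep(3, n - 2L), 2)
}

#' Call preferred intersite spacings against a positional-shuffle null
#'
#' The null redraws each region's site positions uniformly within the
#' region (site counts preserved), `n_shuffles` times; per-distance mean
#' and SD of the null counts give a z-score for the observed counts
#' (counts smoothed by +-1 bp first).  Preferred spacings are local
#' maxima of the z profile with `z >= z_min`, reported in descending z.
#'
#' @param observed a [spacing_profile()] result.
#' @param n_shuffles null replicates (>= 10, default 100).
#' @param z_min call threshold (default 3).
#' @param seed integer seed.
#' @return the profile with `expected`, `sd`, `z` and `called` filled.
#' @export
call_preferred_spacings <- function(observed, n_shuffles = 100L, z_min = 3,
                                    seed = 1L) {
  if (n_shuffles < 10L) stop("n_shuffles must be >= 10")
  set.seed(seed)
  d_range <- observed$d_range
  nd <- length(observed$d)
  null_counts <- matrix(0L, nrow = n_shuffles, ncol = nd)
  for (r in seq_len(n_shuffles)) {
    cnt <- integer(nd)
    for (i in seq_along(observed$site_counts)) {
      ns <- observed$site_counts[i]
      if (ns < 2L) next
      span <- observed$region_lengths[i] - 10L
      pos <- sample.int(span + 1L, ns, replace = TRUE) - 1L
      cnt <- cnt + pair_distance_counts(pos, d_range)
    }
    null_counts[r, ] <- cnt
  }
  null_smooth <- t(apply(null_counts, 1L, smooth3))
  obs_smooth <- smooth3(observed$count)
  expected <- colMeans(null_smooth)
  ## SD floored at 0.5 pair so distances the null never populates cannot
  ## produce infinite z from a single stray pair
  sdv <- pmax(apply(null_smooth, 2L, sd), 0.5)
  z <- (obs_smooth - expected) / sdv
  ## one call per contiguous run of z >= z_min: smoothing smears a sharp
  ## planted distance over +-1 bp, so within a run the raw-count maximum
  ## (ties: larger z, then smaller d) marks the preferred spacing
  above <- z >= z_min
  called <- integer(0)
  zcall <- numeric(0)
  if (any(above)) {
    run <- cumsum(c(TRUE, diff(above) != 0L))
    for (g in unique(run[above])) {
      j <- which(run == g & above)
      best <- j[order(-observed$count[j], -z[j], observed$d[j])][1]
      called <- c(called, observed$d[best])
      zcall <- c(zcall, max(z[j]))
    }
    called <- called[order(-zcall)]
  }
  observed$expected <- expected
  observed$sd <- sdv
  observed$z <- z
  observed$called <- called
  observed
}

#' @export
print.dap_spacing <- function(x, ...) {
  cat("dap_spacing: distances", x$d_range[1], "-", x$d_range[2], "bp,",
      sum(x$count), "pairs\n")
  if (!is.null(x$called))
    cat("called preferred spacings:",
        if (length(x$called)) paste(x$called, collapse = ", ") else "none",
        "\n")
  invisible(x)
}

#' Spacing profile as a data.frame
#'
#' @param x a `dap_spacing`.
#' @param ... unused.
#' @return data.frame with `d`, `count` and, when called, `expected`,
#'   `sd`, `z`, `called`.
#' @export
as.data.frame.dap_spacing <- function(x, ...) {
  out <- data.frame(d = x$d, count = x$count)
  if (!is.null(x$z)) {
    out$expected <- x$expected
    out$sd <- x$sd
    out$z <- x$z
    out$called <- x$d %in% x$called
  }
  out
}
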