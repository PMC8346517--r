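## The three binding-site model classes compared by the pipeline:
##   - PWM: width-16 palindromic position weight matrix found by a
##     deterministic seeded-refinement scheme (single motif),
##   - first-order positional Markov model (a declared simplified
##     stand-in for transcription-factor flexible models),
##   - KSM (k-mer set memory): clusters of aligned k-mers (4-20 bp)
##     enriched in bound vs unbound sequences, scored as the sum of
##     matched cluster scores.

BASES <- c("A", "C", "G", "T")

## base codes A=0 C=1 G=2 T=3, NA for anything else
base_codes <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  function(s) lut[utf8ToInt(s)]
})

## Encode all k-mer windows of a sequence as base-4 doubles (exact up to
## k = 20 since 4^20 < 2^53).  Returns list(fwd, rc, start) with NA-window
## rows removed; `start` is the 0-based window offset.
encode_windows <- function(s, k) {
  x <- base_codes(s)
  m <- length(x) - k + 1L
  if (m < 1L) return(list(fwd = numeric(0), rc = numeric(0),
                          start = integer(0)))
  idx <- outer(seq_len(m), 0L:(k - 1L), `+`)
  M <- matrix(x[idx], nrow = m)
  ok <- !is.na(rowSums(M))
  M <- M[ok, , drop = FALSE]
  pow_desc <- 4^((k - 1L):0L)
  pow_asc <- 4^(0L:(k - 1L))
  list(fwd = as.numeric(M %*% pow_desc),
       rc = as.numeric((3L - M) %*% pow_asc),
       start = which(ok) - 1L)
}

decode_kmer <- function(code, k) {
  out <- character(length(code))
  for (i in seq_along(code)) {
    c0 <- code[i]
    b <- integer(k)
    for (j in k:1) {
      b[j] <- c0 %% 4
      c0 <- (c0 - b[j]) / 4
    }
    out[i] <- paste(BASES[b + 1L], collapse = "")
  }
  out
}

## ---------------------------------------------------------------------
## PWM

#' Build a position weight matrix by seeded refinement
#'
#' Seeding: the most over-represented 8-mers relative to the 0-order
#' background composition are taken as candidate seeds (near-duplicate
#' seeds sharing a long exact overlap are collapsed; ties break by
#' lexicographic k-mer).  Each candidate is placed in the centre of a
#' width-`width` matrix and refined: align each sequence's single best
#' window on either strand against the current log-odds matrix, then
#' re-estimate column frequencies with a pseudocount; with
#' `palindromic = TRUE` the matrix is averaged with its own reverse
#' complement each iteration; stop at an alignment fixpoint or
#' `max_iter`.  The refined model with the highest median best-window
#' log-odds over the sequences wins (majority support beats a
#' sporadically over-represented word), and a final +-4-column register
#' scan re-refines shifted copies of the winner, compared by mean
#' best-window score.  Fully deterministic.
#'
#' @param sequences character vector (>= 20 sequences, each >= `width`).
#' @param width motif width (default 16).
#' @param palindromic enforce reverse-complement symmetry (default TRUE).
#' @param pseudocount added per base per column (default 0.25).
#' @param max_iter refinement cap per seed (default 50).
#' @param n_seeds candidate seeds entering the beam search (default 16).
#' @param beam seeds refined to convergence after the short first pass
#'   (default 3).
#' @return object of class `dap_pwm`: list with `width`, `probs`
#'   (4 x width, rows ACGT), `background`, `pseudocount`, `palindromic`.
#' @export
build_pwm <- function(sequences, width = 16L, palindromic = TRUE,
                      pseudocount = 0.25, max_iter = 50L, n_seeds = 16L,
                      beam = 3L) {
  if (length(sequences) < 20L) stop("need >= 20 sequences")
  if (any(nchar(sequences) < width))
    stop("all sequences must be >= width bp")
  bg <- background_freqs(sequences)
  seeds <- seed_candidates(sequences, bg, k = 8L, n = n_seeds)
  pw <- prep_pwm_windows(sequences, width)
  groups <- split(seq_along(pw$seq), pw$seq)
  ## flat lookup index into a 4 x width score matrix, built once
  idx <- rep((seq_len(width) - 1L) * 4L, each = length(pw$seq)) +
    as.vector(pw$M) + 1L
  ## short refinement for every candidate, full refinement for the best
  ## few by median best-window score (majority support beats sporadic
  ## extreme words)
  first <- lapply(seeds, function(seed) {
    probs <- seed_matrix(seed, width, bg)
    if (palindromic) probs <- palindromise(probs)
    refine_pwm(probs, pw, groups, idx, bg, width, pseudocount,
               palindromic, max_iter = 3L)
  })
  o <- order(-vapply(first, `[[`, 0, "objective"))
  best_fit <- NULL
  for (i in utils::head(o, beam)) {
    fit <- refine_pwm(first[[i]]$probs, pw, groups, idx, bg, width,
                      pseudocount, palindromic, max_iter)
    if (is.null(best_fit) || fit$objective > best_fit$objective)
      best_fit <- fit
  }
  ## register scan: seeding fixes an arbitrary alignment register, so
  ## re-refine shifted copies of the winner and keep the best by MEAN
  ## best-window score — within one motif the mean acts as a likelihood
  ## criterion and resists the edge-column overfit that inflates the
  ## median at off-by-one registers
  for (s in setdiff(-4:4, 0L)) {
    fit <- refine_pwm(shift_matrix(best_fit$probs, s, bg), pw, groups,
                      idx, bg, width, pseudocount, palindromic, max_iter)
    if (fit$mean_objective > best_fit$mean_objective) best_fit <- fit
  }
  structure(list(width = width, probs = best_fit$probs, background = bg,
                 pseudocount = pseudocount, palindromic = palindromic),
            class = "dap_pwm")
}

refine_pwm <- function(probs, pw, groups, idx, bg, width, pseudocount,
                       palindromic, max_iter) {
  prev_align <- NULL
  n <- length(pw$seq)
  score_all <- function(probs) {
    L <- log2(probs / bg)
    v <- L[idx]
    dim(v) <- c(n, width)  # reshape in place; avoids matrix() copy
    rowSums(v)
  }
  for (it in seq_len(max_iter)) {
    sc <- score_all(probs)
    best <- vapply(groups, function(g) g[which.max(sc[g])], 0L)
    probs <- site_freqs(pw$site[best], width, pseudocount)
    if (palindromic) probs <- palindromise(probs)
    if (identical(best, prev_align)) break
    prev_align <- best
  }
  sc <- score_all(probs)
  bests <- vapply(groups, function(g) max(sc[g]), 0)
  ## median = robust motif-selection objective (majority support);
  ## mean = likelihood-like register-selection objective
  list(probs = probs, objective = stats::median(bests),
       mean_objective = mean(bests))
}

background_freqs <- function(sequences) {
  x <- table(factor(unlist(strsplit(paste(sequences, collapse = ""), "")),
                    levels = BASES))
  p <- as.numeric(x) / sum(x)
  stats::setNames(p, BASES)
}

## top-n over-represented k-mers vs 0-order background, near-duplicates
## (>= k-2 exact overlap, either strand) collapsed; ties lexicographic
seed_candidates <- function(sequences, bg, k = 8L, n = 8L,
                            min_count = 5L) {
  enc <- lapply(sequences, encode_windows, k = k)
  all <- c(unlist(lapply(enc, `[[`, "fwd")), unlist(lapply(enc, `[[`, "rc")))
  r <- rle(sort(all))
  keep <- r$lengths >= min_count
  ## small inputs may have no recurrent word at all: fall back to the
  ## most frequent k-mers rather than an empty candidate list
  if (!any(keep)) keep <- r$lengths >= max(1L, max(r$lengths) - 1L)
  kmers <- decode_kmer(r$values[keep], k)
  counts <- r$lengths[keep]
  lp <- log(bg)
  expected <- length(all) *
    exp(vapply(strsplit(kmers, ""), function(b) sum(lp[b]), 0))
  o <- order(-(counts / expected), kmers)
  chosen <- character(0)
  for (km in kmers[o]) {
    dup <- any(vapply(chosen, function(c)
      !is.null(align_pair(km, c)) || !is.null(align_pair(revcomp(km), c)),
      logical(1)))
    if (!dup) chosen <- c(chosen, km)
    if (length(chosen) >= n) break
  }
  chosen
}

seed_matrix <- function(seed, width, bg) {
  probs <- matrix(rep(bg, width), nrow = 4L,
                  dimnames = list(BASES, NULL))
  k <- nchar(seed)
  off <- (width - k) %/% 2L
  b <- strsplit(seed, "")[[1]]
  for (j in seq_len(k)) {
    col <- rep(0.1, 4L)
    col[match(b[j], BASES)] <- 0.7
    probs[, off + j] <- col
  }
  probs
}

## shift matrix columns by s, vacated columns filled with background
shift_matrix <- function(probs, s, bg) {
  W <- ncol(probs)
  out <- matrix(rep(bg, W), nrow = 4L, dimnames = dimnames(probs))
  src <- seq_len(W) - s
  ok <- src >= 1L & src <= W
  out[, which(ok)] <- probs[, src[ok], drop = FALSE]
  out
}

palindromise <- function(probs) {
  rc <- probs[4:1, ncol(probs):1, drop = FALSE]
  dimnames(rc) <- dimnames(probs)
  (probs + rc) / 2
}

## stack every N-free window of every sequence (forward block then
## reverse-complement block per sequence) as one code matrix for fast
## re-scoring during refinement
prep_pwm_windows <- function(sequences, W) {
  items <- lapply(seq_along(sequences), function(i) {
    x <- base_codes(sequences[[i]])
    m <- length(x) - W + 1L
    if (m < 1L) return(NULL)
    idx <- outer(seq_len(m), 0L:(W - 1L), `+`)
    M <- matrix(x[idx], nrow = m)
    ok <- !is.na(rowSums(M))
    if (!any(ok)) return(NULL)
    M <- M[ok, , drop = FALSE]
    starts <- which(ok) - 1L
    site_f <- substring(sequences[[i]], starts + 1L, starts + W)
    list(M = rbind(M, (3L - M)[, W:1L, drop = FALSE]), seq = i,
         site = c(site_f, revcomp(site_f)))
  })
  items <- items[!vapply(items, is.null, logical(1))]
  list(M = do.call(rbind, lapply(items, `[[`, "M")),
       seq = unlist(lapply(items, function(it)
         rep(it$seq, nrow(it$M)))),
       site = unlist(lapply(items, `[[`, "site")))
}

site_freqs <- function(sites, width, pseudocount) {
  M <- do.call(rbind, lapply(sites, function(s) base_codes(s) + 1L))
  counts <- vapply(seq_len(width), function(j)
    tabulate(M[, j], nbins = 4L), integer(4L))
  probs <- counts + pseudocount
  probs <- sweep(probs, 2L, colSums(probs), `/`)
  dimnames(probs) <- list(BASES, NULL)
  probs
}

## best window of one sequence under a probs matrix (log2-odds), both
## strands; NULL if no N-free window.  pos is the 0-based start on the
## forward sequence; site is returned in match orientation.
best_window_pwm <- function(s, probs, bg) {
  W <- ncol(probs)
  L <- log2(probs / bg)
  sc <- window_scores_matrix(s, L)
  if (is.null(sc)) return(NULL)
  i <- which.max(sc$score)  # forward-strand scores listed first: + wins ties
  list(score = sc$score[i], pos = sc$pos[i], strand = sc$strand[i],
       site = sc$site[i])
}

## scores of all valid windows (both strands) under a 4 x W additive
## score matrix indexed by base code + 1
window_scores_matrix <- function(s, L) {
  W <- ncol(L)
  x <- base_codes(s)
  n <- length(x)
  m <- n - W + 1L
  if (m < 1L) return(NULL)
  idx <- outer(seq_len(m), 0L:(W - 1L), `+`)
  M <- matrix(x[idx], nrow = m)
  ok <- !is.na(rowSums(M))
  if (!any(ok)) return(NULL)
  M <- M[ok, , drop = FALSE]
  starts <- which(ok) - 1L
  colidx <- rep(seq_len(W), each = nrow(M))
  fwd <- rowSums(matrix(L[cbind(as.vector(M) + 1L, colidx)], nrow = nrow(M)))
  Mrc <- (3L - M)[, W:1L, drop = FALSE]
  rev <- rowSums(matrix(L[cbind(as.vector(Mrc) + 1L, colidx)],
                        nrow = nrow(M)))
  site_fwd <- substring(s, starts + 1L, starts + W)
  list(score = c(fwd, rev), pos = c(starts, starts),
       strand = rep(c("+", "-"), each = length(starts)),
       site = c(site_fwd, revcomp(site_fwd)))
}

#' Score a sequence with a PWM
#'
#' Maximum over all windows and both strands of the log2-odds
#' `sum_i log2(p_i(base)/bg(base))`; windows containing N are skipped.
#' Returns `-Inf` if the sequence has no valid window.
#'
#' @param pwm a [build_pwm()] model.
#' @param sequence a DNA string.
#' @return list with `value`, `position` (0-based start of the best
#'   window on the forward strand) and `strand`.
#' @export
score_pwm <- function(pwm, sequence) {
  L <- log2(pwm$probs / pwm$background)
  sc <- window_scores_matrix(sequence, L)
  if (is.null(sc)) return(list(value = -Inf, position = NA_integer_,
                               strand = NA_character_))
  i <- which.max(sc$score)
  list(value = sc$score[i], position = sc$pos[i], strand = sc$strand[i])
}

#' Best PWM-aligned site per sequence
#'
#' The single best window of each sequence (either strand), returned in
#' match orientation — the aligned-site input for [build_first_order()].
#'
#' @param pwm a [build_pwm()] model.
#' @param sequences character vector.
#' @return character vector of width-`pwm$width` sites (sequences with no
#'   valid window are dropped).
#' @export
pwm_align_sites <- function(pwm, sequences) {
  hits <- lapply(sequences, best_window_pwm, probs = pwm$probs,
                 bg = pwm$background)
  ok <- !vapply(hits, is.null, logical(1))
  vapply(hits[ok], `[[`, character(1), "site")
}

## ---------------------------------------------------------------------
## First-order positional model

#' Build a first-order positional Markov model
#'
#' Position-specific dinucleotide model estimated by counting from
#' aligned sites of identical width: an initial base distribution at
#' position 1 and a 4x4 transition matrix per subsequent position, all
#' smoothed with a pseudocount.  This is a declared simplified stand-in
#' for HMM-trained flexible models.
#'
#' @param aligned_sites character vector (>= 20) of equal-width sites,
#'   e.g. from [pwm_align_sites()].
#' @param pseudocount smoothing count (default 0.25).
#' @param background 0-order background base probabilities used as the
#'   background chain (default uniform).
#' @return object of class `dap_fom`: list with `width`, `initial`,
#'   `transitions` (list of 4x4 row-stochastic matrices), `background`.
#' @export
build_first_order <- function(aligned_sites, pseudocount = 0.25,
                              background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25)) {
  if (length(aligned_sites) < 20L) stop("need >= 20 aligned sites")
  W <- unique(nchar(aligned_sites))
  if (length(W) != 1L) stop("sites must all have the same width")
  M <- do.call(rbind, lapply(aligned_sites, function(s) base_codes(s) + 1L))
  init <- tabulate(M[, 1L], nbins = 4L) + pseudocount
  init <- stats::setNames(init / sum(init), BASES)
  transitions <- lapply(seq_len(W - 1L), function(j) {
    counts <- matrix(pseudocount, 4L, 4L, dimnames = list(BASES, BASES))
    t <- table(factor(M[, j], levels = 1:4), factor(M[, j + 1L], levels = 1:4))
    counts <- counts + matrix(as.integer(t), 4L, 4L)
    sweep(counts, 1L, rowSums(counts), `/`)
  })
  structure(list(width = W, initial = init, transitions = transitions,
                 background = background),
            class = "dap_fom")
}

#' Score a sequence with a first-order positional model
#'
#' Maximum over windows and strands of
#' `log2 P(window | model) / P(window | 0-order background)`.
#'
#' @param model a [build_first_order()] model.
#' @param sequence a DNA string.
#' @return list with `value`, `position`, `strand` (as [score_pwm()]).
#' @export
score_first_order <- function(model, sequence) {
  sc <- window_scores_fom(model, sequence)
  if (is.null(sc)) return(list(value = -Inf, position = NA_integer_,
                               strand = NA_character_))
  i <- which.max(sc$score)
  list(value = sc$score[i], position = sc$pos[i], strand = sc$strand[i])
}

window_scores_fom <- function(model, s) {
  W <- model$width
  x <- base_codes(s)
  n <- length(x)
  m <- n - W + 1L
  if (m < 1L) return(NULL)
  idx <- outer(seq_len(m), 0L:(W - 1L), `+`)
  M <- matrix(x[idx], nrow = m)
  ok <- !is.na(rowSums(M))
  if (!any(ok)) return(NULL)
  M <- M[ok, , drop = FALSE] + 1L
  starts <- which(ok) - 1L
  lbg <- log2(model$background)
  score_mat <- function(M) {
    sc <- log2(model$initial)[M[, 1L]] - lbg[M[, 1L]]
    for (j in seq_len(W - 1L)) {
      tr <- log2(model$transitions[[j]])
      sc <- sc + tr[cbind(M[, j], M[, j + 1L])] - lbg[M[, j + 1L]]
    }
    unname(sc)
  }
  fwd <- score_mat(M)
  rev <- score_mat((5L - M)[, W:1L, drop = FALSE])
  list(score = c(fwd, rev), pos = c(starts, starts),
       strand = rep(c("+", "-"), each = length(starts)))
}

## ---------------------------------------------------------------------
## KSM

#' Discover a k-mer set memory (KSM) model
#'
#' For each k in `[kmin, kmax]`, every k-mer is counted by per-sequence
#' containment (either strand, once per sequence) in bound and unbound
#' sequences centred/trimmed to `window` bp.  Enrichment in bound
#' sequences is tested with the hypergeometric upper tail;
#' Benjamini-Hochberg-adjusted p-values below `alpha` are retained
#' (capped at the `max_candidates` most significant).  Retained k-mers
#' are clustered greedily in significance order: a k-mer joins the first
#' cluster in which it overlaps a member by at least k - 2 identical
#' bases at a consistent offset (either strand), else it seeds a new
#' cluster.  A cluster's score is `-log10` of its seed's hypergeometric
#' p-value.
#'
#' @param bound_seqs,unbound_seqs character vectors of DNA sequences.
#' @param kmin,kmax k-mer size range (defaults 4 and 20).
#' @param window centre-trim width in bp (default 300).
#' @param alpha BH-adjusted significance threshold (default 1e-3).
#' @param max_candidates cap on retained k-mers before clustering.
#' @return object of class `dap_ksm`: list with `clusters` (each a list
#'   with `members`, `offsets`, `strands`, `seed`, `p`, `score`,
#'   `n_bound`, `n_unbound`), `kmin`, `kmax`, `window`, `alpha`,
#'   `n_bound_seqs`, `n_unbound_seqs`.  No enrichment yields an empty
#'   model, not an error.
#' @export
discover_ksm <- function(bound_seqs, unbound_seqs, kmin = 4L, kmax = 20L,
                         window = 300L, alpha = 1e-3,
                         max_candidates = 1000L) {
  if (length(bound_seqs) == 0L || length(unbound_seqs) == 0L)
    stop("bound and unbound sets must be non-empty")
  bound <- centre_trim(bound_seqs, window)
  unbound <- centre_trim(unbound_seqs, window)
  nb <- length(bound); nu <- length(unbound)
  cc_b <- concat_codes(bound, gap = kmax + 1L)
  cc_u <- concat_codes(unbound, gap = kmax + 1L)
  parts <- vector("list", kmax - kmin + 1L)
  for (k in kmin:kmax) {
    cb <- containment_counts(cc_b, k)
    if (length(cb$code) == 0L) next
    cu <- containment_counts(cc_u, k)
    hit_u <- cu$count[match(cb$code, cu$code)]
    hit_u[is.na(hit_u)] <- 0L
    K <- cb$count + hit_u
    p <- phyper(cb$count - 1L, K, nb + nu - K, nb, lower.tail = FALSE)
    parts[[k - kmin + 1L]] <- list(code = cb$code,
                                   k = rep(k, length(cb$code)),
                                   n_bound = cb$count, n_unbound = hit_u,
                                   p = p)
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  cand <- if (length(parts))
    data.frame(code = unlist(lapply(parts, `[[`, "code")),
               k = unlist(lapply(parts, `[[`, "k")),
               n_bound = unlist(lapply(parts, `[[`, "n_bound")),
               n_unbound = unlist(lapply(parts, `[[`, "n_unbound")),
               p = unlist(lapply(parts, `[[`, "p"))) else NULL
  model <- structure(list(clusters = list(), kmin = kmin, kmax = kmax,
                          window = window, alpha = alpha,
                          n_bound_seqs = nb, n_unbound_seqs = nu),
                     class = "dap_ksm")
  if (is.null(cand)) return(model)
  cand$padj <- p.adjust(cand$p, method = "BH")
  cand <- cand[cand$padj < alpha, , drop = FALSE]
  if (nrow(cand) == 0L) return(model)
  cand$kmer <- unlist(lapply(seq_len(nrow(cand)), function(i)
    decode_kmer(cand$code[i], cand$k[i])))
  ## significance order; ties by longer k-mer then lexicographic
  cand <- cand[order(cand$p, -cand$k, cand$kmer), , drop = FALSE]
  cand <- utils::head(cand, max_candidates)
  model$clusters <- cluster_kmers(cand)
  model
}

centre_trim <- function(seqs, window) {
  n <- nchar(seqs)
  off <- pmax(0L, (n - window) %/% 2L)
  substring(seqs, off + 1L, pmin(n, off + window))
}

## Concatenate per-sequence base codes with NA separators so rolling
## window codes can be computed in one pass for any k; separators poison
## windows that would span sequences.
concat_codes <- function(seqs, gap = 21L) {
  n <- length(seqs)
  codes <- lapply(seqs, base_codes)
  sep <- rep(NA_integer_, gap)
  x <- unlist(lapply(codes, function(c) c(c, sep)), use.names = FALSE)
  id <- unlist(lapply(seq_len(n), function(i)
    rep(c(i, NA_integer_), c(length(codes[[i]]), gap))), use.names = FALSE)
  list(x = x, id = id)
}

## distinct-per-sequence containment counts (either strand) of all k-mers
## present in `seqs`; `cc` is a concat_codes() result.  Returns sorted
## codes and counts.  Rolling base-4 codes come from a linear filter; a
## (sequence id, code) pair is packed exactly into one double
## (id * 4^20 + code < 2^53) to dedupe per sequence.
containment_counts <- function(cc, k) {
  ## filter()'s first coefficient multiplies the window's last base, so
  ## ascending powers give the standard big-endian code
  x <- cc$x
  fwd <- stats::filter(x, 4^(0L:(k - 1L)), method = "convolution",
                       sides = 1L)
  rc <- stats::filter(3L - x, 4^((k - 1L):0L), method = "convolution",
                      sides = 1L)
  ## filter() reports the window ending at position i; shift to starts
  n <- length(x)
  starts <- seq_len(n - k + 1L)
  fwd <- as.numeric(fwd[starts + k - 1L])
  rc <- as.numeric(rc[starts + k - 1L])
  id <- cc$id[starts]
  M <- 4^20
  packed <- c(id * M + fwd, id * M + rc)
  packed <- unique(packed[!is.na(packed)])
  if (length(packed) == 0L)
    return(list(code = numeric(0), count = integer(0)))
  code <- sort(packed - floor(packed / M) * M)
  r <- rle(code)
  list(code = r$values, count = r$lengths)
}

## greedy single-pass clustering in significance order
cluster_kmers <- function(cand) {
  clusters <- list()
  for (i in seq_len(nrow(cand))) {
    km <- cand$kmer[i]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      al <- align_to_cluster(km, clusters[[ci]])
      if (!is.null(al)) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, al$kmer)
        clusters[[ci]]$offsets <- c(clusters[[ci]]$offsets, al$offset)
        clusters[[ci]]$strands <- c(clusters[[ci]]$strands, al$strand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      p <- max(cand$p[i], 1e-300)
      clusters[[length(clusters) + 1L]] <- list(
        members = km, offsets = 0L, strands = "+", seed = km,
        p = cand$p[i], score = -log10(p),
        n_bound = cand$n_bound[i], n_unbound = cand$n_unbound[i])
    }
  }
  clusters[order(-vapply(clusters, `[[`, 0, "score"))]
}

## can `km` (or its reverse complement) overlap some member by
## >= nchar(km) - 2 identical bases?  Returns kmer as stored (oriented),
## cluster-frame offset, strand; NULL if no alignment.
align_to_cluster <- function(km, cluster) {
  for (orient in c("+", "-")) {
    q <- if (orient == "+") km else revcomp(km)
    for (mi in seq_along(cluster$members)) {
      s <- align_pair(q, cluster$members[mi])
      if (!is.null(s))
        return(list(kmer = q, offset = cluster$offsets[mi] + s,
                    strand = orient))
    }
  }
  NULL
}

## best shift aligning q against m with exact identity over the overlap
## and overlap >= nchar(q) - 2; prefers larger overlap then smaller |shift|
align_pair <- function(q, m) {
  kq <- nchar(q); km <- nchar(m)
  need <- kq - 2L
  s <- (-(kq - 1L)):(km - 1L)
  lo <- pmax(0L, s); hi <- pmin(km, s + kq)
  ov <- hi - lo
  keep <- ov >= need
  if (!any(keep)) return(NULL)
  s <- s[keep]; lo <- lo[keep]; hi <- hi[keep]; ov <- ov[keep]
  eq <- substring(m, lo + 1L, hi) == substring(q, lo - s + 1L, hi - s)
  if (!any(eq)) return(NULL)
  s <- s[eq]; ov <- ov[eq]
  o <- order(-ov, abs(s))
  s[o[1]]
}

#' Score sequences with a KSM model
#'
#' A sequence's score is the sum, over clusters with at least one member
#' k-mer present in the sequence (either strand), of the cluster scores;
#' each cluster counts at most once per sequence.  A model with no
#' clusters scores everything 0.
#'
#' @param model a [discover_ksm()] model.
#' @param sequences character vector.
#' @return numeric vector of scores (>= 0), one per sequence.
#' @export
score_ksm <- function(model, sequences) {
  if (length(model$clusters) == 0L) return(numeric(length(sequences)))
  both <- cbind(sequences, revcomp(sequences))
  scores <- numeric(length(sequences))
  for (cl in model$clusters) {
    hit <- vapply(seq_along(sequences), function(i)
      any(stringi::stri_detect_fixed(both[i, 1L], cl$members)) ||
        any(stringi::stri_detect_fixed(both[i, 2L], cl$members)),
      logical(1))
    scores[hit] <- scores[hit] + cl$score
  }
  scores
}

#' @export
print.dap_pwm <- function(x, ...) {
  cat("dap_pwm: width", x$width,
      if (x$palindromic) "(palindromic)" else "", "\n")
  cat("consensus:", paste(BASES[apply(x$probs, 2, which.max)],
                          collapse = ""), "\n")
  invisible(x)
}

#' @export
print.dap_ksm <- function(x, ...) {
  cat("dap_ksm:", length(x$clusters), "cluster(s), k in [",
      x$kmin, ",", x$kmax, "]\n")
  if (length(x$clusters))
    cat("top cluster seed:", x$clusters[[1]]$seed, "score",
        round(x$clusters[[1]]$score, 2), "\n")
  invisible(x)
}

#' @export
print.dap_fom <- function(x, ...) {
  cat("dap_fom: first-order positional model, width", x$width, "\n")
  invisible(x)
}
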