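# Independent brute-force oracles and small fixture builders.  Oracles
# are deliberately naive (explicit loops, direct arithmetic) so they
# share no code with the implementation they check.

ov_bp <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

# ---- random fixtures -------------------------------------------------

random_peak_list <- function(n, chroms = c("c1", "c2"), max_pos = 5000L,
                             width_range = c(50L, 400L),
                             disjoint = FALSE) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  chrom <- sample(chroms, n, replace = TRUE)
  if (disjoint) {
    chrom <- rep(chroms[1], n)
    gaps <- sample(10:200, n, replace = TRUE)
    start <- cumsum(gaps + w) - w
  } else {
    start <- sample.int(max_pos, n, replace = TRUE) - 1L
  }
  df <- data.frame(chrom = chrom, start = start, end = start + w,
                   stringsAsFactors = FALSE)
  df$summit <- df$start + sapply(w, function(x) sample.int(x, 1L)) - 1L
  df$summit_height <- round(runif(n, 1, 100), 3)
  df[order(df$chrom, df$start, df$end), ]
}

random_dna <- function(n, len, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    character(1))
}

# constant-coverage replicate tracks over a single test chromosome
flat_tracks <- function(chrom = "c1", len = 5000L, value = 1, n_rep = 2L) {
  lapply(seq_len(n_rep), function(r)
    dap_track(setNames(list(rep(value, len)), chrom)))
}

# ---- oracles ---------------------------------------------------------

# replicate-consensus rule, all-pairs
oracle_consensus <- function(lists) {
  ref <- lists[[1]]
  out <- NULL
  for (i in seq_len(nrow(ref))) {
    group <- ref[i, , drop = FALSE]
    present_in_all <- TRUE
    for (other in lists[-1]) {
      found <- FALSE
      for (j in seq_len(nrow(other))) {
        if (other$chrom[j] == ref$chrom[i] &&
            ov_bp(ref$start[i], ref$end[i],
                  other$start[j], other$end[j]) > 0L) {
          found <- TRUE
          group <- rbind(group, other[j, , drop = FALSE])
        }
      }
      if (!found) { present_in_all <- FALSE; break }
    }
    if (present_in_all)
      out <- rbind(out, group[which.max(group$summit_height), , drop = FALSE])
  }
  if (is.null(out)) return(ref[0, , drop = FALSE])
  out <- unique(out)
  out[order(out$chrom, out$start, out$end), ]
}

# naive reimplementation of the merge rule: all overlapping pairs with
# both own-length fractions > 0.5 are candidate commons, paired greedily
# by descending overlap (ties by A chrom/start then B start); everything
# unpaired is set-specific over its own interval.  Coverage columns are
# not part of the oracle.
oracle_merge <- function(a, b) {
  pairs <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- ov_bp(a$start[i], a$end[i], b$start[j], b$end[j])
    if (ov <= 0L) next
    fa <- ov / (a$end[i] - a$start[i])
    fb <- ov / (b$end[j] - b$start[j])
    pairs <- rbind(pairs, data.frame(i = i, j = j, ov = ov, fa = fa,
                                     fb = fb))
  }
  used_a <- rep(FALSE, nrow(a)); used_b <- rep(FALSE, nrow(b))
  out <- NULL
  if (!is.null(pairs)) {
    cand <- pairs[pairs$fa > 0.5 & pairs$fb > 0.5, , drop = FALSE]
    cand <- cand[order(-cand$ov, a$chrom[cand$i], a$start[cand$i],
                       b$start[cand$j]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      out <- rbind(out, data.frame(
        chrom = a$chrom[i], start = min(a$start[i], b$start[j]),
        end = max(a$end[i], b$end[j]), class = "common"))
    }
  }
  for (i in which(!used_a))
    out <- rbind(out, data.frame(chrom = a$chrom[i], start = a$start[i],
                                 end = a$end[i], class = "A_only"))
  for (j in which(!used_b))
    out <- rbind(out, data.frame(chrom = b$chrom[j], start = b$start[j],
                                 end = b$end[j], class = "B_only"))
  out[order(out$chrom, out$start, out$end, out$class), ]
}

# all-pairs CArG scan: explicit per-window string check
oracle_carg <- function(seq, max_mm = 1L) {
  hits <- NULL
  n <- nchar(seq)
  for (i in seq_len(max(0L, n - 9L))) {
    w <- strsplit(substr(seq, i, i + 9L), "")[[1]]
    if (any(w == "N")) next
    mm <- sum(w[1:2] != "C") + sum(!(w[3:8] %in% c("A", "T"))) +
      sum(w[9:10] != "G")
    if (mm <= max_mm)
      hits <- rbind(hits, data.frame(position = i - 1L, n_mismatch = mm))
  }
  if (is.null(hits)) data.frame(position = integer(0),
                                n_mismatch = integer(0)) else hits
}

# all-pairs spacing counts over regions
oracle_spacing_counts <- function(regions, genome, max_mm, d_lo, d_hi) {
  counts <- setNames(rep(0L, d_hi - d_lo + 1L), d_lo:d_hi)
  for (i in seq_len(nrow(regions))) {
    s <- substr(genome$seq[[regions$chrom[i]]], regions$start[i] + 1L,
                regions$end[i])
    pos <- oracle_carg(s, max_mm)$position
    if (length(pos) < 2L) next
    for (a in seq_along(pos)) for (b in seq_along(pos)) {
      if (b <= a) next
      d <- abs(pos[b] - pos[a])
      if (d >= d_lo && d <= d_hi)
        counts[as.character(d)] <- counts[as.character(d)] + 1L
    }
  }
  unname(counts)
}

# exhaustive nearest-TSS assignment
oracle_assign <- function(peaks, genes, max_dist) {
  out <- character(0)
  for (i in seq_len(nrow(peaks))) {
    sm <- if (!is.null(peaks$summit)) peaks$summit[i] else
      (peaks$start[i] + peaks$end[i]) %/% 2L
    best <- Inf; who <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      d <- abs(genes$tss[j] - sm)
      if (d < best) { best <- d; who <- genes$gene[j] }
      else if (d == best) who <- c(who, genes$gene[j])
    }
    if (best <= max_dist) out <- c(out, who)
  }
  unique(out)
}

# AUROC by explicit pair enumeration
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# hypergeometric upper tail by lchoose sum
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  i <- i[(n - i) <= (N - K)]
  if (length(i) == 0L) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# brute-force PWM scan: max log2-odds over all windows and strands
oracle_pwm_scan <- function(pwm, seq) {
  W <- pwm$width
  best <- -Inf
  rc <- revcomp(seq)
  for (s in c(seq, rc)) {
    n <- nchar(s)
    for (i in seq_len(max(0L, n - W + 1L))) {
      w <- strsplit(substr(s, i, i + W - 1L), "")[[1]]
      if (any(w == "N")) next
      sc <- 0
      for (j in seq_len(W))
        sc <- sc + log2(pwm$probs[w[j], j] / pwm$background[w[j]])
      best <- max(best, sc)
    }
  }
  best
}

# brute-force first-order scan
oracle_fom_scan <- function(model, seq) {
  W <- model$width
  best <- -Inf
  for (s in c(seq, revcomp(seq))) {
    n <- nchar(s)
    for (i in seq_len(max(0L, n - W + 1L))) {
      w <- strsplit(substr(s, i, i + W - 1L), "")[[1]]
      if (any(w == "N")) next
      sc <- log2(model$initial[w[1]] / model$background[w[1]])
      for (j in seq_len(W - 1L))
        sc <- sc + log2(model$transitions[[j]][w[j], w[j + 1L]] /
                          model$background[w[j + 1L]])
      best <- max(best, sc)
    }
  }
  best
}

# tiny genome with uniform category blocks for background sampling
toy_genome <- function(len = 60000L, gc = 0.4, seed = 1L,
                       chrom = "t1") {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(names(p), len, replace = TRUE, prob = p),
               collapse = "")
  ends <- seq(500L, len, by = 500L)
  if (tail(ends, 1L) != len) ends <- c(ends, len)
  cats <- rep(c("promoter", "exon", "intron", "intergenic"),
              length.out = length(ends))
  dap_genome(setNames(seq, chrom),
             data.frame(chrom = chrom, start = ends - c(ends[1], diff(ends)),
                        end = ends, category = cats,
                        stringsAsFactors = FALSE))
}
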