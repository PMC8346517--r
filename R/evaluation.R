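## Matched unbound backgrounds and AUROC evaluation of binding-site
## models against each complex's specific regions.

#' Sample GC/size/origin-matched unbound background regions
#'
#' For each bound region two unbound regions are drawn by rejection
#' sampling (one for model discovery, one for evaluation) with identical
#' length, the same origin category (promoter / exon / intron /
#' intergenic, taken at the region midpoint) and GC content in the same
#' decile bin of the bound set's GC distribution.  Background regions
#' overlap neither any bound region nor each other.
#'
#' @param bound_regions data.frame with `chrom`, `start`, `end`.
#' @param genome a [dap_genome] with category annotation.
#' @param n_bins_gc number of GC bins over the bound GC distribution.
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap per region.
#' @return list with `discovery` and `evaluation` data.frames (`chrom`,
#'   `start`, `end`, `gc`, `category`), each with `nrow(bound_regions)`
#'   rows.
#' @export
sample_matched_background <- function(bound_regions, genome, n_bins_gc = 10L,
                                      seed = 1L, max_tries = 10000L) {
  if (is.null(genome$categories)) stop("genome has no category annotation")
  set.seed(seed)
  n <- nrow(bound_regions)
  seqs <- region_seqs(genome, bound_regions)
  gc <- gc_content(seqs)
  edges <- unique(quantile(gc, probs = seq(0, 1, length.out = n_bins_gc + 1L),
                           na.rm = TRUE))
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  bin_of <- function(g) findInterval(g, edges, rightmost.closed = TRUE)
  cat_at <- function(chrom, pos) {
    blk <- genome$categories
    hit <- blk$chrom == chrom & blk$start <= pos & pos < blk$end
    blk$category[which(hit)[1]]
  }
  mid <- (bound_regions$start + bound_regions$end) %/% 2L
  bound_cat <- vapply(seq_len(n), function(i)
    cat_at(bound_regions$chrom[i], mid[i]), character(1))
  bound_bin <- bin_of(gc)
  taken <- bound_regions[, c("chrom", "start", "end")]
  out <- list()
  for (role in c("discovery", "evaluation")) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      len <- bound_regions$end[i] - bound_regions$start[i]
      chrom <- bound_regions$chrom[i]
      L <- chrom_length(genome, chrom)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- sample.int(L - len, 1L) - 1L
        same <- taken$chrom == chrom
        if (any(overlap_bp(s, s + len, taken$start[same],
                           taken$end[same]) > 0L)) next
        if (!identical(cat_at(chrom, s + len %/% 2L), bound_cat[i])) next
        g <- gc_content(genome_seq(genome, chrom, s, s + len))
        if (is.na(g) || bin_of(g) != bound_bin[i]) next
        rows[[i]] <- data.frame(chrom = chrom, start = s, end = s + len,
                                gc = g, category = bound_cat[i],
                                stringsAsFactors = FALSE)
        taken <- rbind(taken, rows[[i]][, c("chrom", "start", "end")])
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not match background for region ", chrom, ":",
             bound_regions$start[i], "-", bound_regions$end[i],
             " (", role, ")")
    }
    out[[role]] <- do.call(rbind, rows)
  }
  out
}

#' AUROC by pair counting (Mann-Whitney form)
#'
#' `auc = (#(pos > neg) + 0.5 #(pos = neg)) / (n_pos * n_neg)`, computed
#' via midranks.
#'
#' @param pos_scores,neg_scores non-empty numeric score vectors.
#' @return the AUROC in \[0, 1\].
#' @export
compute_auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L) stop("score lists must be non-empty")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

score_with_model <- function(kind, model, seqs) {
  switch(kind,
         PWM = vapply(seqs, function(s) score_pwm(model, s)$value, 0,
                      USE.NAMES = FALSE),
         first_order = vapply(seqs, function(s)
           score_first_order(model, s)$value, 0, USE.NAMES = FALSE),
         KSM = score_ksm(model, seqs),
         stop("unknown model kind: ", kind))
}

#' Cross-evaluate all models on both complexes' specific regions
#'
#' Each model kind (PWM, first-order, KSM), trained on each complex's
#' best-bound sequences, is scored against each complex's specific
#' regions (positives) versus that set's matched evaluation background
#' (negatives); discrimination is summarised as AUROC.
#'
#' @param models_a,models_b named lists with elements `pwm`, `fom`,
#'   `ksm` — the models trained on complexes A and B.
#' @param a_specific_seqs,b_specific_seqs character vectors of specific
#'   region sequences.
#' @param eval_background_a_seqs,eval_background_b_seqs matched
#'   evaluation background sequences for the two specific sets.
#' @return data.frame with columns `model`, `trained_on`,
#'   `evaluated_on`, `auc`, `n_pos`, `n_neg` (12 rows).
#' @export
cross_evaluate <- function(models_a, models_b, a_specific_seqs,
                           b_specific_seqs, eval_background_a_seqs,
                           eval_background_b_seqs) {
  kinds <- c(PWM = "pwm", first_order = "fom", KSM = "ksm")
  grid <- expand.grid(model = names(kinds), trained_on = c("A", "B"),
                      evaluated_on = c("A_specific", "B_specific"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    kind <- grid$model[r]
    models <- if (grid$trained_on[r] == "A") models_a else models_b
    pos <- if (grid$evaluated_on[r] == "A_specific") a_specific_seqs
           else b_specific_seqs
    neg <- if (grid$evaluated_on[r] == "A_specific")
      eval_background_a_seqs else eval_background_b_seqs
    ps <- score_with_model(kind, models[[kinds[[kind]]]], pos)
    ns <- score_with_model(kind, models[[kinds[[kind]]]], neg)
    cbind(grid[r, , drop = FALSE],
          data.frame(auc = compute_auc(ps, ns), n_pos = length(ps),
                     n_neg = length(ns)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
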