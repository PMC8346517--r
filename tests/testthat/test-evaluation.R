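test_that("AUROC equals explicit pair counting", {
  expect_equal(compute_auc(c(3, 2), c(1, 0)), 1)
  expect_equal(compute_auc(1, 1), 0.5)
  expect_equal(compute_auc(c(2, 0), c(1, 1)), 0.5)
  expect_error(compute_auc(numeric(0), 1), "non-empty")
  set.seed(51)
  for (i in 1:40) {
    pos <- sample(0:10, sample(2:20, 1), replace = TRUE) / 2
    neg <- sample(0:10, sample(2:20, 1), replace = TRUE) / 2
    expect_equal(compute_auc(pos, neg), oracle_auc(pos, neg))
  }
  # -Inf sentinel scores rank below everything
  expect_equal(compute_auc(c(1, 2), c(-Inf, -Inf)), 1)
})

test_that("matched backgrounds respect cardinality, GC, origin, overlap", {
  g <- toy_genome(len = 240000L, seed = 52)
  set.seed(53)
  starts <- seq(2000L, 220000L, by = 16000L)
  bound <- data.frame(chrom = "t1", start = starts, end = starts + 300L)
  bg <- sample_matched_background(bound, g, seed = 54)
  for (role in c("discovery", "evaluation")) {
    expect_equal(nrow(bg[[role]]), nrow(bound))
    expect_true(all(bg[[role]]$end - bg[[role]]$start == 300L))
    # no overlap with any bound region
    for (i in seq_len(nrow(bg[[role]])))
      expect_true(all(pmin(bg[[role]]$end[i], bound$end) -
                        pmax(bg[[role]]$start[i], bound$start) <= 0L))
  }
  # discovery and evaluation regions are mutually disjoint
  for (i in seq_len(nrow(bg$discovery)))
    expect_true(all(pmin(bg$discovery$end[i], bg$evaluation$end) -
                      pmax(bg$discovery$start[i], bg$evaluation$start) <= 0L))
  # same origin category as the matched bound region
  cat_at <- function(pos) {
    blk <- g$categories
    blk$category[blk$start <= pos & pos < blk$end][1]
  }
  mids <- (bound$start + bound$end) %/% 2L
  expect_equal(bg$discovery$category, vapply(mids, cat_at, ""))
  # GC deciles match within-bin by construction
  gcs <- gc_content(vapply(seq_len(nrow(bound)), function(i)
    substr(g$seq[[1]], bound$start[i] + 1L, bound$end[i]), ""))
  expect_lt(max(abs(sort(bg$discovery$gc) - sort(gcs))), 0.15)
})

test_that("background matching fails loudly when impossible", {
  g <- toy_genome(len = 60000L, seed = 55)
  # one bound region of extreme GC that no unbound window can match
  g$seq["t1"] <- paste0(strrep("G", 400), substr(g$seq[["t1"]], 401, 60000))
  bound <- data.frame(chrom = "t1", start = c(0L, 10000L, 20000L),
                      end = c(400L, 10400L, 20400L))
  expect_error(sample_matched_background(bound, g, seed = 56,
                                         max_tries = 200L),
               "could not match")
})

test_that("cross-evaluation covers all model/training/evaluation cells", {
  set.seed(57)
  spec <- synth_spec()
  pos_a <- simulate_region_sequences(40, "A_only", spec, 58, width = 200)
  pos_b <- simulate_region_sequences(40, "B_only", spec, 59, width = 200)
  neg <- simulate_background_sequences(40, spec, 60, width = 200)
  pwm <- build_pwm(pos_a, n_seeds = 4L)
  fom <- build_first_order(pwm_align_sites(pwm, pos_a))
  ksm <- discover_ksm(pos_a, neg, kmax = 12L)
  models <- list(pwm = pwm, fom = fom, ksm = ksm)
  res <- cross_evaluate(models, models, pos_a, pos_b, neg, neg)
  expect_equal(nrow(res), 12L)
  expect_setequal(unique(res$model), c("first_order", "KSM", "PWM"))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_true(all(res$n_pos == 40L & res$n_neg == 40L))
  # AUROC recomputation agrees with the pair-counting oracle
  ps <- score_ksm(ksm, pos_a)
  ns <- score_ksm(ksm, neg)
  expect_equal(res$auc[res$model == "KSM" & res$trained_on == "A" &
                         res$evaluated_on == "A_specific"],
               oracle_auc(ps, ns))
})

test_that("AUROC on label-shuffled scores sits near chance", {
  set.seed(61)
  aucs <- replicate(10, {
    scores <- rnorm(1000)
    compute_auc(scores[1:500], scores[501:1000])
  })
  expect_true(all(aucs > 0.42 & aucs < 0.58))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})
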