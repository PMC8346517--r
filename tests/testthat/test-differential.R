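tracks1 <- flat_tracks(len = 8000L, n_rep = 2L)

test_that("peak-set merging classifies by reciprocal overlap fractions", {
  a <- data.frame(chrom = "c1", start = 1000L, end = 1400L)
  b <- data.frame(chrom = "c1", start = 1020L, end = 1420L)
  m <- merge_peak_sets(a, b, tracks1, tracks1)
  expect_equal(nrow(m), 1L)
  expect_equal(m$class, "common")
  expect_true(m$high_confidence)  # f = 380/400 = 0.95 >= 0.8
  expect_equal(c(m$start, m$end), c(1000L, 1420L))

  # identical intervals
  m2 <- merge_peak_sets(a, a, tracks1, tracks1)
  expect_equal(m2$class, "common")
  expect_equal(c(m2$start, m2$end), c(1000L, 1400L))

  # f = 0.25 both: two set-specific entries over their own intervals
  a3 <- data.frame(chrom = "c1", start = 0L, end = 400L)
  b3 <- data.frame(chrom = "c1", start = 300L, end = 700L)
  m3 <- merge_peak_sets(a3, b3, tracks1, tracks1)
  expect_equal(m3$class, c("A_only", "B_only"))
  expect_equal(m3$start, c(0L, 300L))

  unsorted <- data.frame(chrom = "c1", start = c(500L, 0L),
                         end = c(900L, 400L))
  expect_error(merge_peak_sets(unsorted, b3, tracks1, tracks1), "sorted")
})

test_that("every input peak lands in exactly one merged entry", {
  set.seed(31)
  for (i in 1:40) {
    a <- random_peak_list(sample(3:12, 1), chroms = "c1",
                          width_range = c(100L, 200L), disjoint = TRUE)
    b <- random_peak_list(sample(3:12, 1), chroms = "c1",
                          width_range = c(100L, 200L), disjoint = TRUE)
    a <- a[, c("chrom", "start", "end")]
    b <- b[, c("chrom", "start", "end")]
    m <- merge_peak_sets(a, b, tracks1, tracks1)
    n_common <- sum(m$class == "common")
    expect_equal(nrow(m), nrow(a) + nrow(b) - n_common)
    # specific entries preserve their own interval
    for (cls in c("A_only", "B_only")) {
      src <- if (cls == "A_only") a else b
      sp <- m[m$class == cls, ]
      expect_true(all(sp$start %in% src$start))
    }
  }
})

test_that("CFR follows the pseudocounted coverage ratio", {
  m <- data.frame(cov_a = c(10, 10, 0.3), cov_b = c(10, 5, 0))
  got <- compute_cfr(m, pseudocount = 0.01)
  expect_equal(got$cfr[1], 1)
  expect_equal(got$cfr[2], 5.01 / 10.01)
  expect_gt(got$cfr[3], 0)
  expect_lt(got$cfr[3], 1)
  expect_error(compute_cfr(data.frame(cov_a = -1, cov_b = 1)), "negative")

  # scale invariance for coverages well above the pseudocount
  set.seed(32)
  cov_a <- runif(100, 5, 500); cov_b <- runif(100, 5, 500)
  f <- runif(100, 0.5, 2)
  c1 <- compute_cfr(data.frame(cov_a = cov_a, cov_b = cov_b))$cfr
  c2 <- compute_cfr(data.frame(cov_a = cov_a * f, cov_b = cov_b * f))$cfr
  expect_true(all(abs(c2 / c1 - 1) < 0.01))
})

test_that("specific-set selection matches a full-sort oracle", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(40:150, 1)
    m <- data.frame(chrom = "c1", start = seq_len(n) * 1000L,
                    end = seq_len(n) * 1000L + 400L,
                    cov_a = runif(n, 0, 100), cov_b = runif(n, 0, 100))
    m <- compute_cfr(m)
    sp <- select_specific(m, 0.15)
    k <- ceiling(0.15 * n)
    expect_equal(nrow(sp$a_specific), k)
    expect_equal(nrow(sp$b_specific), k)
    expect_equal(length(intersect(rownames(sp$a_specific),
                                  rownames(sp$b_specific))), 0L)
    srt <- sort(m$cfr)
    expect_true(all(sp$a_specific$cfr <= srt[k] + 1e-12))
    expect_true(all(sp$b_specific$cfr >= srt[n - k + 1] - 1e-12))
  }
  # all-equal CFR still yields two disjoint deterministic sets
  m <- compute_cfr(data.frame(chrom = "c1", start = 1:100 * 1000L,
                              end = 1:100 * 1000L + 400L,
                              cov_a = rep(2, 100), cov_b = rep(2, 100)))
  sp <- select_specific(m, 0.15)
  expect_equal(nrow(sp$a_specific), 15L)
  expect_equal(nrow(sp$b_specific), 15L)
  sp2 <- select_specific(m, 0.15)
  expect_identical(sp, sp2)
  expect_error(select_specific(m, 0.6), "fraction")
})

test_that("best-peak selection is a coverage-ranked top-n", {
  set.seed(34)
  n <- 500
  ps <- data.frame(chrom = "c1", start = seq_len(n) * 1000L,
                   end = seq_len(n) * 1000L + 400L,
                   mean_coverage = runif(n, 0, 300))
  best <- select_best_peaks(ps, 100)
  expect_equal(nrow(best), 100L)
  expect_gte(min(best$mean_coverage),
             max(ps$mean_coverage[!rownames(ps) %in% rownames(best)]))
  # order invariance
  perm <- ps[sample(n), ]
  best2 <- select_best_peaks(perm, 100)
  expect_equal(sort(best2$start), sort(best$start))
  expect_warning(all_of_them <- select_best_peaks(ps, 1000), "fewer")
  expect_equal(nrow(all_of_them), n)
  expect_error(select_best_peaks(ps, 0), "n must be")
})
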