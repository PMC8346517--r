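mk_track <- function(v, chrom = "c1") dap_track(setNames(list(v), chrom))

test_that("threshold-run peak calling finds runs, summits and edge cases", {
  expect_equal(nrow(call_peaks(mk_track(rep(0, 1000)), 5)), 0L)

  v <- rep(0, 1000); v[501:600] <- 10
  p <- call_peaks(mk_track(v), 5, min_width = 50)
  expect_equal(p[, c("start", "end", "summit")],
               data.frame(start = 500L, end = 600L, summit = 500L))

  # two bumps separated by a sub-threshold gap
  v <- rep(0, 1000); v[101:200] <- 8; v[201:250] <- 2; v[251:350] <- 9
  p <- call_peaks(mk_track(v), 5, min_width = 50)
  expect_equal(nrow(p), 2L)
  expect_equal(p$start, c(100L, 250L))
  # runs shorter than min_width are dropped
  v <- rep(0, 1000); v[101:120] <- 10
  expect_equal(nrow(call_peaks(mk_track(v), 5, min_width = 50)), 0L)
  expect_error(call_peaks(mk_track(v), 0), "min_height")
})

test_that("consensus requires presence in all replicates", {
  set.seed(21)
  l <- random_peak_list(10, disjoint = TRUE)
  expect_equal(consensus_peaks(list(l, l, l)), l)

  # peak in 2 of 3 replicates is dropped
  one <- data.frame(chrom = "c1", start = 100L, end = 200L, summit = 150L,
                    summit_height = 5)
  far <- data.frame(chrom = "c1", start = 5000L, end = 5100L,
                    summit = 5050L, summit_height = 7)
  got <- consensus_peaks(list(one, rbind(one, far), rbind(one, far)))
  expect_equal(got, one)
  got2 <- consensus_peaks(list(rbind(one, far), rbind(one, far), one))
  expect_equal(got2, one)

  expect_warning(out <- consensus_peaks(list(one, one[0, ])), "no peaks")
  expect_equal(nrow(out), 0L)
  expect_error(consensus_peaks(list(one)), "at least 2")
})

test_that("consensus matches the brute-force oracle on random instances", {
  set.seed(22)
  for (i in 1:60) {
    lists <- lapply(1:3, function(r) random_peak_list(sample(3:15, 1)))
    got <- consensus_peaks(lists)
    exp <- oracle_consensus(lists)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got, exp, info = paste("instance", i))
  }
})

test_that("subpeak splitting applies the valley rule", {
  v <- rep(0, 400)
  v[101:300] <- c(seq(1, 10, length.out = 100), seq(10, 1, length.out = 100))
  peak <- data.frame(chrom = "c1", start = 100L, end = 300L)
  got <- split_subpeaks(peak, mk_track(v))
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 100L)
  expect_equal(got$end, 300L)

  # two maxima of 10 with a valley of 2 (< 0.5 * 10): split
  v <- rep(0, 400)
  v[101:150] <- 10; v[151:160] <- 2; v[161:210] <- 10
  peak <- data.frame(chrom = "c1", start = 100L, end = 210L)
  got <- split_subpeaks(peak, mk_track(v))
  expect_equal(nrow(got), 2L)
  expect_equal(got$end[1], 150L)  # cut at the leftmost valley base
  expect_equal(got$summit, c(100L, 160L))

  # valley of 7 (>= 0.5 * 10): no split
  v[151:160] <- 7
  got <- split_subpeaks(peak, mk_track(v))
  expect_equal(nrow(got), 1L)
})

test_that("resizing centres a fixed window on the summit and clips", {
  g <- dap_genome(c(c1 = strrep("A", 2000)))
  p <- data.frame(chrom = "c1", start = 900L, end = 1100L, summit = 1000L)
  r <- resize_peaks(p, g, flank = 200L)
  expect_equal(c(r$start, r$end), c(800L, 1201L))
  expect_equal(r$end - r$start, 401L)

  p2 <- data.frame(chrom = "c1", start = 40L, end = 60L, summit = 50L)
  r2 <- resize_peaks(p2, g, flank = 200L)
  expect_equal(c(r2$start, r2$end), c(0L, 251L))

  # idempotence and fixed width for random interior summits
  set.seed(23)
  p3 <- data.frame(chrom = "c1", start = 0L, end = 2000L,
                   summit = sample(300:1700, 50, replace = TRUE))
  r3 <- resize_peaks(p3, g)
  expect_true(all(r3$end - r3$start == 401L))
  expect_equal(resize_peaks(r3, g), r3)
})

test_that("coverage normalisation follows reads per kb per million", {
  expect_equal(normalize_counts(0, 400, 2e6), 0)
  expect_equal(normalize_counts(200, 400, 2e6), 250)
  # invariance under library rescaling
  set.seed(24)
  for (i in 1:50) {
    cnt <- runif(1, 10, 1000); len <- sample(100:1000, 1)
    tot <- runif(1, 1e5, 1e7); f <- runif(1, 0.1, 10)
    expect_equal(normalize_counts(cnt * f, len, tot * f),
                 normalize_counts(cnt, len, tot))
  }
  expect_error(normalize_counts(10, 0, 100), "length")
  expect_error(normalize_counts(10, 100, 0), "total")
})

test_that("full peak stage recovers planted regions from triplicates", {
  spec <- synth_spec(genome_length = 200000, n_common = 20L,
                     n_a_specific = 5L, n_b_specific = 5L, seed = 25)
  g <- make_genome(spec$genome_length, spec$gc_content, 60)
  pt <- plant_truth(g, spec)
  tr <- simulate_replicates(pt$genome, pt$truth, spec, seed = 26)
  peaks <- process_complex(tr$a, pt$genome)
  bound <- pt$truth[pt$truth$class != "B_only", ]
  hits <- vapply(seq_len(nrow(bound)), function(i)
    sum(peaks$chrom == bound$chrom[i] &
          pmin(peaks$end, bound$end[i]) -
          pmax(peaks$start, bound$start[i]) > 0L), 0L)
  expect_gte(mean(hits == 1L), 0.95)  # recall, one peak per region
  # precision: peaks land on bound regions
  fp <- vapply(seq_len(nrow(peaks)), function(i)
    !any(bound$chrom == peaks$chrom[i] &
           pmin(peaks$end[i], bound$end) -
           pmax(peaks$start[i], bound$start) > 0L), logical(1))
  expect_lte(mean(fp), 0.05)
  expect_true(all(abs(peaks$mean_coverage -
                        rowMeans(peaks[, sprintf("cov_rep%d", 1:3)])) < 1e-9))
})
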