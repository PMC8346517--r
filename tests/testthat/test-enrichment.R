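test_that("peaks map to the nearest TSS within range, ties to both", {
  genes <- data.frame(gene = c("g1", "g2", "g3"), chrom = "c1",
                      tss = c(1000L, 5000L, 5400L))
  peak <- data.frame(chrom = "c1", start = 850L, end = 950L, summit = 900L)
  expect_equal(assign_peaks_to_genes(peak, genes), "g1")
  # equidistant summit assigns both genes
  tie <- data.frame(chrom = "c1", start = 5100L, end = 5300L,
                    summit = 5200L)
  expect_setequal(assign_peaks_to_genes(tie, genes), c("g2", "g3"))
  # out of range stays unassigned
  far <- data.frame(chrom = "c1", start = 20000L, end = 20100L,
                    summit = 20050L)
  expect_length(assign_peaks_to_genes(far, genes), 0L)
})

test_that("peak-gene assignment equals exhaustive search on random fixtures", {
  set.seed(81)
  for (i in 1:40) {
    genes <- data.frame(gene = sprintf("g%02d", 1:15),
                        chrom = sample(c("c1", "c2"), 15, replace = TRUE),
                        tss = sample.int(50000L, 15))
    peaks <- random_peak_list(8, max_pos = 50000L)
    got <- assign_peaks_to_genes(peaks, genes, max_distance = 3000L)
    expect_setequal(got, oracle_assign(peaks, genes, 3000L))
  }
})

test_that("term enrichment computes exact hypergeometric fold and p", {
  uni <- sprintf("g%03d", 1:10)
  tm <- data.frame(term = "T1", gene = uni[1:4])
  res <- term_enrichment(uni[1:5], tm, uni)
  # N=10, K=4, n=5, k=4: p = C(4,4) C(6,1) / C(10,5) = 6/252
  expect_equal(res$k, 4L)
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  expect_equal(res$fold, (4 / 5) / (4 / 10))

  # no enrichment: k/n = K/N gives fold 1 and p >= 0.5
  uni2 <- sprintf("h%03d", 1:20)
  tm2 <- data.frame(term = "T1", gene = uni2[c(1, 2, 11, 12)])
  res2 <- term_enrichment(uni2[1:10], tm2, uni2)
  expect_equal(res2$fold, 1)
  expect_gte(res2$p, 0.5)

  # fold at a genome-scale configuration: k=8, n=200, K=120, N=22800
  uni3 <- sprintf("at%05d", 1:22800)
  tm3 <- data.frame(term = "carpel", gene = c(uni3[1:8], uni3[1001:1112]))
  res3 <- term_enrichment(c(uni3[1:8], uni3[10001:10192]), tm3, uni3)
  expect_equal(res3$k, 8L)
  expect_equal(res3$K, 120L)
  expect_equal(res3$fold, 7.6, tolerance = 1e-12)

  expect_error(term_enrichment(c("zz"), tm, uni), "subset")
})

test_that("fold is invariant under joint scaling of the universe", {
  set.seed(82)
  base <- term_enrichment(sprintf("g%03d", 1:20),
                          data.frame(term = "T", gene = sprintf("g%03d", 1:8)),
                          sprintf("g%03d", 1:100))
  scaled_uni <- c(sprintf("g%03d", 1:100), sprintf("x%03d", 1:100))
  scaled_tm <- data.frame(term = "T", gene = c(sprintf("g%03d", 1:8),
                                               sprintf("x%03d", 1:8)))
  scaled <- term_enrichment(sprintf("g%03d", 1:20), scaled_tm, scaled_uni)
  expect_equal(scaled$fold, base$fold)
})

test_that("BH adjustment is monotone and ordered by rank", {
  set.seed(83)
  uni <- sprintf("g%03d", 1:200)
  tm <- do.call(rbind, lapply(1:15, function(i)
    data.frame(term = sprintf("T%02d", i), gene = sample(uni, 25))))
  res <- term_enrichment(sample(uni, 40), tm, uni)
  expect_true(all(diff(res$fdr) >= -1e-12))
  expect_true(all(res$fdr >= res$p - 1e-12))
  expect_true(all(res$fdr <= 1))
})
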