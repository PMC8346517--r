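small_spec <- function(...) {
  synth_spec(genome_length = 120000, n_common = 10L, n_a_specific = 5L,
             n_b_specific = 5L, n_background_genes = 20L, ...)
}

test_that("genome generation is seeded, GC-calibrated and tiled", {
  g1 <- make_genome(100000, 0.5, seed = 1)
  g2 <- make_genome(100000, 0.5, seed = 1)
  expect_identical(g1$seq, g2$seq)
  expect_false(identical(g1$seq, make_genome(100000, 0.5, seed = 2)$seq))

  g <- make_genome(100000, 0.4, seed = 3)
  gc <- gc_content(g$seq[[1]])
  expect_lt(abs(gc - 0.4), 3 * sqrt(0.4 * 0.6 / 100000))

  blk <- g$categories
  expect_equal(blk$start[1], 0L)
  expect_equal(blk$end[nrow(blk)], 100000L)
  expect_true(all(blk$start[-1] == blk$end[-nrow(blk)]))
  expect_true(all(blk$category %in%
                    c("promoter", "exon", "intron", "intergenic")))
  expect_error(make_genome(100000, 1.2, 1), "gc_content")
  expect_error(make_genome(5000, 0.4, 1), "10 kb")
})

test_that("planted truth honours counts, classes, spacings and k-mers", {
  spec <- small_spec(spacing_a = data.frame(distance = 47L, weight = 1),
                     seed = 5)
  g <- make_genome(spec$genome_length, spec$gc_content, 50)
  pt <- plant_truth(g, spec)
  expect_equal(nrow(pt$truth), 20L)
  expect_equal(as.integer(table(pt$truth$class)[c("A_only", "B_only", "common")]),
               c(5L, 5L, 10L))
  a <- pt$truth[pt$truth$class == "A_only", ]
  expect_true(all(a$box2 - a$box1 == 47L))
  expect_true(all(a$planted_spacing == 47L))
  # planted boxes are really in the genome sequence
  for (i in seq_len(nrow(a))) {
    box <- substr(pt$genome$seq[[1]], a$box1[i] + 1L, a$box1[i] + 10L)
    expect_match(box, "^CC[AT]{6}GG$")
  }
  # regions >= 500 bp apart
  tr <- pt$truth[order(pt$truth$start), ]
  expect_true(all(tr$start[-1] - tr$end[-nrow(tr)] >= 500L))
  expect_error(plant_truth(make_genome(12000, 0.4, 1), small_spec()),
               "too small")
})

test_that("planted k-mer frequency matches the planting probability", {
  spec <- synth_spec(seed = 6)
  seqs <- simulate_region_sequences(400, "A_only", spec, seed = 7)
  frac <- mean(grepl(spec$diff_kmers_a[1], seqs))
  # binomial check at alpha = 0.01 around p = 0.7
  expect_lt(abs(frac - spec$kmer_prob_own),
            2.58 * sqrt(0.7 * 0.3 / 400))
  cross <- mean(grepl(spec$diff_kmers_b[1], seqs))
  expect_lt(cross, 0.15)
})

test_that("replicate simulation: signal strength, determinism, dispersion", {
  spec <- small_spec(seed = 8)
  g <- make_genome(spec$genome_length, spec$gc_content, 51)
  pt <- plant_truth(g, spec)
  tr1 <- simulate_replicates(pt$genome, pt$truth, spec, seed = 9)
  tr2 <- simulate_replicates(pt$genome, pt$truth, spec, seed = 9)
  expect_identical(tr1$a[[1]]$values, tr2$a[[1]]$values)

  a_only <- pt$truth[pt$truth$class == "A_only", ]
  v <- tr1$a[[1]]$values[[1]]
  in_peak <- unlist(lapply(seq_len(nrow(a_only)), function(i)
    (a_only$start[i] + 1L):a_only$end[i]))
  expect_gt(mean(v[in_peak]), 5 * mean(v[-in_peak]))

  spec0 <- small_spec(seed = 8, dispersion = 0)
  tr0 <- simulate_replicates(pt$genome, pt$truth, spec0, seed = 10)
  expect_identical(tr0$a[[1]]$values, tr0$a[[2]]$values)
  expect_identical(tr0$a[[2]]$values, tr0$a[[3]]$values)
})

test_that("dataset bundles are complete and regenerate identically", {
  spec <- small_spec(seed = 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds <- generate_dataset(spec, d1, overwrite = TRUE)
  files <- dir(d1)
  expect_true(all(c("genome.fa", "categories.bed", "truth.tsv",
                    "genes.tsv", "terms.tsv", "manifest.json") %in% files))
  expect_length(grep("^cov_[ab]_rep[123]\\.bedGraph$", files), 6L)
  expect_error(generate_dataset(spec, d1), "not empty")

  generate_dataset(spec, d2, overwrite = TRUE)
  for (f in c("genome.fa", "truth.tsv", "cov_a_rep1.bedGraph"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$n_common, spec$n_common)
  expect_equal(manifest$seed, spec$seed)
})
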