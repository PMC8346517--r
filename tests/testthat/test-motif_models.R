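B4 <- c("A", "C", "G", "T")

test_that("PWM discovery recovers a planted site", {
  set.seed(41)
  site <- "GATTACAGGCCTGAAT"
  seqs <- vapply(1:100, function(i) {
    flank <- random_dna(2, 40)
    paste0(flank[1], site, flank[2])
  }, character(1))
  pwm <- build_pwm(seqs, palindromic = FALSE)
  planted <- strsplit(site, "")[[1]]
  # recovered matrix may sit on either strand
  cons_fwd <- paste(B4[apply(pwm$probs, 2, which.max)], collapse = "")
  hit <- cons_fwd == site || revcomp(cons_fwd) == site
  expect_true(hit)
  probs <- if (cons_fwd == site) pwm$probs else
    pwm$probs[4:1, 16:1]
  for (j in 1:16) expect_gte(probs[planted[j], j], 0.9)
})

test_that("palindromic PWMs equal their own reverse complement", {
  set.seed(42)
  seqs <- random_dna(30, 60)
  pwm <- build_pwm(seqs, palindromic = TRUE)
  rc <- pwm$probs[4:1, 16:1]
  dimnames(rc) <- dimnames(pwm$probs)
  expect_identical(pwm$probs, rc)
  expect_true(all(abs(colSums(pwm$probs) - 1) < 1e-9))
  expect_error(build_pwm(random_dna(5, 60)), ">= 20")
  expect_error(build_pwm(random_dna(30, 10)), "width")
})

test_that("PWM scanning equals the brute-force window oracle", {
  set.seed(43)
  sites <- random_dna(40, 16)
  pwm <- build_pwm(vapply(sites, function(s)
    paste0(random_dna(1, 20), s, random_dna(1, 20)), character(1)),
    palindromic = FALSE)
  for (i in 1:25) {
    s <- random_dna(1, 40)
    expect_equal(score_pwm(pwm, s)$value, oracle_pwm_scan(pwm, s),
                 tolerance = 1e-9)
  }
  # strand symmetry
  s <- random_dna(1, 80)
  expect_equal(score_pwm(pwm, s)$value, score_pwm(pwm, revcomp(s))$value)
  # consensus scores the column-max sum
  cons <- paste(B4[apply(pwm$probs, 2, which.max)], collapse = "")
  expect_equal(score_pwm(pwm, cons)$value,
               sum(log2(apply(pwm$probs, 2, max) /
                          pwm$background[B4[apply(pwm$probs, 2,
                                                  which.max)]])))
  # N windows are skipped; all-N has no valid window
  expect_equal(score_pwm(pwm, strrep("N", 40))$value, -Inf)
})

test_that("first-order model estimation is row-stochastic and consistent", {
  sites <- rep("ACGTACGTACGTACGT", 25)
  fom <- build_first_order(sites)
  for (tr in fom$transitions)
    expect_true(all(abs(rowSums(tr) - 1) < 1e-9))
  # near-indicator transitions for identical sites
  expect_gt(fom$transitions[[1]]["A", "C"], 0.95)

  # recovery of a known first-order chain at n = 600
  set.seed(44)
  P <- matrix(c(.5, .3, .1, .1,
                .1, .5, .3, .1,
                .1, .1, .5, .3,
                .3, .1, .1, .5), 4, 4, byrow = TRUE,
              dimnames = list(B4, B4))
  sim <- vapply(1:600, function(i) {
    b <- integer(12); b[1] <- sample.int(4, 1)
    for (j in 2:12) b[j] <- sample.int(4, 1, prob = P[b[j - 1], ])
    paste(B4[b], collapse = "")
  }, character(1))
  fom2 <- build_first_order(sim)
  # ~150 observations per transition row and position: cell SD ~0.04,
  # so the max over all 176 cells concentrates near 3 sigma
  err <- vapply(fom2$transitions, function(tr) max(abs(tr - P)), 0)
  expect_lt(max(err), 0.15)
  expect_lt(mean(vapply(fom2$transitions,
                        function(tr) mean(abs(tr - P)), 0)), 0.04)
  expect_error(build_first_order(sites[1:5]), ">= 20")
  expect_error(build_first_order(c(sites, "ACGT")), "same width")
})

test_that("first-order scanning equals the brute-force oracle", {
  set.seed(45)
  sites <- substring(random_dna(30, 12), 1, 12)
  fom <- build_first_order(sites, background = c(A = .3, C = .2,
                                                 G = .2, T = .3))
  for (i in 1:20) {
    s <- random_dna(1, 30)
    expect_equal(score_first_order(fom, s)$value, oracle_fom_scan(fom, s),
                 tolerance = 1e-9)
  }
  s <- random_dna(1, 50)
  expect_equal(score_first_order(fom, s)$value,
               score_first_order(fom, revcomp(s))$value)
})

test_that("KSM discovery finds a planted k-mer with an exact seed p", {
  set.seed(46)
  planted <- "GATTCCGTAG"
  bound <- random_dna(150, 300)
  pick <- seq_len(120)  # 80%
  substr(bound[pick], 50, 59) <- planted
  unbound <- random_dna(150, 300)
  substr(unbound[1:8], 50, 59) <- planted  # ~5%
  ksm <- discover_ksm(bound, unbound)
  expect_gt(length(ksm$clusters), 0L)
  top <- ksm$clusters[[1]]
  expect_true(any(top$members %in% c(planted, revcomp(planted))))
  oracle_p <- oracle_hyper_tail(top$n_bound, top$n_bound + top$n_unbound,
                                300, 150)
  expect_equal(top$p, oracle_p, tolerance = 1e-9)
  expect_equal(top$score, -log10(max(top$p, 1e-300)))
})

test_that("KSM clustering groups overlapping k-mers as hand-computed", {
  cand <- data.frame(
    code = NA, k = nchar(c("GATTCCGTAG", "ATTCCGTAGC", "GATTCCGT",
                           "CCCGGGAAAT", "CCGGGAAATT", "TTTTTTTT")),
    n_bound = c(100, 90, 80, 70, 60, 50), n_unbound = 0,
    p = c(1e-30, 1e-28, 1e-25, 1e-20, 1e-18, 1e-10))
  cand$kmer <- c("GATTCCGTAG", "ATTCCGTAGC", "GATTCCGT",
                 "CCCGGGAAAT", "CCGGGAAATT", "TTTTTTTT")
  cl <- duetdap:::cluster_kmers(cand)
  expect_length(cl, 3L)
  expect_setequal(cl[[1]]$members,
                  c("GATTCCGTAG", "ATTCCGTAGC", "GATTCCGT"))
  expect_setequal(cl[[2]]$members, c("CCCGGGAAAT", "CCGGGAAATT"))
  expect_equal(cl[[3]]$members, "TTTTTTTT")
  # offsets are consistent with the alignment
  expect_equal(cl[[1]]$offsets[cl[[1]]$members == "ATTCCGTAGC"], 1L)
})

test_that("KSM scoring sums matched cluster scores once each", {
  model <- structure(list(clusters = list(
    list(members = c("GATTACA", "ATTACAG"), score = 3.2),
    list(members = "CCCGGG", score = 2.1)),
    kmin = 4L, kmax = 20L, window = 300L), class = "dap_ksm")
  expect_equal(score_ksm(model, "TTTTTTTTTT"), 0)
  expect_equal(score_ksm(model, "AAGATTACAGAA"), 3.2)  # both members, once
  expect_equal(score_ksm(model, "AAGATTACAGTTCCCGGGTT"), 5.3)
  # reverse-complement containment counts
  expect_equal(score_ksm(model, revcomp("AAGATTACAGAA")), 3.2)
  # identical bound and unbound sets give an empty model, not an error
  set.seed(47)
  same <- random_dna(60, 200)
  expect_length(discover_ksm(same, same)$clusters, 0L)
})

test_that("model files round-trip bit-exactly", {
  set.seed(48)
  seqs <- random_dna(40, 60)
  pwm <- build_pwm(seqs)
  f <- withr::local_tempfile(fileext = ".meme")
  write_pwm_meme(pwm, f)
  back <- read_pwm_meme(f)
  expect_identical(back$probs, pwm$probs)
  expect_identical(back$background, pwm$background)
  expect_identical(back$palindromic, pwm$palindromic)

  fom <- build_first_order(substring(random_dna(25, 12), 1, 12))
  fj <- withr::local_tempfile(fileext = ".json")
  write_model_json(fom, fj)
  fom2 <- read_model_json(fj)
  expect_identical(fom2$initial, fom$initial)
  expect_identical(fom2$transitions, fom$transitions)

  planted <- "GATTCCGTAG"
  bound <- random_dna(100, 250)
  substr(bound[1:80], 50, 59) <- planted
  ksm <- discover_ksm(bound, random_dna(100, 250))
  kj <- withr::local_tempfile(fileext = ".json")
  write_model_json(ksm, kj)
  ksm2 <- read_model_json(kj)
  expect_identical(ksm2$clusters, ksm$clusters)
  expect_identical(score_ksm(ksm2, bound[1:5]), score_ksm(ksm, bound[1:5]))
})
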