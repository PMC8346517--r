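## Synthetic seq-DAP-seq world: a small genome with category annotation,
## planted bound regions (CArG-box pairs at complex-specific spacings,
## complex-specific flanking k-mers) and triplicate coverage tracks for two
## complexes.  Ground truth is recorded so downstream stages can be tested
## by parameter recovery.

#' Synthetic dataset specification
#'
#' Collects every knob of the generator with defaults chosen to mimic the
#' statistical structure the pipeline assumes: a ~1 Mb genome at plant-like
#' GC, two complexes sharing a CArG-box core motif but differing in
#' preferred intersite spacings (47/57 bp vs 25/34 bp) and in flanking
#' k-mer content, assayed in triplicate.
#'
#' @param genome_length genome size in bp (single chromosome).
#' @param gc_content background GC fraction.
#' @param n_common,n_a_specific,n_b_specific planted region counts.
#' @param region_width width of each planted bound region (bp).
#' @param spacing_a,spacing_b data.frames with columns `distance` (bp,
#'   start-to-start between the two 10-bp CArG boxes) and `weight`
#'   (mixture weights summing to 1).
#' @param diff_kmers_a,diff_kmers_b character vectors of k-mers planted in
#'   the flanks of complex-specific regions.
#' @param kmer_prob_own probability a specific region carries each of its
#'   own complex's k-mers.
#' @param kmer_prob_other leak probability into other classes.
#' @param peak_height_mean mean signal height at unit affinity (read-depth
#'   units).
#' @param dispersion replicate-to-replicate gamma dispersion of peak
#'   heights; 0 gives identical replicates.
#' @param background_mean per-base Poisson background mean.
#' @param n_replicates replicates per complex.
#' @param n_background_genes decoy genes placed outside bound regions.
#' @param seed master seed for the generator.
#' @return a list of class `dap_synth_spec`.
#' @export
synth_spec <- function(genome_length = 1e6,
                       gc_content = 0.36,
                       n_common = 260L,
                       n_a_specific = 40L,
                       n_b_specific = 40L,
                       region_width = 400L,
                       spacing_a = data.frame(distance = c(47L, 57L),
                                              weight = c(0.5, 0.5)),
                       spacing_b = data.frame(distance = c(25L, 34L),
                                              weight = c(0.5, 0.5)),
                       diff_kmers_a = c("CGTTGACCTA", "TAGACGGTCA"),
                       diff_kmers_b = c("ATCCGGTTAC", "GTACAGCGAT"),
                       kmer_prob_own = 0.7,
                       kmer_prob_other = 0.05,
                       peak_height_mean = 50,
                       dispersion = 0.1,
                       background_mean = 0.5,
                       n_replicates = 3L,
                       n_background_genes = 300L,
                       seed = 1L) {
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  if (abs(sum(spacing_a$weight) - 1) > 1e-8 ||
      abs(sum(spacing_b$weight) - 1) > 1e-8)
    stop("spacing weights must sum to 1")
  if (min(n_common, n_a_specific, n_b_specific) < 0L)
    stop("region counts must be >= 0")
  spec <- as.list(environment())
  class(spec) <- "dap_synth_spec"
  spec
}

#' Generate a random annotated genome
#'
#' I.i.d. bases with P(G) = P(C) = gc/2, partitioned into category blocks
#' (promoter / exon / intron / intergenic) with lengths drawn uniformly in
#' 200-2000 bp and categories sampled at fixed proportions
#' 0.2/0.3/0.2/0.3.
#'
#' @param length genome length in bp (>= 10 kb).
#' @param gc_content GC fraction in (0, 1).
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return a [dap_genome].
#' @export
make_genome <- function(length, gc_content, seed, chrom = "chr1") {
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  if (length < 10000) stop("genome length must be >= 10 kb")
  set.seed(seed)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  seq <- paste(bases, collapse = "")
  ## category blocks tiling [0, length)
  lens <- integer(0)
  total <- 0L
  while (total < length) {
    l <- sample(200:2000, 1L)
    lens <- c(lens, min(l, length - total))
    total <- total + l
  }
  ends <- cumsum(lens)
  cats <- sample(c("promoter", "exon", "intron", "intergenic"),
                 length(lens), replace = TRUE,
                 prob = c(0.2, 0.3, 0.2, 0.3))
  categories <- data.frame(chrom = chrom, start = ends - lens, end = ends,
                           category = cats, stringsAsFactors = FALSE)
  dap_genome(stats::setNames(seq, chrom), categories)
}

## Draw one CArG box realisation: CC + 6 x A/T + GG.
random_carg_box <- function(n) {
  core <- matrix(sample(c("A", "T"), 6L * n, replace = TRUE), nrow = n)
  paste0("CC", apply(core, 1L, paste, collapse = ""), "GG")
}

draw_spacing <- function(tbl, n) {
  tbl$distance[sample.int(nrow(tbl), n, replace = TRUE, prob = tbl$weight)]
}

## Build one planted region sequence of width w on a random background:
## two CArG boxes at the given start-to-start spacing, centred, plus any
## planted k-mers written into the flanks.  Returns list(seq, box1, box2)
## with box offsets relative to region start.
build_region_seq <- function(width, gc, spacing, kmers) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- paste(sample(names(p), width, replace = TRUE, prob = p),
             collapse = "")
  box1 <- max(0L, (width - spacing - 10L) %/% 2L)
  box2 <- box1 + spacing
  if (box2 + 10L > width) stop("region too narrow for spacing ", spacing)
  boxes <- random_carg_box(2L)
  substr(s, box1 + 1L, box1 + 10L) <- boxes[1]
  substr(s, box2 + 1L, box2 + 10L) <- boxes[2]
  ## k-mers go into the left/right flanks, clear of the boxes
  for (km in kmers) {
    k <- nchar(km)
    left_ok <- box1 >= k
    right_ok <- width - (box2 + 10L) >= k
    if (!left_ok && !right_ok) next
    side <- if (left_ok && right_ok) sample(c("L", "R"), 1L)
            else if (left_ok) "L" else "R"
    pos <- if (side == "L") sample.int(box1 - k + 1L, 1L) - 1L
           else box2 + 10L + sample.int(width - box2 - 10L - k + 1L, 1L) - 1L
    substr(s, pos + 1L, pos + k) <- km
  }
  list(seq = s, box1 = box1, box2 = box2)
}

## Which planted k-mers does a region of a given class get?
draw_kmers_for_class <- function(class, spec) {
  pa <- if (class == "A_only") spec$kmer_prob_own else spec$kmer_prob_other
  pb <- if (class == "B_only") spec$kmer_prob_own else spec$kmer_prob_other
  c(spec$diff_kmers_a[runif(length(spec$diff_kmers_a)) < pa],
    spec$diff_kmers_b[runif(length(spec$diff_kmers_b)) < pb])
}

spacing_table_for_class <- function(class, spec) {
  switch(class,
         A_only = spec$spacing_a,
         B_only = spec$spacing_b,
         ## common regions are bound by both complexes: equal mixture
         common = data.frame(
           distance = c(spec$spacing_a$distance, spec$spacing_b$distance),
           weight = c(spec$spacing_a$weight, spec$spacing_b$weight) / 2))
}

#' Plant ground-truth bound regions into a genome
#'
#' Each region receives two CArG boxes at a spacing drawn from its class's
#' spacing distribution (start-to-start distance of the 10-bp boxes) and,
#' for specific regions, differential flanking k-mers at the configured
#' probabilities.  Regions are >= 500 bp apart.  Relative binding
#' affinities per complex are drawn log-normally; specific regions have
#' the other complex's affinity suppressed ten-fold.
#'
#' @param genome a [dap_genome]; the returned genome has the planted sites
#'   written into its sequence.
#' @param spec a [synth_spec].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return list with elements `genome` (mutated) and `truth` (data.frame
#'   with columns `chrom`, `start`, `end`, `class`, `planted_spacing`,
#'   `planted_kmers`, `box1`, `box2`, `affinity_a`, `affinity_b`).
#' @export
plant_truth <- function(genome, spec, seed = spec$seed) {
  set.seed(seed)
  chrom <- names(genome$seq)[1]
  len <- chrom_length(genome, chrom)
  w <- spec$region_width
  n <- spec$n_common + spec$n_a_specific + spec$n_b_specific
  if (n * (w + 500L) > 0.8 * len)
    stop("genome too small for the requested region density")
  ## greedy placement with >= 500 bp separation
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n) {
    tries <- tries + 1L
    if (tries > 200L * n) stop("could not place regions >= 500 bp apart")
    cand <- sample.int(len - w, 1L) - 1L
    if (all(abs(cand - starts) >= w + 500L)) starts <- c(starts, cand)
  }
  starts <- sort(starts)
  classes <- sample(c(rep("common", spec$n_common),
                      rep("A_only", spec$n_a_specific),
                      rep("B_only", spec$n_b_specific)))
  seq <- genome$seq[[chrom]]
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    d <- draw_spacing(spacing_table_for_class(cls, spec), 1L)
    kmers <- draw_kmers_for_class(cls, spec)
    reg <- build_region_seq(w, spec$gc_content, d, kmers)
    substr(seq, starts[i] + 1L, starts[i] + w) <- reg$seq
    aff <- exp(rnorm(1L, 0, 0.4))
    ratio <- exp(rnorm(1L, 0, 0.15))
    aff_a <- switch(cls, common = aff, A_only = aff, B_only = 0.1 * aff)
    aff_b <- switch(cls, common = aff * ratio, A_only = 0.1 * aff,
                    B_only = aff)
    rec[[i]] <- data.frame(
      chrom = chrom, start = starts[i], end = starts[i] + w, class = cls,
      planted_spacing = d,
      planted_kmers = paste(kmers, collapse = ","),
      box1 = starts[i] + reg$box1, box2 = starts[i] + reg$box2,
      affinity_a = aff_a, affinity_b = aff_b, stringsAsFactors = FALSE)
  }
  genome$seq[[chrom]] <- seq
  list(genome = genome, truth = do.call(rbind, rec))
}

#' Simulate replicate coverage tracks for both complexes
#'
#' Signal at each truth region is a triangular bump centred between the
#' planted boxes with peak height affinity x `peak_height_mean`, scaled by
#' a per-region, per-replicate gamma factor of mean 1 and shape
#' 1/dispersion; per-base Poisson background noise is added.  With
#' `dispersion = 0` all replicates of a complex are identical (noise
#' included).
#'
#' @param genome a [dap_genome].
#' @param truth truth table from [plant_truth()].
#' @param spec a [synth_spec].
#' @param seed integer seed (defaults to `spec$seed + 1`).
#' @return list with elements `a` and `b`, each a list of
#'   `spec$n_replicates` [dap_track] objects, plus `region_counts`, a
#'   data.frame of summed coverage per truth region, replicate and
#'   complex.
#' @export
simulate_replicates <- function(genome, truth, spec,
                                seed = spec$seed + 1L) {
  if (nrow(truth) == 0L) stop("truth table is empty")
  set.seed(seed)
  chrom <- names(genome$seq)[1]
  len <- chrom_length(genome, chrom)
  halfw <- spec$region_width / 2
  centres <- (truth$box1 + truth$box2 + 10L) / 2
  bump_at <- function(height, centre) {
    lo <- max(0L, floor(centre - halfw))
    hi <- min(len - 1L, ceiling(centre + halfw))
    x <- lo:hi
    list(idx = x + 1L, val = height * pmax(0, 1 - abs(x - centre) / halfw))
  }
  simulate_one <- function(affinity, rep_seed) {
    set.seed(rep_seed)
    v <- as.numeric(rpois(len, spec$background_mean))
    fac <- if (spec$dispersion > 0)
      rgamma(nrow(truth), shape = 1 / spec$dispersion,
             scale = spec$dispersion) else rep(1, nrow(truth))
    for (i in seq_len(nrow(truth))) {
      b <- bump_at(affinity[i] * spec$peak_height_mean * fac[i], centres[i])
      v[b$idx] <- v[b$idx] + b$val
    }
    dap_track(stats::setNames(list(v), chrom))
  }
  reps <- function(affinity, base) {
    lapply(seq_len(spec$n_replicates), function(r) {
      ## dispersion = 0 collapses the replicate seed so tracks are identical
      s <- if (spec$dispersion > 0) base + r else base + 1L
      simulate_one(affinity, s)
    })
  }
  tracks_a <- reps(truth$affinity_a, seed * 13L)
  tracks_b <- reps(truth$affinity_b, seed * 29L)
  counts <- do.call(rbind, lapply(c("a", "b"), function(cx) {
    tr <- if (cx == "a") tracks_a else tracks_b
    do.call(rbind, lapply(seq_along(tr), function(r) {
      v <- tr[[r]]$values[[chrom]]
      data.frame(region = seq_len(nrow(truth)), complex = cx, replicate = r,
                 count = vapply(seq_len(nrow(truth)), function(i)
                   sum(v[(truth$start[i] + 1L):truth$end[i]]), 0))
    }))
  }))
  list(a = tracks_a, b = tracks_b, region_counts = counts)
}

#' Generate a complete synthetic dataset bundle on disk
#'
#' Composes [make_genome()], [plant_truth()] and [simulate_replicates()]
#' and writes: `genome.fa`, `categories.bed`, `truth.tsv`,
#' `cov_{a,b}_rep<r>.bedGraph`, `genes.tsv` (one gene TSS downstream of
#' each bound region plus decoy genes), `terms.tsv` (a planted term
#' covering most A-specific genes, one covering most B-specific genes, and
#' random decoy terms) and `manifest.json` echoing the spec.
#'
#' @param spec a [synth_spec].
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return list with the in-memory objects (`genome`, `truth`, `tracks`,
#'   `genes`, `terms`) and `paths` of everything written, invisibly
#'   usable by the pipeline.
#' @export
generate_dataset <- function(spec, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite)
    stop("output directory not empty: ", out_dir, " (use overwrite = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome0 <- make_genome(spec$genome_length, spec$gc_content,
                         derive_seed(spec$seed, 1L))
  pt <- plant_truth(genome0, spec, seed = derive_seed(spec$seed, 2L))
  tracks <- simulate_replicates(pt$genome, pt$truth, spec,
                                seed = derive_seed(spec$seed, 3L))
  gt <- synth_genes_terms(pt$genome, pt$truth, spec,
                          seed = derive_seed(spec$seed, 4L))
  paths <- list(genome = file.path(out_dir, "genome.fa"),
                categories = file.path(out_dir, "categories.bed"),
                truth = file.path(out_dir, "truth.tsv"),
                genes = file.path(out_dir, "genes.tsv"),
                terms = file.path(out_dir, "terms.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_fasta(pt$genome$seq, paths$genome)
  write_intervals(
    data.frame(chrom = pt$genome$categories$chrom,
               start = pt$genome$categories$start,
               end = pt$genome$categories$end,
               name = pt$genome$categories$category),
    paths$categories, "BED6")
  write.table(pt$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gt$genes, paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gt$terms, paths$terms, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  for (cx in c("a", "b"))
    for (r in seq_len(spec$n_replicates)) {
      p <- file.path(out_dir, sprintf("cov_%s_rep%d.bedGraph", cx, r))
      paths[[sprintf("cov_%s_rep%d", cx, r)]] <- p
      write_coverage(tracks[[cx]][[r]], p)
    }
  manifest <- spec
  manifest$spacing_a <- as.list(spec$spacing_a)
  manifest$spacing_b <- as.list(spec$spacing_b)
  jsonlite::write_json(unclass(manifest), paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(genome = pt$genome, truth = pt$truth, tracks = tracks,
                 genes = gt$genes, terms = gt$terms, spec = spec,
                 paths = paths))
}

## Gene models and term->gene maps with planted enrichment: each truth
## region gets a gene with TSS 150 bp downstream of the region; decoy
## genes land outside bound regions.
synth_genes_terms <- function(genome, truth, spec, seed) {
  set.seed(seed)
  chrom <- names(genome$seq)[1]
  len <- chrom_length(genome, chrom)
  region_genes <- data.frame(
    gene = sprintf("G%04d", seq_len(nrow(truth))),
    chrom = chrom, tss = pmin(truth$end + 150L, len - 1L), strand = "+",
    stringsAsFactors = FALSE)
  decoy_tss <- integer(0)
  while (length(decoy_tss) < spec$n_background_genes) {
    cand <- sample.int(len, spec$n_background_genes)
    ok <- vapply(cand, function(p)
      all(p < truth$start - 3000L | p > truth$end + 3000L), logical(1))
    decoy_tss <- utils::head(c(decoy_tss, cand[ok]), spec$n_background_genes)
  }
  decoy_genes <- data.frame(
    gene = sprintf("D%04d", seq_along(decoy_tss)),
    chrom = chrom, tss = decoy_tss, strand = "+", stringsAsFactors = FALSE)
  genes <- rbind(region_genes, decoy_genes)
  term_for <- function(cls, id) {
    members <- region_genes$gene[truth$class == cls]
    members <- members[runif(length(members)) < 0.8]
    data.frame(term = id, gene = c(members,
                                   sample(decoy_genes$gene, 5L)),
               stringsAsFactors = FALSE)
  }
  rand_terms <- do.call(rbind, lapply(1:10, function(i)
    data.frame(term = sprintf("RT%02d", i),
               gene = sample(genes$gene, 30L), stringsAsFactors = FALSE)))
  terms <- rbind(term_for("A_only", "PLANT_A"), term_for("B_only", "PLANT_B"),
                 rand_terms)
  list(genes = genes, terms = terms)
}

#' Simulate standalone region sequences of a given class
#'
#' Generates independent sequences with the same construction the genome
#' planting uses (background base composition, two CArG boxes at a
#' class-specific spacing, class-specific differential k-mers), without a
#' genome.  Useful for desk-scale model-evaluation experiments.
#'
#' @param n number of sequences.
#' @param class `"A_only"`, `"B_only"` or `"common"`.
#' @param spec a [synth_spec].
#' @param seed integer seed.
#' @param width sequence width (defaults to `spec$region_width`).
#' @return character vector of sequences.
#' @export
simulate_region_sequences <- function(n, class, spec, seed,
                                      width = spec$region_width) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    d <- draw_spacing(spacing_table_for_class(class, spec), 1L)
    build_region_seq(width, spec$gc_content, d,
                     draw_kmers_for_class(class, spec))$seq
  }, character(1))
}

#' Simulate unbound background sequences
#'
#' I.i.d. sequences at the spec's background base composition with no
#' planted sites; the matched "unbound" counterpart of
#' [simulate_region_sequences()].
#'
#' @param n number of sequences.
#' @param spec a [synth_spec].
#' @param seed integer seed.
#' @param width sequence width (defaults to `spec$region_width`).
#' @return character vector of sequences.
#' @export
simulate_background_sequences <- function(n, spec, seed,
                                          width = spec$region_width) {
  set.seed(seed)
  gc <- spec$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(p), width, replace = TRUE, prob = p), collapse = ""),
    character(1))
}
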