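## End-to-end orchestration: consensus peaks per complex -> merge ->
## CFR -> specific sets -> models from best-bound peaks -> AUROC ->
## spacing preferences -> term enrichment, from a single validated
## config with one master seed.

#' Pipeline configuration
#'
#' Collects input paths (or in-memory objects) and every stage parameter
#' with the module defaults.  Paths and objects are interchangeable:
#' `genome` may be a [dap_genome] or a FASTA path (with `categories` a
#' BED path), `tracks_a`/`tracks_b` lists of [dap_track] or bedGraph
#' paths.
#'
#' @param genome a [dap_genome] or FASTA path.
#' @param categories BED path of category blocks (when `genome` is a
#'   path).
#' @param tracks_a,tracks_b per-replicate coverage: lists of
#'   [dap_track] or character vectors of bedGraph paths.
#' @param genes optional gene-model TSV path or data.frame.
#' @param terms optional term-map TSV path or data.frame.
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param min_height,min_width peak-calling thresholds.
#' @param flank resize half-width (bp).
#' @param valley_fraction subpeak valley threshold.
#' @param common_min,common_high merge overlap thresholds.
#' @param cfr_pseudocount CFR pseudocount.
#' @param fraction specific-set tail fraction.
#' @param n_best training peaks per complex.
#' @param pwm_width,pwm_palindromic,pwm_pseudocount PWM options.
#' @param kmin,kmax,ksm_window,ksm_alpha KSM options.
#' @param spacing_max_mismatch,d_range,n_shuffles,z_min spacing options.
#' @param enrich_max_distance,enrich_top_n enrichment options.
#' @return a list of class `dap_config`.
#' @export
pipeline_config <- function(genome, categories = NULL, tracks_a, tracks_b,
                            genes = NULL, terms = NULL, out_dir = NULL,
                            seed = 1L,
                            min_height = 5, min_width = 50L, flank = 200L,
                            valley_fraction = 0.5,
                            common_min = 0.5, common_high = 0.8,
                            cfr_pseudocount = 0.01, fraction = 0.15,
                            n_best = 600L,
                            pwm_width = 16L, pwm_palindromic = TRUE,
                            pwm_pseudocount = 0.25,
                            kmin = 4L, kmax = 20L, ksm_window = 300L,
                            ksm_alpha = 1e-3,
                            spacing_max_mismatch = 1L,
                            d_range = c(10L, 100L), n_shuffles = 100L,
                            z_min = 3,
                            enrich_max_distance = 3000L,
                            enrich_top_n = 250L) {
  cfg <- as.list(environment())
  for (f in c("tracks_a", "tracks_b"))
    if (is.character(cfg[[f]])) {
      missing <- !file.exists(cfg[[f]])
      if (any(missing))
        stop("missing coverage file: ", cfg[[f]][missing][1])
    }
  if (is.character(genome) && !file.exists(genome))
    stop("missing genome file: ", genome)
  class(cfg) <- "dap_config"
  cfg
}

load_config_inputs <- function(config) {
  genome <- config$genome
  if (is.character(genome)) {
    seqs <- read_fasta(genome)
    categories <- NULL
    if (!is.null(config$categories)) {
      bed <- read_intervals(config$categories, "BED6")
      categories <- data.frame(chrom = bed$chrom, start = bed$start,
                               end = bed$end, category = bed$name,
                               stringsAsFactors = FALSE)
    }
    genome <- dap_genome(seqs, categories)
  }
  load_tracks <- function(x) {
    if (is.character(x)) lapply(x, read_coverage, genome = genome) else x
  }
  list(genome = genome,
       tracks_a = load_tracks(config$tracks_a),
       tracks_b = load_tracks(config$tracks_b),
       genes = if (is.character(config$genes)) read_gene_models(config$genes)
               else config$genes,
       terms = if (is.character(config$terms)) read_term_map(config$terms)
               else config$terms)
}

#' Run the full differential binding pipeline
#'
#' Stages: per-replicate peak calling and replicate consensus for each
#' complex; merge of the two peak sets with CFR and specific-set
#' selection; PWM / first-order / KSM models from each complex's
#' best-bound peaks (KSM against a matched discovery background); AUROC
#' cross-evaluation against matched evaluation backgrounds; intersite
#' spacing preferences per specific set; term enrichment of the most
#' differentially bound peaks (when gene models and term maps are
#' supplied).  All outputs are written under `config$out_dir` when set;
#' results are also returned.  Identical config and seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return list with `peaks_a`, `peaks_b`, `merged`, `specific`,
#'   `models_a`, `models_b`, `auc`, `spacing_a`, `spacing_b`,
#'   `enrich_a`, `enrich_b`, `config`.
#' @export
run_pipeline <- function(config) {
  inp <- load_config_inputs(config)
  genome <- inp$genome
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  peaks_a <- stage("peaks_a", process_complex(
    inp$tracks_a, genome, config$min_height, config$min_width,
    config$flank, config$valley_fraction))
  peaks_b <- stage("peaks_b", process_complex(
    inp$tracks_b, genome, config$min_height, config$min_width,
    config$flank, config$valley_fraction))
  merged <- stage("merge", {
    m <- merge_peak_sets(peaks_a, peaks_b, inp$tracks_a, inp$tracks_b,
                         config$common_min, config$common_high)
    compute_cfr(m, config$cfr_pseudocount)
  })
  specific <- stage("select_specific",
                    select_specific(merged, config$fraction))
  build_models <- function(peaks, tracks, s) {
    best <- suppressWarnings(select_best_peaks(peaks, config$n_best))
    bg <- sample_matched_background(best, genome, seed = s)
    seqs <- region_seqs(genome, best)
    pwm <- build_pwm(seqs, config$pwm_width, config$pwm_palindromic,
                     config$pwm_pseudocount)
    fom <- build_first_order(pwm_align_sites(pwm, seqs),
                             config$pwm_pseudocount,
                             background = pwm$background)
    ksm <- discover_ksm(seqs, region_seqs(genome, bg$discovery),
                        config$kmin, config$kmax, config$ksm_window,
                        config$ksm_alpha)
    list(pwm = pwm, fom = fom, ksm = ksm, best = best)
  }
  models_a <- stage("models_a",
                    build_models(peaks_a, inp$tracks_a,
                                 derive_seed(seed, 11L)))
  models_b <- stage("models_b",
                    build_models(peaks_b, inp$tracks_b,
                                 derive_seed(seed, 12L)))
  auc <- stage("evaluate", {
    bg_a <- sample_matched_background(specific$a_specific, genome,
                                      seed = derive_seed(seed, 21L))
    bg_b <- sample_matched_background(specific$b_specific, genome,
                                      seed = derive_seed(seed, 22L))
    cross_evaluate(models_a[c("pwm", "fom", "ksm")],
                   models_b[c("pwm", "fom", "ksm")],
                   region_seqs(genome, specific$a_specific),
                   region_seqs(genome, specific$b_specific),
                   region_seqs(genome, bg_a$evaluation),
                   region_seqs(genome, bg_b$evaluation))
  })
  call_spacing <- function(regions, s) {
    prof <- spacing_profile(regions, genome, config$spacing_max_mismatch,
                            config$d_range)
    call_preferred_spacings(prof, config$n_shuffles, config$z_min, seed = s)
  }
  spacing_a <- stage("spacing_a",
                     call_spacing(specific$a_specific,
                                  derive_seed(seed, 31L)))
  spacing_b <- stage("spacing_b",
                     call_spacing(specific$b_specific,
                                  derive_seed(seed, 32L)))
  enrich_a <- enrich_b <- NULL
  if (!is.null(inp$genes) && !is.null(inp$terms)) {
    top_diff <- function(side) {
      o <- if (side == "A") order(merged$cfr, merged$chrom, merged$start)
           else order(-merged$cfr, merged$chrom, merged$start)
      merged[o[seq_len(min(config$enrich_top_n, nrow(merged)))], ,
             drop = FALSE]
    }
    run_enrich <- function(side) {
      genes <- assign_peaks_to_genes(top_diff(side), inp$genes,
                                     config$enrich_max_distance)
      term_enrichment(genes, inp$terms, unique(inp$genes$gene))
    }
    enrich_a <- stage("enrich_a", run_enrich("A"))
    enrich_b <- stage("enrich_b", run_enrich("B"))
  }
  result <- list(peaks_a = peaks_a, peaks_b = peaks_b, merged = merged,
                 specific = specific, models_a = models_a,
                 models_b = models_b, auc = auc, spacing_a = spacing_a,
                 spacing_b = spacing_b, enrich_a = enrich_a,
                 enrich_b = enrich_b, config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  out <- result$config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    con <- file(file.path(out, name), "w")
    on.exit(close(con))
    writeLines(sprintf("# duetdap %s seed=%d", duetdap_version(),
                       result$config$seed), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tsv(result$merged, "merged.tsv")
  for (side in c("a", "b")) {
    sp <- result$specific[[paste0(side, "_specific")]]
    write_intervals(
      data.frame(chrom = sp$chrom, start = sp$start, end = sp$end,
                 name = sp$class, score = sp$cfr),
      file.path(out, sprintf("specific_%s.bed", side)), "BED6")
    models <- result[[paste0("models_", side)]]
    mdir <- file.path(out, paste0("models_", side))
    dir.create(mdir, showWarnings = FALSE)
    write_pwm_meme(models$pwm, file.path(mdir, "pwm.meme"))
    write_model_json(models$fom, file.path(mdir, "first_order.json"))
    write_model_json(models$ksm, file.path(mdir, "ksm.json"))
    tsv(as.data.frame(result[[paste0("spacing_", side)]]),
        sprintf("spacing_%s.tsv", side))
    enr <- result[[paste0("enrich_", side)]]
    if (!is.null(enr)) tsv(enr, sprintf("enrich_%s.tsv", side))
  }
  tsv(result$auc, "auc.tsv")
  log <- c(sprintf("duetdap %s", duetdap_version()),
           sprintf("seed: %d", result$config$seed),
           sprintf("peaks_a: %d  peaks_b: %d  merged: %d",
                   nrow(result$peaks_a), nrow(result$peaks_b),
                   nrow(result$merged)))
  writeLines(log, file.path(out, "run.log"))
  invisible(out)
}
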