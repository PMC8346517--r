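## I/O for the plain-text formats the pipeline touches: FASTA, BED6,
## narrowPeak, 4-column bedGraph, TSV tables.  All coordinates written and
## read are 0-based half-open (BED-native).

#' Genome container
#'
#' Bundles chromosome sequences with an optional feature-category annotation
#' (promoter / exon / intron / intergenic blocks that tile each chromosome).
#'
#' @param seq named character vector of chromosome sequences over ACGTN.
#' @param categories optional data.frame with columns `chrom`, `start`,
#'   `end`, `category`; blocks must be non-overlapping and tile each
#'   chromosome exactly.
#' @return an object of class `dap_genome`: a list with elements `seq`
#'   and `categories`.
#' @export
dap_genome <- function(seq, categories = NULL) {
  if (is.null(names(seq)) || anyDuplicated(names(seq)))
    stop("sequences must have unique names")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("non-ACGTN character in sequence(s): ",
         paste(names(seq)[bad], collapse = ", "))
  if (!is.null(categories)) {
    categories <- order_intervals(categories)
    for (chrom in names(seq)) {
      blk <- categories[categories$chrom == chrom, , drop = FALSE]
      if (nrow(blk) == 0L) next
      if (blk$start[1] != 0L || blk$end[nrow(blk)] != nchar(seq[[chrom]]) ||
          (nrow(blk) > 1L && any(blk$start[-1] != blk$end[-nrow(blk)])))
        stop("category blocks must tile chromosome ", chrom, " exactly")
    }
  }
  structure(list(seq = seq, categories = categories), class = "dap_genome")
}

#' @export
print.dap_genome <- function(x, ...) {
  cat("dap_genome:", length(x$seq), "sequence(s),",
      sum(nchar(x$seq)), "bp total\n")
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are uppercased; line wrapping is ignored.  Only A, C, G, T, N
#' are accepted; duplicate record ids are an error.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN character in record(s): ",
         paste(ids[bad], collapse = ", "))
  seqs
}

#' Write sequences as FASTA
#'
#' Records are written in lexicographic id order, wrapped at 80 columns.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param wrap line width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 80L) {
  if (length(seqs) == 0L) stop("no sequences to write")
  if (any(nchar(seqs) == 0L)) stop("empty sequence")
  seqs <- seqs[order(names(seqs))]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read genomic intervals (BED6 or narrowPeak)
#'
#' Coordinates are 0-based half-open.  For narrowPeak, column 10 is the
#' summit offset from `start` (-1 means unknown) and is returned as the
#' absolute `summit` position (or `NA`).
#'
#' @param path path to a tab-separated interval file; `#` lines skipped.
#' @param dialect `"BED6"` or `"narrowPeak"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` and, for narrowPeak, `summit`.
#' @export
read_intervals <- function(path, dialect = c("BED6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer",
                                  rep(NA, if (dialect == "BED6") 3L else 7L)),
                   fill = TRUE)
  out <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                    name = if (ncol(df) >= 4) as.character(df[[4]]) else ".",
                    score = if (ncol(df) >= 5) as.numeric(df[[5]]) else 0,
                    strand = if (ncol(df) >= 6) as.character(df[[6]]) else ".",
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end))
    stop("interval with start >= end")
  if (any(out$start < 0L))
    stop("negative start coordinate")
  if (dialect == "narrowPeak") {
    off <- if (ncol(df) >= 10) as.integer(df[[10]]) else rep(-1L, nrow(df))
    out$summit <- ifelse(off < 0L, NA_integer_, out$start + off)
    bad <- !is.na(out$summit) & (out$summit < out$start | out$summit >= out$end)
    if (any(bad)) stop("summit outside interval")
  }
  out
}

#' Write genomic intervals (BED6 or narrowPeak)
#'
#' Rows are sorted by (chrom, start, end); a `#` header comment records the
#' tool version.
#'
#' @param items data.frame with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`, `summit`.
#' @param path output path.
#' @param dialect `"BED6"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(items, path, dialect = c("BED6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  items <- order_intervals(items)
  n <- nrow(items)
  name <- if ("name" %in% names(items)) items$name else rep(".", n)
  score <- if ("score" %in% names(items)) items$score else rep(0, n)
  strand <- if ("strand" %in% names(items)) items$strand else rep(".", n)
  cols <- list(items$chrom, as.integer(items$start), as.integer(items$end),
               name, score, strand)
  if (dialect == "narrowPeak") {
    summit <- if ("summit" %in% names(items)) items$summit else
      rep(NA_integer_, n)
    off <- ifelse(is.na(summit), -1L, as.integer(summit - items$start))
    cols <- c(cols, list(rep(0, n), rep(-1, n), rep(-1, n), off))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# duetdap ", duetdap_version(), " ", dialect), con)
  write.table(as.data.frame(cols), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coverage track container
#'
#' Per-base signal vectors for each chromosome plus the library size
#' (total mapped reads) used for normalisation.
#'
#' @param values named list of non-negative numeric vectors, one per
#'   chromosome, with lengths equal to the chromosome lengths.
#' @param library_size total mapped reads; defaults to the summed signal.
#' @return an object of class `dap_track`.
#' @export
dap_track <- function(values, library_size = NULL) {
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("coverage values must be >= 0")
  if (is.null(library_size)) library_size <- sum(vapply(values, sum, 0))
  structure(list(values = values, library_size = library_size),
            class = "dap_track")
}

#' @export
print.dap_track <- function(x, ...) {
  cat("dap_track:", length(x$values), "chromosome(s), library_size =",
      format(x$library_size), "\n")
  invisible(x)
}

#' Read a bedGraph coverage track
#'
#' Four-column bedGraph; bases not covered by any line get value 0.
#' Overlapping lines and out-of-bounds intervals are errors.  A
#' `# library_size=<n>` header comment, if present, is honoured.
#'
#' @param path bedGraph path.
#' @param genome a [dap_genome] providing chromosome lengths.
#' @return a [dap_track].
#' @export
read_coverage <- function(path, genome) {
  first <- readLines(path, n = 5L)
  lib <- NA_real_
  m <- regmatches(first, regexpr("# library_size=([0-9.eE+]+)", first))
  if (length(unlist(m)))
    lib <- as.numeric(sub("# library_size=", "", unlist(m)[1]))
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric"))
  values <- lapply(names(genome$seq), function(ch) {
    len <- nchar(genome$seq[[ch]])
    v <- numeric(len)
    rows <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(rows)) {
      if (any(rows$start < 0L | rows$end > len))
        stop("bedGraph interval out of bounds on ", ch)
      rows <- rows[order(rows$start), , drop = FALSE]
      if (nrow(rows) > 1L && any(rows$start[-1] < rows$end[-nrow(rows)]))
        stop("overlapping bedGraph lines on ", ch)
      for (i in seq_len(nrow(rows)))
        v[(rows$start[i] + 1L):rows$end[i]] <- rows$value[i]
    }
    v
  })
  names(values) <- names(genome$seq)
  unknown <- setdiff(unique(df$chrom), names(genome$seq))
  if (length(unknown)) stop("unknown chromosome in bedGraph: ", unknown[1])
  dap_track(values, library_size = if (is.na(lib)) NULL else lib)
}

#' Write a coverage track as bedGraph
#'
#' Run-length compressed; zero runs are omitted, so an all-zero track has
#' an empty body.
#'
#' @param track a [dap_track].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duetdap %s bedGraph", duetdap_version()), con)
  writeLines(sprintf("# library_size=%.10g", track$library_size), con)
  for (ch in sort(names(track$values))) {
    r <- rle(track$values[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.10g", ch, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

duetdap_version <- function() {
  as.character(utils::packageVersion("duetdap"))
}
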