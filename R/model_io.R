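## On-disk model formats: MEME minimal motif format for PWMs, documented
## JSON for first-order and KSM models.  Numbers are written at full
## precision so read(write(x)) is bit-exact.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a PWM in MEME minimal motif format
#'
#' Package metadata (pseudocount, palindromic flag) is carried in `#`
#' comment lines, which MEME-suite parsers ignore.
#'
#' @param pwm a [build_pwm()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm_meme <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(rbind(BASES, fmt_num(pwm$background)), collapse = " "),
               "", "MOTIF motif1",
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 0 E= 0",
                       pwm$width)), con)
  for (j in seq_len(pwm$width))
    writeLines(paste(fmt_num(pwm$probs[, j]), collapse = " "), con)
  writeLines(c(sprintf("# duetdap pseudocount= %s", fmt_num(pwm$pseudocount)),
               sprintf("# duetdap palindromic= %d",
                       as.integer(pwm$palindromic))), con)
  invisible(path)
}

#' Read a PWM from MEME minimal motif format
#'
#' @param path path written by [write_pwm_meme()] (or any minimal-format
#'   single-motif MEME file).
#' @return a `dap_pwm`.
#' @export
read_pwm_meme <- function(path) {
  lines <- readLines(path)
  bgl <- lines[grep("^Background letter frequencies", lines) + 1L]
  bgv <- strsplit(trimws(bgl), "\\s+")[[1]]
  background <- stats::setNames(as.numeric(bgv[c(2, 4, 6, 8)]),
                                bgv[c(1, 3, 5, 7)])
  hdr <- grep("^letter-probability matrix", lines)
  w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
  rows <- lines[(hdr + 1L):(hdr + w)]
  probs <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(x) as.numeric(x), numeric(4)))
  probs <- t(probs)
  dimnames(probs) <- list(BASES, NULL)
  pc_line <- grep("# duetdap pseudocount=", lines, value = TRUE)
  pal_line <- grep("# duetdap palindromic=", lines, value = TRUE)
  structure(list(
    width = w, probs = probs, background = background,
    pseudocount = if (length(pc_line))
      as.numeric(sub(".*= ", "", pc_line)) else 0.25,
    palindromic = if (length(pal_line))
      as.logical(as.integer(sub(".*= ", "", pal_line))) else FALSE),
    class = "dap_pwm")
}

#' Write a first-order or KSM model as JSON
#'
#' @param model a `dap_fom` or `dap_ksm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  type <- class(model)[1]
  obj <- unclass(model)
  if (type == "dap_fom") {
    obj$initial <- as.list(obj$initial)
    obj$background <- as.list(obj$background)
    obj$transitions <- lapply(obj$transitions, function(m)
      stats::setNames(lapply(seq_len(4), function(i) unname(m[i, ])), BASES))
  }
  ## digits = I(17) gives significant (not decimal) digits: doubles
  ## round-trip bit-exactly
  jsonlite::write_json(list(format = "duetdap-model", type = type,
                            version = duetdap_version(), model = obj),
                       path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a model written by [write_model_json()]
#'
#' @param path JSON path.
#' @return a `dap_fom` or `dap_ksm`.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (!identical(x$format, "duetdap-model")) stop("not a duetdap model file")
  m <- x$model
  if (x$type == "dap_fom") {
    m$width <- as.integer(m$width)
    m$initial <- unlist(m$initial)
    m$background <- unlist(m$background)
    m$transitions <- lapply(m$transitions, function(tr) {
      mat <- do.call(rbind, lapply(tr, unlist))
      dimnames(mat) <- list(BASES, BASES)
      mat
    })
  } else if (x$type == "dap_ksm") {
    for (f in c("kmin", "kmax", "window", "n_bound_seqs", "n_unbound_seqs"))
      m[[f]] <- as.integer(m[[f]])
    m$clusters <- lapply(m$clusters, function(cl) {
      cl$members <- unlist(cl$members)
      cl$offsets <- as.integer(unlist(cl$offsets))
      cl$strands <- unlist(cl$strands)
      cl$n_bound <- as.integer(cl$n_bound)
      cl$n_unbound <- as.integer(cl$n_unbound)
      cl
    })
  } else stop("unknown model type: ", x$type)
  structure(m, class = x$type)
}
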