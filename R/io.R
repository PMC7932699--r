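#' @name io
#' @title Plain-text format readers and writers
#' @description
#' All genomic coordinates are 0-based half-open (BED convention)
#' internally. Writers are deterministic: stable row order and fixed
#' float formatting (6 significant digits), so written files diff
#' cleanly. Readers fail with the offending line number on malformed
#' input.
NULL

fmt_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15, format(x, scientific = FALSE, trim = TRUE),
         formatC(x, digits = 6, format = "g"))
}

#' Read a BED file of peak intervals
#' @param path BED file (>= 3 columns; optional name, score, strand,
#'   summit offset as columns 4-7).
#' @return data.frame `chrom`, `start`, `end` plus any optional columns.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) stop("malformed BED line ", which(nf < 3)[1], " in ", path)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2))),
                    end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3))),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end))
    stop("non-numeric coordinate at BED line ",
         which(is.na(out$start) | is.na(out$end))[1], " in ", path)
  if (any(out$start < 0 | out$end <= out$start))
    stop("coordinate violation at BED line ",
         which(out$start < 0 | out$end <= out$start)[1], " in ", path)
  extras <- c("name", "score", "strand", "summit")
  for (k in 4:7) {
    if (all(nf >= k)) {
      v <- vapply(parts, `[`, "", k)
      out[[extras[k - 3]]] <- if (extras[k - 3] %in% c("score", "summit"))
        as.numeric(v) else v
    }
  }
  out
}

#' Write intervals as BED
#' @param x data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`, `summit`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_peaks(x)
  opt <- c("name", "score", "strand", "summit")
  last <- max(c(0, which(opt %in% names(x))))
  defaults <- list(name = ".", score = 0, strand = ".", summit = 0)
  cols <- list(x$chrom, x$start, x$end)
  for (nm in opt[seq_len(last)]) {
    v <- x[[nm]] %||% defaults[[nm]]
    cols <- c(cols, list(if (is.numeric(v)) fmt_num(v) else v))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a chrom.sizes table
#' @param path two-column TSV: chromosome name, length.
#' @return data.frame `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", col.names = c("chrom", "size"),
                         colClasses = c("character", "integer"))
  assert_that(all(x$size > 0), "non-positive chromosome size")
  x
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' The 12-column tabular dialect; only query id (1), subject id (2),
#' e-value (11) and bitscore (12) are consumed. The subject species is
#' a per-file tag, never parsed from ids.
#'
#' @param path tabular hit file.
#' @param subject_species species tag recorded on every row.
#' @return data.frame `query_id`, `subject_species`, `subject_id`,
#'   `evalue`, `bitscore`.
#' @export
read_outfmt6 <- function(path, subject_species) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12)
  if (length(bad)) stop("malformed outfmt6 line ", bad[1], " in ", path,
                        " (expected 12 fields)")
  out <- data.frame(
    query_id = vapply(parts, `[`, "", 1),
    subject_species = subject_species,
    subject_id = vapply(parts, `[`, "", 2),
    evalue = as.numeric(vapply(parts, `[`, "", 11)),
    bitscore = as.numeric(vapply(parts, `[`, "", 12)),
    stringsAsFactors = FALSE)
  assert_that(!anyNA(out$evalue) && !anyNA(out$bitscore),
              "non-numeric score fields in outfmt6 file")
  out
}

#' Write a hit table in the 12-column tabular dialect
#'
#' Unconsumed columns (identity, alignment length, mismatches, gap
#' opens, coordinates) are written as zeros.
#'
#' @param hits data.frame with `query_id`, `subject_id`, `evalue`,
#'   `bitscore`.
#' @param path output path.
#' @export
write_outfmt6 <- function(hits, path) {
  writeLines(paste(hits$query_id, hits$subject_id, "0", "0", "0", "0",
                   "0", "0", "0", "0",
                   formatC(hits$evalue, digits = 6, format = "g"),
                   fmt_num(hits$bitscore), sep = "\t"), path)
  invisible(path)
}

#' Read a long-format expression TSV
#'
#' Expected columns: `gene`, `stage`, `replicate`, `tpm` (header
#' required).
#'
#' @param path TSV path.
#' @param species species label for the resulting matrix.
#' @param stages optional stage order (default: order of appearance).
#' @return an `ExpressionMatrix`.
#' @export
read_expression_tsv <- function(path, species, stages = NULL) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  req <- c("gene", "stage", "replicate", "tpm")
  assert_that(all(req %in% names(x)),
              "expression TSV needs columns gene, stage, replicate, tpm")
  x$transcript <- x$gene
  aggregate_expression(x, data.frame(transcript = unique(x$gene),
                                     gene = unique(x$gene)),
                       species = species, stages = stages)
}

#' Write an ExpressionMatrix as a long-format TSV
#' @param m an `ExpressionMatrix`.
#' @param path output path.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  d <- dim(m$replicate_tpm)
  long <- data.frame(
    gene = rep(m$genes, times = d[2] * d[3]),
    stage = rep(rep(m$stages, each = d[1]), times = d[3]),
    replicate = rep(seq_len(d[3]), each = d[1] * d[2]),
    tpm = as.vector(m$replicate_tpm))
  long <- long[order(long$gene, match(long$stage, m$stages), long$replicate), ]
  con <- file(path, "w")
  writeLines("gene\tstage\treplicate\ttpm", con)
  writeLines(paste(long$gene, long$stage, long$replicate,
                   fmt_num(long$tpm), sep = "\t"), con)
  close(con)
  invisible(path)
}

#' Write a generic matrix as a tagged TSV
#' @param x matrix with dimnames.
#' @param path output path.
#' @param tag optional comment line (e.g. the scaling method or metric)
#'   written as `# tag` before the header.
#' @export
write_matrix_tsv <- function(x, path, tag = NULL) {
  con <- file(path, "w")
  if (!is.null(tag)) writeLines(paste0("# ", tag), con)
  writeLines(paste(c("id", colnames(x)), collapse = "\t"), con)
  writeLines(paste(rownames(x),
                   apply(x, 1, function(r) paste(fmt_num(r), collapse = "\t")),
                   sep = "\t"), con)
  close(con)
  invisible(path)
}

#' Read a JASPAR-style PWM text file
#'
#' Four lines of per-base counts, optionally preceded by a `>id`
#' header, in A/C/G/T order; bracketed JASPAR formatting
#' (`A [ 4 19 0 ]`) is accepted.
#'
#' @param path PWM text file.
#' @param ... passed to [pwm()] (background, pseudocount).
#' @return a `PWM`.
#' @export
read_pwm <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  id <- "motif"
  if (startsWith(lines[1], ">")) {
    id <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  assert_that(length(lines) == 4, "PWM file must have 4 base rows")
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("\\[|\\]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  assert_that(length(unique(lengths(rows))) == 1, "ragged PWM rows")
  pwm(do.call(rbind, rows), id = id, ...)
}
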