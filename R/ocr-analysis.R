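#' Conserved fraction of peak bases from alignment scores
#'
#' Peaks are re-distributed into fine bins (100 bp by convention,
#' [assign_to_bins()]), each binned sequence is aligned against another
#' genome, and a bin counts as conserved when its best alignment hit
#' scores at least `score_min` (inclusive; default 40). The statistic
#' is the fraction of total occupied-bin length that is conserved --
#' length of conserved sequence in the peaks, not a count of conserved
#' peaks.
#'
#' @param binned `BinnedPeaks` on the fine grid.
#' @param hits data.frame of alignment hits with columns `chrom`,
#'   `start`, `end` (query interval on the focal genome), `target`
#'   (target genome id), `score`. A hit contributes its score to every
#'   bin it overlaps.
#' @param score_min conservation score threshold (inclusive).
#' @param by_target also return per-target-genome fractions.
#' @return list with `fraction` (conserved length / occupied length),
#'   `not_conserved_fraction` (bins with no hit against any genome; the
#'   negative control), `conserved_length`, `total_length`, and
#'   optionally `fraction_by_target`.
#' @export
conserved_fraction <- function(binned, hits, score_min = 40, by_target = FALSE) {
  stopifnot(inherits(binned, "BinnedPeaks"))
  assert_that(nrow(binned$bins) > 0, "empty peak set")
  keys <- occupied_keys(binned)
  blen <- binned$bins$end - binned$bins$start
  total <- sum(blen)
  best <- rep(-Inf, length(keys))
  names(best) <- keys
  hit_keys_of <- function(h) {
    # bins overlapped by each hit interval, on the binned grid
    w <- binned$grid$bin_width
    out <- vector("list", nrow(h))
    for (i in seq_len(nrow(h))) {
      starts <- seq((h$start[i] %/% w) * w, h$end[i] - 1, by = w)
      out[[i]] <- bin_key(as.character(h$chrom[i]), starts)
    }
    out
  }
  if (nrow(hits) > 0) {
    hk <- hit_keys_of(hits)
    for (i in seq_along(hk)) {
      j <- match(hk[[i]], keys)
      j <- j[!is.na(j)]
      if (length(j)) best[j] <- pmax(best[j], hits$score[i])
    }
  }
  conserved <- best >= score_min
  out <- list(fraction = sum(blen[conserved]) / total,
              not_conserved_fraction = sum(blen[!is.finite(best)]) / total,
              conserved_length = sum(blen[conserved]),
              total_length = total)
  if (by_target && nrow(hits) > 0) {
    out$fraction_by_target <- vapply(split(hits, hits$target), function(h) {
      conserved_fraction(binned, h, score_min)$fraction
    }, numeric(1))
  }
  out
}

#' Fraction of reads in peaks (FRiP)
#'
#' Library-quality score: reads overlapping any peak divided by the
#' total read count. Passing requires `score >= qc_min` (default 0.2,
#' the replicate-inclusion rule).
#'
#' @param reads data.frame of read intervals (`chrom`, `start`, `end`),
#'   or a single precomputed in-peak read count.
#' @param peaks data.frame of peak intervals (`chrom`, `start`, `end`);
#'   ignored when `reads` is a count.
#' @param total_reads total sequenced reads (default: `nrow(reads)`).
#' @param qc_min QC pass threshold (inclusive).
#' @return list with `score`, `pass`, `reads_in_peaks`, `total_reads`.
#' @export
frip <- function(reads, peaks = NULL, total_reads = NULL, qc_min = 0.2) {
  if (is.numeric(reads) && length(reads) == 1) {
    assert_that(!is.null(total_reads) && total_reads > 0,
                "total_reads must be a positive count")
    n_in <- reads
  } else {
    total_reads <- total_reads %||% nrow(reads)
    assert_that(total_reads > 0, "total_reads must be a positive count")
    validate_peaks(peaks)
    n_in <- 0L
    for (chrom in unique(as.character(reads$chrom))) {
      r <- reads[reads$chrom == chrom, , drop = FALSE]
      p <- peaks[peaks$chrom == chrom, , drop = FALSE]
      if (nrow(p) == 0) next
      # IRanges is 1-based closed; half-open [s,e) maps to s+1..e
      ov <- IRanges::countOverlaps(
        IRanges::IRanges(r$start + 1L, r$end),
        IRanges::IRanges(p$start + 1L, p$end))
      n_in <- n_in + sum(ov > 0)
    }
  }
  score <- n_in / total_reads
  list(score = score, pass = score >= qc_min,
       reads_in_peaks = n_in, total_reads = total_reads)
}

#' Differential accessibility between consecutive stages, per bin
#'
#' Per genomic bin, a two-sided two-sample Student's t-test between the
#' replicate coverage values of consecutive stages; bins below `alpha`
#' are counted as increased (later mean higher) or decreased. No
#' multiple-testing correction by default (volcano-count convention);
#' Benjamini-Hochberg available.
#'
#' @param signal numeric matrix, bins x samples (e.g. 200-bp bin
#'   coverage), with rownames as bin ids.
#' @param groups list mapping stage name -> column indices or names,
#'   in developmental order; >= 2 replicates per stage.
#' @param alpha significance threshold.
#' @param adjust p-value adjustment method (`"none"` default, or
#'   `"BH"`).
#' @param min_fold optional fold-change floor on |mean ratio| (none by
#'   default).
#' @return list with `counts` (data.frame per transition: `from`, `to`,
#'   `increased`, `decreased`, `tested`, `skipped`) and `tests` (per
#'   transition, data.frame of per-bin `t`, `p`, `diff`). Bins with
#'   zero variance in both groups are skipped.
#' @export
differential_bins <- function(signal, groups, alpha = 0.05,
                              adjust = c("none", "BH"), min_fold = NULL) {
  adjust <- match.arg(adjust)
  signal <- as.matrix(signal)
  stages <- names(groups)
  assert_that(length(stages) >= 2, "need at least two stages")
  for (g in groups) assert_that(length(g) >= 2, "need >= 2 replicates per stage")
  tests <- list(); counts <- list()
  for (k in seq_len(length(stages) - 1)) {
    x <- signal[, groups[[k]], drop = FALSE]
    y <- signal[, groups[[k + 1]], drop = FALSE]
    nx <- ncol(x); ny <- ncol(y)
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
    skip <- vx == 0 & vy == 0
    # classical (equal-variance) Student's t
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tstat <- (my - mx) / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- 2 * stats::pt(-abs(tstat), df = nx + ny - 2)
    p[skip] <- NA
    if (adjust == "BH") p <- stats::p.adjust(p, "BH")
    sig <- !is.na(p) & p < alpha
    if (!is.null(min_fold)) {
      fold <- pmax(my, .Machine$double.eps) / pmax(mx, .Machine$double.eps)
      sig <- sig & (pmax(fold, 1 / fold) >= min_fold)
    }
    lab <- paste(stages[k], stages[k + 1], sep = "->")
    tests[[lab]] <- data.frame(bin = rownames(signal) %||% seq_len(nrow(signal)),
                               t = tstat, p = p, diff = my - mx)
    counts[[lab]] <- data.frame(from = stages[k], to = stages[k + 1],
                                increased = sum(sig & my > mx),
                                decreased = sum(sig & my < mx),
                                tested = sum(!skip), skipped = sum(skip))
  }
  list(counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
       tests = tests)
}

#' Position weight matrix constructor
#'
#' @param mat 4 x L numeric matrix of per-position base probabilities
#'   (rows A, C, G, T; columns sum to 1) or counts (normalized).
#' @param id motif identifier.
#' @param background background base frequencies (default uniform).
#' @param pseudocount added to probabilities before the log-odds
#'   transform (default 0.01).
#' @return a `PWM` object with the log2-odds score matrix.
#' @export
pwm <- function(mat, id = "motif", background = rep(0.25, 4),
                pseudocount = 0.01) {
  mat <- as.matrix(mat)
  assert_that(nrow(mat) == 4, "PWM needs 4 rows (A, C, G, T)")
  assert_that(all(mat >= 0), "negative PWM entries")
  assert_that(all(colSums(mat) > 0), "empty PWM column")
  rownames(mat) <- c("A", "C", "G", "T")
  prob <- sweep(mat, 2, colSums(mat), "/")
  prob <- sweep(prob + pseudocount, 2, colSums(prob + pseudocount), "/")
  lo <- log2(prob / background)
  structure(list(id = id, prob = prob, log_odds = lo,
                 background = background, pseudocount = pseudocount,
                 max_score = sum(apply(lo, 2, max)),
                 width = ncol(mat)),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, max log2-odds score %.3f\n",
              x$id, x$width, x$max_score))
  invisible(x)
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

# score every window of one sequence on one strand; windows containing
# N (or any non-ACGT) score -Inf
scan_one_strand <- function(seq, p) {
  L <- p$width
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < L) return(numeric(0))
  code <- match(chars, c("A", "C", "G", "T"))   # NA for N etc.
  scores <- numeric(n - L + 1)
  for (j in seq_len(L)) {
    idx <- code[j:(j + n - L)]
    col <- p$log_odds[, j]
    s <- col[idx]
    s[is.na(idx)] <- -Inf
    scores <- scores + s
  }
  scores
}

#' Count motif occurrences in sequences
#'
#' Scans both strands of each sequence with the PWM's log-odds scores
#' and counts windows scoring at least `frac` of the maximum attainable
#' motif score (default 75%). Windows containing N never match.
#'
#' @param sequences character vector of nucleotide strings over
#'   A,C,G,T,N (e.g. OCR sequences).
#' @param p a [pwm()].
#' @param frac fraction of the maximum score required (inclusive).
#' @param stage optional per-sequence stage labels for the mean count
#'   per OCR per stage.
#' @return list with `counts` (per sequence) and, if `stage` is given,
#'   `mean_by_stage`.
#' @export
motif_occurrences <- function(sequences, p, frac = 0.75, stage = NULL) {
  stopifnot(inherits(p, "PWM"))
  sequences <- toupper(sequences)
  thr <- frac * p$max_score
  counts <- vapply(sequences, function(s) {
    fw <- scan_one_strand(s, p)
    rv <- scan_one_strand(revcomp(s), p)
    sum(fw >= thr) + sum(rv >= thr)
  }, integer(1), USE.NAMES = FALSE)
  out <- list(counts = counts)
  if (!is.null(stage)) {
    assert_that(length(stage) == length(sequences),
                "stage must have one label per sequence")
    out$mean_by_stage <- tapply(counts, stage, mean)
  }
  out
}
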