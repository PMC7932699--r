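#' Gene-by-stage expression matrix for one species
#'
#' Container for a replicated developmental expression time course of one
#' species: per-replicate TPM values as a gene x stage x replicate array,
#' plus the replicate mean and standard error per gene and stage. Stage
#' order is fixed at construction and drives every downstream rank-based
#' statistic (heterochrony correlations, stage z-scores, stage distances).
#'
#' @param replicate_tpm numeric array, gene x stage x replicate, all
#'   values >= 0. Dimnames for genes and stages are taken from the array
#'   unless given explicitly.
#' @param species single species label.
#' @param genes,stages optional character vectors overriding the array
#'   dimnames; `stages` is kept in the given order.
#' @return An object of class `ExpressionMatrix` with fields `species`,
#'   `genes`, `stages`, `replicate_tpm`, `mean_tpm`, `sem_tpm`.
#' @details The mean is the arithmetic mean over replicates; the standard
#'   error uses the sample standard deviation (divisor n-1) divided by
#'   sqrt(n). With a single replicate the SEM is reported as `NA`.
#' @export
expression_matrix <- function(replicate_tpm, species, genes = NULL, stages = NULL) {
  assert_that(is.array(replicate_tpm) && length(dim(replicate_tpm)) == 3,
              "replicate_tpm must be a gene x stage x replicate array")
  assert_that(all(replicate_tpm >= 0), "TPM values must be non-negative")
  genes <- genes %||% dimnames(replicate_tpm)[[1]] %||%
    paste0("g", seq_len(dim(replicate_tpm)[1]))
  stages <- stages %||% dimnames(replicate_tpm)[[2]] %||%
    paste0("s", seq_len(dim(replicate_tpm)[2]))
  assert_that(length(stages) >= 1 && !anyDuplicated(stages),
              "stages must be non-empty and duplicate-free")
  assert_that(dim(replicate_tpm)[3] >= 1, "at least one replicate required")
  dimnames(replicate_tpm) <- list(genes, stages,
                                  paste0("rep", seq_len(dim(replicate_tpm)[3])))
  mean_tpm <- apply(replicate_tpm, c(1, 2), mean)
  n_rep <- dim(replicate_tpm)[3]
  sem_tpm <- if (n_rep > 1) {
    apply(replicate_tpm, c(1, 2), stats::sd) / sqrt(n_rep)
  } else {
    matrix(NA_real_, nrow = length(genes), ncol = length(stages),
           dimnames = list(genes, stages))
  }
  structure(
    list(species = species, genes = genes, stages = stages,
         replicate_tpm = replicate_tpm, mean_tpm = mean_tpm, sem_tpm = sem_tpm),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: species '%s', %d genes x %d stages x %d replicates\n",
              x$species, length(x$genes), length(x$stages),
              dim(x$replicate_tpm)[3]))
  cat("stages:", paste(x$stages, collapse = " "), "\n")
  invisible(x)
}

#' Aggregate transcript-level TPMs to gene level
#'
#' Sums TPM over the splicing variants of each gene, per stage and
#' replicate, and builds an [expression_matrix()] from the result.
#' Transcripts without a gene mapping are dropped with a warning.
#'
#' @param transcript_tpm data.frame with columns `transcript`, `stage`,
#'   `replicate`, `tpm` (long format).
#' @param tx2gene data.frame with columns `transcript`, `gene`; every
#'   transcript must map to exactly one gene.
#' @param species species label for the result.
#' @param stages optional stage order; defaults to order of appearance.
#' @return An `ExpressionMatrix` at gene level.
#' @export
aggregate_expression <- function(transcript_tpm, tx2gene, species,
                                 stages = NULL) {
  req <- c("transcript", "stage", "replicate", "tpm")
  assert_that(all(req %in% names(transcript_tpm)),
              "transcript_tpm needs columns transcript, stage, replicate, tpm")
  assert_that(nrow(transcript_tpm) > 0, "empty transcript table")
  assert_that(!anyDuplicated(tx2gene$transcript),
              "a transcript maps to more than one gene")
  idx <- match(transcript_tpm$transcript, tx2gene$transcript)
  if (anyNA(idx)) {
    orphans <- unique(transcript_tpm$transcript[is.na(idx)])
    warning(sprintf("%d transcript(s) without gene mapping excluded: %s",
                    length(orphans),
                    paste(utils::head(orphans, 5), collapse = ", ")))
    transcript_tpm <- transcript_tpm[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  assert_that(nrow(transcript_tpm) > 0, "no mapped transcripts left")
  transcript_tpm$gene <- tx2gene$gene[idx]
  stages <- stages %||% unique(as.character(transcript_tpm$stage))
  reps <- sort(unique(transcript_tpm$replicate))
  genes <- sort(unique(transcript_tpm$gene))
  arr <- array(0, dim = c(length(genes), length(stages), length(reps)),
               dimnames = list(genes, stages, NULL))
  gi <- match(transcript_tpm$gene, genes)
  si <- match(as.character(transcript_tpm$stage), stages)
  ri <- match(transcript_tpm$replicate, reps)
  assert_that(!anyNA(si), "stage value not in the given stage order")
  flat <- gi + (si - 1L) * length(genes) +
    (ri - 1L) * length(genes) * length(stages)
  sums <- tapply(transcript_tpm$tpm, flat, sum)
  arr[as.integer(names(sums))] <- as.numeric(sums)
  expression_matrix(arr, species = species, genes = genes, stages = stages)
}

#' Expression filter: drop genes never reaching a TPM floor
#'
#' A gene counts as expressed if the maximum over stages of its mean TPM
#' reaches `min_max_tpm` (default 1.0; genes with maximum TPM < 1 are
#' treated as not expressed).
#'
#' @param m an `ExpressionMatrix`.
#' @param min_max_tpm inclusive threshold on the per-gene stage maximum.
#' @return character vector of expressed gene ids.
#' @export
filter_expressed <- function(m, min_max_tpm = 1.0) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  keep <- apply(m$mean_tpm, 1, max) >= min_max_tpm
  m$genes[keep]
}

#' Subset an ExpressionMatrix to a gene set
#' @param m an `ExpressionMatrix`.
#' @param genes gene ids to keep (order preserved as given).
#' @return an `ExpressionMatrix` over `genes`.
#' @export
subset_genes <- function(m, genes) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  assert_that(all(genes %in% m$genes), "unknown gene id in subset")
  expression_matrix(m$replicate_tpm[genes, , , drop = FALSE],
                    species = m$species, genes = genes, stages = m$stages)
}

#' Scale a gene expression matrix
#'
#' The four scaling methods applied per gene over that species' stages:
#' \describe{
#'   \item{max1}{x / max_t(x): each gene's peak is set to 1.}
#'   \item{zscore}{(x - mean_t(x)) / sd_t(x); population sd (divisor T).}
#'   \item{unitvec}{x / ||x||_2: each gene's profile has Euclidean norm 1.}
#'   \item{log10}{log10(x + 1).}
#' }
#'
#' @param m an `ExpressionMatrix` (mean TPMs are scaled).
#' @param method one of `"max1"`, `"zscore"`, `"unitvec"`, `"log10"`.
#' @param sd_type `"population"` (default) or `"sample"` sd convention
#'   for the zscore method.
#' @return A `ScaledMatrix`: list with `method`, `species`, `stages`,
#'   and `values` (gene x stage matrix).
#' @details Genes violating the method's precondition raise an error:
#'   all-zero profiles for max1/unitvec, zero-variance profiles for
#'   zscore. Callers filter first (see [filter_expressed()]).
#' @export
scale_expression <- function(m, method = c("max1", "zscore", "unitvec", "log10"),
                             sd_type = c("population", "sample")) {
  method <- match.arg(method)
  sd_type <- match.arg(sd_type)
  x <- if (inherits(m, "ExpressionMatrix")) m$mean_tpm else as.matrix(m)
  species <- if (inherits(m, "ExpressionMatrix")) m$species else NA_character_
  vals <- switch(method,
    max1 = {
      mx <- apply(x, 1, max)
      if (any(mx <= 0)) stop("max1 scaling undefined for all-zero gene(s): ",
                             paste(utils::head(rownames(x)[mx <= 0], 5), collapse = ", "))
      x / mx
    },
    zscore = {
      mu <- rowMeans(x)
      sdv <- if (sd_type == "population") apply(x, 1, pop_sd) else apply(x, 1, stats::sd)
      if (any(sdv == 0)) stop("zscore scaling undefined for zero-variance gene(s): ",
                              paste(utils::head(rownames(x)[sdv == 0], 5), collapse = ", "))
      (x - mu) / sdv
    },
    unitvec = {
      nrm <- sqrt(rowSums(x^2))
      if (any(nrm == 0)) stop("unitvec scaling undefined for all-zero gene(s): ",
                              paste(utils::head(rownames(x)[nrm == 0], 5), collapse = ", "))
      x / nrm
    },
    log10 = log10(x + 1)
  )
  structure(list(method = method, species = species,
                 stages = colnames(x), values = vals),
            class = "ScaledMatrix")
}

#' @export
print.ScaledMatrix <- function(x, ...) {
  cat(sprintf("ScaledMatrix (%s): %d genes x %d stages [species %s]\n",
              x$method, nrow(x$values), ncol(x$values), x$species))
  invisible(x)
}
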