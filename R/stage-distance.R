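#' @name stage_distance
#' @title Cross-species stage-distance matrices
#' @description
#' The developmental-hourglass analysis compares every stage of species
#' A with every stage of species B: the two stage expression vectors u
#' and v over the shared expressed ortholog genes are reduced to a
#' scalar distance, giving a stages_A x stages_B matrix whose global
#' minimum marks the most conserved stage combination. Four metrics are
#' supported:
#' \itemize{
#'   \item euclidean: sqrt(sum((u_i - v_i)^2))
#'   \item correlation: 1 - Pearson(u, v)
#'   \item shannon: -1/2 sum(u_i log((u_i+v_i)/(2 u_i)) +
#'     v_i log((u_i+v_i)/(2 v_i))), natural log, 0 log(.) = 0 -- the
#'     Jensen-Shannon divergence for probability vectors
#'   \item std_euclidean: sqrt(sum((u_i - v_i)^2 / V_i)) where V_i is
#'     the per-gene variance over all stage values of both species
#'     (population convention); zero-variance genes are excluded with
#'     a message
#' }
NULL

dist_euclidean <- function(u, v) sqrt(sum((u - v)^2))

dist_correlation <- function(u, v) {
  assert_that(pop_sd(u) > 0 && pop_sd(v) > 0,
              "correlation distance undefined for a zero-variance vector")
  1 - stats::cor(u, v)
}

dist_shannon <- function(u, v) {
  assert_that(all(u >= 0) && all(v >= 0),
              "shannon distance requires non-negative vectors")
  m <- u + v
  xlog <- function(a, b) ifelse(a == 0, 0, a * log(b / (2 * a)))
  -0.5 * sum(xlog(u, m) + xlog(v, m))
}

dist_std_euclidean <- function(u, v, V) sqrt(sum((u - v)^2 / V))

#' Stage-by-stage distance matrix between two species
#'
#' @param sa,sb `ScaledMatrix` (or plain gene x stage matrices) for
#'   species A and B; rows are matched through `pairs`.
#' @param pairs ortholog pair table (`gene_a`, `gene_b`); only pairs
#'   with both genes present in the two matrices are used -- the shared
#'   expressed ortholog universe.
#' @param metric one of `"euclidean"`, `"correlation"`, `"shannon"`,
#'   `"std_euclidean"`.
#' @return a `DistanceMatrix`: list with `d` (stages_A x stages_B
#'   matrix), `metric`, `genes` (pair table used).
#' @export
stage_distance <- function(sa, sb, pairs,
                           metric = c("euclidean", "correlation",
                                      "shannon", "std_euclidean")) {
  metric <- match.arg(metric)
  xa <- if (inherits(sa, "ScaledMatrix")) sa$values else as.matrix(sa)
  xb <- if (inherits(sb, "ScaledMatrix")) sb$values else as.matrix(sb)
  pairs <- as.data.frame(pairs)[, c("gene_a", "gene_b")]
  pairs <- pairs[pairs$gene_a %in% rownames(xa) &
                   pairs$gene_b %in% rownames(xb), , drop = FALSE]
  assert_that(nrow(pairs) > 0, "no shared ortholog genes between the matrices")
  A <- xa[pairs$gene_a, , drop = FALSE]
  B <- xb[pairs$gene_b, , drop = FALSE]
  if (metric == "std_euclidean") {
    V <- apply(cbind(A, B), 1, pop_var)
    keep <- V > 0
    if (!all(keep)) {
      message(sum(!keep), " zero-variance gene(s) excluded from std_euclidean")
      A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
      V <- V[keep]; pairs <- pairs[keep, , drop = FALSE]
    }
  }
  d <- matrix(NA_real_, ncol(A), ncol(B),
              dimnames = list(colnames(A), colnames(B)))
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      d[i, j] <- switch(metric,
        euclidean = dist_euclidean(A[, i], B[, j]),
        correlation = dist_correlation(A[, i], B[, j]),
        shannon = dist_shannon(A[, i], B[, j]),
        std_euclidean = dist_std_euclidean(A[, i], B[, j], V))
    }
  }
  structure(list(d = d, metric = metric, genes = pairs),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, digits = 4, ...) {
  cat(sprintf("DistanceMatrix (%s), %d x %d stages, %d ortholog genes\n",
              x$metric, nrow(x$d), ncol(x$d), nrow(x$genes)))
  print(round(x$d, digits))
  invisible(x)
}

#' Per-stage and global minima of a stage-distance matrix
#'
#' For every stage of species B, the minimizing stage of species A and
#' its value; plus the global minimum pair. Ties are reported in full,
#' never broken.
#'
#' @param dm a `DistanceMatrix` (or plain matrix).
#' @param tol tolerance for tie detection.
#' @return list with `per_stage_b` (data.frame `stage_b`, `stage_a`,
#'   `value`; ties expand to multiple rows), `global` (data.frame
#'   `stage_a`, `stage_b`, `value` -- several rows when tied), and
#'   `tied` (logical: the global minimum is not unique).
#' @export
min_distance_summary <- function(dm, tol = 1e-12) {
  d <- if (inherits(dm, "DistanceMatrix")) dm$d else as.matrix(dm)
  assert_that(length(d) > 0, "empty distance matrix")
  sa <- rownames(d) %||% paste0("a", seq_len(nrow(d)))
  sb <- colnames(d) %||% paste0("b", seq_len(ncol(d)))
  per <- do.call(rbind, lapply(seq_len(ncol(d)), function(j) {
    m <- min(d[, j])
    i <- which(d[, j] <= m + tol)
    data.frame(stage_b = sb[j], stage_a = sa[i], value = d[i, j],
               stringsAsFactors = FALSE)
  }))
  gmin <- min(d)
  gw <- which(d <= gmin + tol, arr.ind = TRUE)
  global <- data.frame(stage_a = sa[gw[, 1]], stage_b = sb[gw[, 2]],
                       value = d[gw], stringsAsFactors = FALSE)
  list(per_stage_b = per, global = global, tied = nrow(global) > 1)
}
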