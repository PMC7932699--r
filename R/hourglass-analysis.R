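#' Concatenate per-gene scaled profiles of two species
#'
#' For each ortholog pair, the species-A stage profile followed by the
#' species-B stage profile as one vector of length T_A + T_B (e.g. a
#' 10-dimensional vector for 6 + 4 stages), the input to gene
#' clustering.
#'
#' @param sa,sb `ScaledMatrix` (or gene x stage matrices).
#' @param pairs pair table (`gene_a`, `gene_b`); either id may be `NA`
#'   or absent from its matrix.
#' @param missing policy for genes absent (or `NA`) in one species:
#'   `"exclude"` (default; the cross-species distance universe) or
#'   `"zero"` (zero-fill, keeping species-specific genes for the
#'   clustering view).
#' @return numeric matrix, one row per retained pair (rownames
#'   `gene_a|gene_b`), T_A + T_B columns named by stage.
#' @export
concat_vectors <- function(sa, sb, pairs, missing = c("exclude", "zero")) {
  missing <- match.arg(missing)
  xa <- if (inherits(sa, "ScaledMatrix")) sa$values else as.matrix(sa)
  xb <- if (inherits(sb, "ScaledMatrix")) sb$values else as.matrix(sb)
  pairs <- as.data.frame(pairs)[, c("gene_a", "gene_b")]
  in_a <- !is.na(pairs$gene_a) & pairs$gene_a %in% rownames(xa)
  in_b <- !is.na(pairs$gene_b) & pairs$gene_b %in% rownames(xb)
  keep <- if (missing == "exclude") in_a & in_b else in_a | in_b
  pairs <- pairs[keep, , drop = FALSE]
  in_a <- in_a[keep]; in_b <- in_b[keep]
  out <- matrix(0, nrow(pairs), ncol(xa) + ncol(xb),
                dimnames = list(paste(pairs$gene_a, pairs$gene_b, sep = "|"),
                                c(colnames(xa), colnames(xb))))
  out[in_a, seq_len(ncol(xa))] <- xa[pairs$gene_a[in_a], , drop = FALSE]
  out[in_b, ncol(xa) + seq_len(ncol(xb))] <- xb[pairs$gene_b[in_b], , drop = FALSE]
  out
}

#' Hierarchical gene clustering with a pluggable embedder
#'
#' Ward-linkage agglomerative clustering on Euclidean distances of the
#' (optionally embedded) concatenated profile vectors. The
#' dimensionality-reduction step is injected as a callable so any
#' embedding (UMAP, t-SNE, identity) can sit in front of the same
#' deterministic clustering contract.
#'
#' @param vectors numeric matrix, genes x dimensions (finite values).
#' @param k number of clusters to cut.
#' @param embedder function matrix -> matrix applied first (default
#'   identity).
#' @return integer cluster labels 1..k, named by the vector rownames.
#' @export
cluster_genes <- function(vectors, k, embedder = identity) {
  vectors <- as.matrix(vectors)
  assert_that(all(is.finite(vectors)), "vectors must be finite")
  assert_that(k >= 1 && nrow(vectors) >= k,
              "fewer vectors than requested clusters")
  emb <- embedder(vectors)
  hc <- stats::hclust(stats::dist(emb, method = "euclidean"),
                      method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' PCA of stage expression profiles across both species
#'
#' Stages of both species are the observations (rows), shared ortholog
#' genes the variables: an exact PCA via singular value decomposition
#' of the column-centered stage x gene matrix. The sign of each
#' component is fixed so its largest-magnitude gene loading is
#' positive.
#'
#' @param sa,sb `ScaledMatrix` (or gene x stage matrices).
#' @param pairs ortholog pair table.
#' @param n_pc number of components to return (default 3, capped at
#'   the matrix rank).
#' @return list with `scores` (stage x PC; rownames carry the species
#'   prefix), `loadings` (gene x PC), `explained` (variance ratios of
#'   all components, summing to 1), `center`.
#' @export
pca_stages <- function(sa, sb, pairs, n_pc = 3) {
  X <- t(concat_vectors(sa, sb, pairs, missing = "exclude"))
  assert_that(nrow(X) >= 2, "need at least two stage observations")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  ev <- sv$d^2
  explained <- ev / sum(ev)
  n_pc <- min(n_pc, sum(sv$d > max(sv$d) * 1e-12))
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  for (k in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(ncol(scores))))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(ncol(loadings))))
  list(scores = scores[, seq_len(n_pc), drop = FALSE],
       loadings = loadings[, seq_len(n_pc), drop = FALSE],
       explained = explained, center = ctr)
}

#' Count stage-associated genes
#'
#' Per gene, the stage z-score z_k = (u_k - mean(u)) / sd(u) over its
#' own stages (population sd); a gene is stage-associated at stage k
#' when its mean TPM there is at least `tpm_min` and |z_k| >=
#' `z_min`. Genes with zero profile variance are never counted.
#'
#' @param m an `ExpressionMatrix`.
#' @param tpm_min TPM floor (inclusive, default 1.0).
#' @param z_min z-score magnitude threshold (inclusive, default 1.0).
#' @return named integer vector of per-stage counts.
#' @export
stage_associated_counts <- function(m, tpm_min = 1.0, z_min = 1.0) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  assert_that(length(m$stages) >= 2, "need at least two stages")
  x <- m$mean_tpm
  mu <- rowMeans(x)
  sdv <- apply(x, 1, pop_sd)
  ok <- sdv > 0
  z <- (x - mu) / ifelse(sdv == 0, NA, sdv)
  hit <- ok & x >= tpm_min & abs(z) >= z_min
  hit[is.na(hit)] <- FALSE
  stats::setNames(colSums(hit), m$stages)
}

#' Shannon entropy of tissue expression distributions
#'
#' Per gene, the expression probability over tissues p_k =
#' TPM_k / sum_k TPM_k and its entropy H = -sum_k p_k log p_k (0 log 0
#' = 0). Low entropy marks tissue-restricted expression; the maximum,
#' log K, marks uniform expression over the K tissues.
#'
#' @param ref numeric matrix, tissue x gene TPM (>= 0).
#' @param base log base: `"natural"` (default), `"log2"`, or a number.
#' @return an `EntropyTable`: list with `p` (tissue x gene), `H`
#'   (per-gene entropy; `NA` for genes with zero total), `K`, `base`.
#' @export
tissue_entropy <- function(ref, base = "natural") {
  ref <- as.matrix(ref)
  assert_that(all(ref >= 0), "negative TPM")
  logb <- if (identical(base, "natural")) log else
    if (identical(base, "log2")) log2 else function(x) log(x, base)
  tot <- colSums(ref)
  p <- sweep(ref, 2, ifelse(tot == 0, NA, tot), "/")
  H <- apply(p, 2, function(q) {
    if (anyNA(q)) return(NA_real_)
    q <- q[q > 0]
    -sum(q * logb(q))
  })
  structure(list(p = p, H = H, K = nrow(ref), base = base),
            class = "EntropyTable")
}

#' @export
print.EntropyTable <- function(x, ...) {
  cat(sprintf("EntropyTable: %d genes over %d tissues (log base %s); %d undefined\n",
              length(x$H), x$K, as.character(x$base), sum(is.na(x$H))))
  invisible(x)
}

#' Count tissue-associated genes per stage
#'
#' Per stage, the number of genes whose mean TPM there reaches
#' `tpm_min` and whose tissue entropy satisfies the threshold in the
#' configured direction (default: H >= `h_thr`, inclusive).
#'
#' @param m an `ExpressionMatrix` (the focal tissue's time course).
#' @param e an [tissue_entropy()] table; genes are matched by name.
#' @param tpm_min TPM floor (inclusive).
#' @param h_thr entropy threshold (default 0.65).
#' @param direction `">="` (default) or `"<="`.
#' @return named integer vector of per-stage counts; genes with
#'   undefined entropy are never counted.
#' @export
tissue_associated_counts <- function(m, e, tpm_min = 1.0, h_thr = 0.65,
                                     direction = c(">=", "<=")) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(e, "EntropyTable"))
  direction <- match.arg(direction)
  H <- e$H[m$genes]
  pass_h <- !is.na(H) & if (direction == ">=") H >= h_thr else H <= h_thr
  hit <- (m$mean_tpm >= tpm_min) & pass_h
  stats::setNames(colSums(hit), m$stages)
}
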