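#' Detect heterochronically regulated ortholog pairs
#'
#' For each ortholog pair, computes the Pearson correlation coefficient
#' (PCC) between a gene's mean TPM profile and the integer stage rank
#' (1..T) separately in each species, and reports pairs whose expression
#' rises over development in one species while falling in the other.
#'
#' @param ma,mb `ExpressionMatrix` for species A and B.
#' @param pairs data.frame with columns `gene_a`, `gene_b` (an
#'   [assign_orthologs()] pair table works directly).
#' @param thr PCC magnitude threshold (default 0.5): a pair is reported
#'   when PCC_A > `thr` and PCC_B < -`thr` (direction `"up_a_down_b"`),
#'   and, if `both_directions`, also the mirrored case
#'   (`"down_a_up_b"`).
#' @param both_directions report both temporal directions (default TRUE).
#' @param use_tpm compute PCC on mean TPM (default, matching the stage
#'   association convention) rather than Max-1 scaled values.
#' @return data.frame with `gene_a`, `gene_b`, `pcc_a`, `pcc_b`,
#'   `direction`. Pairs with a zero-variance profile in either species
#'   have undefined PCC and are skipped (collected in the
#'   `"skipped"` attribute).
#' @export
detect_heterochronic <- function(ma, mb, pairs, thr = 0.5,
                                 both_directions = TRUE, use_tpm = TRUE) {
  stopifnot(inherits(ma, "ExpressionMatrix"), inherits(mb, "ExpressionMatrix"))
  assert_that(length(ma$stages) >= 3 && length(mb$stages) >= 3,
              "need at least 3 stages per species for stage correlation")
  pairs <- as.data.frame(pairs)[, c("gene_a", "gene_b")]
  pairs <- pairs[pairs$gene_a %in% ma$genes & pairs$gene_b %in% mb$genes, ]
  xa <- if (use_tpm) ma$mean_tpm else scale_expression(ma, "max1")$values
  xb <- if (use_tpm) mb$mean_tpm else scale_expression(mb, "max1")$values
  ra <- seq_along(ma$stages); rb <- seq_along(mb$stages)
  pcc_row <- function(v, r) {
    if (pop_sd(v) == 0) return(NA_real_)
    stats::cor(v, r)
  }
  pcc_a <- apply(xa[pairs$gene_a, , drop = FALSE], 1, pcc_row, r = ra)
  pcc_b <- apply(xb[pairs$gene_b, , drop = FALSE], 1, pcc_row, r = rb)
  ok <- !is.na(pcc_a) & !is.na(pcc_b)
  skipped <- pairs[!ok, , drop = FALSE]
  res <- data.frame(pairs[ok, , drop = FALSE],
                    pcc_a = pcc_a[ok], pcc_b = pcc_b[ok],
                    row.names = NULL)
  up_a <- res$pcc_a > thr & res$pcc_b < -thr
  down_a <- res$pcc_a < -thr & res$pcc_b > thr
  res$direction <- ifelse(up_a, "up_a_down_b",
                          ifelse(down_a, "down_a_up_b", NA))
  keep <- if (both_directions) up_a | down_a else up_a
  out <- res[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# interspecific per-gene profile distance; if stage counts differ the
# longer profile is linearly interpolated onto the shorter one's
# normalized rank grid (a diagnostic alignment, not a biological staging)
gene_profile_distance <- function(va, vb) {
  ta <- length(va); tb <- length(vb)
  if (ta == tb) return(sqrt(sum((va - vb)^2)))
  if (ta > tb) {
    va <- stats::approx(seq(0, 1, length.out = ta), va,
                        xout = seq(0, 1, length.out = tb))$y
  } else {
    vb <- stats::approx(seq(0, 1, length.out = tb), vb,
                        xout = seq(0, 1, length.out = ta))$y
  }
  sqrt(sum((va - vb)^2))
}

#' Scaling-sensitivity ratio: heterochronic vs housekeeping distance
#'
#' A diagnostic of how sensitive a scaling method is to differential
#' regulation relative to housekeeping noise: the ratio of the mean
#' interspecific Euclidean profile distance over a set of heterochronic
#' genes to that over a set of housekeeping genes, computed after
#' applying the given scaling per species. Larger values mean the
#' scaling amplifies true cross-species regulatory differences relative
#' to the incidental variation of constitutively expressed genes.
#'
#' @param ma,mb `ExpressionMatrix` for the two species.
#' @param pairs ortholog pair table (`gene_a`, `gene_b`).
#' @param housekeeping,heterochronic non-empty vectors of `gene_a` ids
#'   selecting the two pair subsets.
#' @param method scaling method passed to [scale_expression()].
#' @return the ratio (heterochronic mean distance / housekeeping mean
#'   distance). Errors if the housekeeping mean distance is zero.
#' @export
sensitivity_ratio <- function(ma, mb, pairs,
                              housekeeping, heterochronic,
                              method = c("max1", "zscore", "unitvec", "log10")) {
  method <- match.arg(method)
  assert_that(length(housekeeping) > 0 && length(heterochronic) > 0,
              "both gene sets must be non-empty")
  pairs <- as.data.frame(pairs)[, c("gene_a", "gene_b")]
  sa <- scale_expression(ma, method)$values
  sb <- scale_expression(mb, method)$values
  mean_dist <- function(set) {
    sub <- pairs[pairs$gene_a %in% set, , drop = FALSE]
    assert_that(nrow(sub) > 0, "gene set has no ortholog pair in `pairs`")
    d <- mapply(function(a, b) gene_profile_distance(sa[a, ], sb[b, ]),
                sub$gene_a, sub$gene_b)
    mean(d)
  }
  num <- mean_dist(heterochronic)
  if (num == 0) return(0)  # no heterochronic divergence: ratio 0 by definition
  den <- mean_dist(housekeeping)
  assert_that(den > 0, "housekeeping interspecific distance is zero; ratio undefined")
  num / den
}
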