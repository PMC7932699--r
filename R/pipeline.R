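#' Pipeline configuration
#'
#' Collects every threshold the two workflows use, with the package
#' defaults: TPM floor 1.0, heterochrony |PCC| 0.5, stage z-score 1.0,
#' tissue entropy 0.65, conservation score 40, reciprocal bin overlap
#' fraction 0.4, motif score fraction 0.75, differential alpha 0.05,
#' FRiP QC 0.2. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    species_a = "species_a", species_b = "species_b",
    scaling = "max1",
    metrics = c("euclidean", "correlation", "shannon", "std_euclidean"),
    tpm_min = 1.0, pcc_thr = 0.5, z_min = 1.0, h_thr = 0.65,
    entropy_direction = ">=",
    score_min = 40, min_frac = 0.4, frac_motif = 0.75,
    alpha = 0.05, frip_qc_min = 0.2,
    log_base = "natural", sd_type = "population",
    evalue_max = 1e-30,
    seed = 1L,
    n_clusters = 7L,
    sim_expression = list(), sim_peaks = list(),
    out_dir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  assert_that(length(unknown) == 0,
              paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  with(cfg, {
    assert_that(tpm_min >= 0 && pcc_thr >= 0 && pcc_thr <= 1 && z_min >= 0,
                "threshold out of range")
    assert_that(min_frac > 0 && min_frac <= 1 &&
                  frac_motif > 0 && frac_motif <= 1 &&
                  alpha > 0 && alpha < 1 &&
                  frip_qc_min >= 0 && frip_qc_min <= 1,
                "threshold out of range")
    assert_that(scaling %in% c("max1", "zscore", "unitvec", "log10"),
                "unknown scaling method")
  })
  structure(cfg, class = "PipelineConfig")
}

config_hash <- function(cfg) {
  semantic <- cfg[setdiff(names(cfg), "out_dir")]
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(semantic), f)
  unname(tools::md5sum(f))
}

#' Run a full synthetic-data workflow
#'
#' Chains the package's modules into the two standard workflows on
#' simulated inputs: `"transcriptome"` (orthology assignment ->
#' expression filter and scaling -> stage-distance matrices, PCA, gene
#' clustering, heterochrony list, stage-associated counts) and `"ocr"`
#' (peak binning -> FRiP QC -> one-hot distances, conservation
#' fractions, differential bins, tissue-specific peaks). Deterministic
#' given the config (which carries the seed); if `cfg$out_dir` is set,
#' every result table is written there as TSV, tagged with the config
#' hash, together with a plain-text log of the thresholds used.
#'
#' @param cfg a [pipeline_config()].
#' @param workflow `"transcriptome"` or `"ocr"`.
#' @return a result bundle (named list, including `config_hash` and
#'   `log`, a character vector of log lines).
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         workflow = c("transcriptome", "ocr")) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  workflow <- match.arg(workflow)
  hash <- config_hash(cfg)
  log <- c(sprintf("workflow=%s config_hash=%s seed=%d", workflow, hash, cfg$seed),
           sprintf("thresholds: tpm_min=%g pcc_thr=%g z_min=%g h_thr=%g score_min=%g min_frac=%g frac_motif=%g alpha=%g frip_qc_min=%g",
                   cfg$tpm_min, cfg$pcc_thr, cfg$z_min, cfg$h_thr, cfg$score_min,
                   cfg$min_frac, cfg$frac_motif, cfg$alpha, cfg$frip_qc_min))
  res <- if (workflow == "transcriptome") {
    sim <- simulate_expression(do.call(expression_sim_config,
                                       c(cfg$sim_expression, list(seed = cfg$seed))))
    expr_a <- filter_expressed(sim$a, cfg$tpm_min)
    expr_b <- filter_expressed(sim$b, cfg$tpm_min)
    pairs <- sim$truth$ortholog_truth
    pairs <- pairs[pairs$gene_a %in% expr_a & pairs$gene_b %in% expr_b, ]
    sa <- scale_expression(subset_genes(sim$a, expr_a), cfg$scaling)
    sb <- scale_expression(subset_genes(sim$b, expr_b), cfg$scaling)
    dists <- lapply(stats::setNames(cfg$metrics, cfg$metrics), function(m)
      stage_distance(sa, sb, pairs, m))
    pca <- pca_stages(sa, sb, pairs)
    vecs <- concat_vectors(sa, sb, sim$truth$classes[, c("gene_a", "gene_b")],
                           missing = "zero")
    clusters <- cluster_genes(vecs, k = cfg$n_clusters)
    het <- detect_heterochronic(sim$a, sim$b, pairs, thr = cfg$pcc_thr)
    counts_a <- stage_associated_counts(sim$a, cfg$tpm_min, cfg$z_min)
    counts_b <- stage_associated_counts(sim$b, cfg$tpm_min, cfg$z_min)
    log <- c(log, sprintf("expressed genes: A=%d B=%d ortholog pairs=%d",
                          length(expr_a), length(expr_b), nrow(pairs)),
             sprintf("heterochronic pairs: %d", nrow(het)))
    list(sim = sim, pairs = pairs, scaled_a = sa, scaled_b = sb,
         distances = dists, pca = pca, clusters = clusters,
         heterochronic = het,
         stage_counts = list(a = counts_a, b = counts_b))
  } else {
    genome <- data.frame(chrom = c("chr1", "chr2"), size = c(2e6L, 2e6L))
    sim <- do.call(simulate_peak_data,
                   c(list(genome = genome, seed = cfg$seed), cfg$sim_peaks))
    g500 <- bin_grid(genome, 500)
    g100 <- bin_grid(genome, 100)
    binned500 <- lapply(sim$peaks, assign_to_bins, g = g500,
                        min_frac = cfg$min_frac)
    binned100 <- lapply(sim$peaks, assign_to_bins, g = g100,
                        min_frac = cfg$min_frac)
    stages <- names(sim$peaks)
    frips <- lapply(stages, function(s)
      frip(sim$reads[[s]], sim$peaks[[s]], qc_min = cfg$frip_qc_min))
    names(frips) <- stages
    dmat <- matrix(0, length(stages), length(stages),
                   dimnames = list(stages, stages))
    uni <- bin_universe(binned500)
    for (i in seq_along(stages)) for (j in seq_along(stages))
      dmat[i, j] <- onehot_distance(binned500[[i]], binned500[[j]], uni)
    consv <- vapply(stages, function(s)
      conserved_fraction(binned100[[s]], sim$hits[[s]], cfg$score_min)$fraction,
      numeric(1))
    log <- c(log, sprintf("FRiP: %s", paste(sprintf("%s=%.3f", stages,
             vapply(frips, `[[`, 0, "score")), collapse = " ")),
             sprintf("conserved fraction: %s", paste(sprintf("%s=%.3f", stages,
             consv), collapse = " ")))
    list(sim = sim, binned500 = binned500, binned100 = binned100,
         frip = frips, onehot_distances = dmat, conserved = consv)
  }
  res$config_hash <- hash
  res$log <- log
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(log, file.path(cfg$out_dir, "run.log"))
    if (workflow == "transcriptome") {
      for (m in names(res$distances))
        write_matrix_tsv(res$distances[[m]]$d,
                         file.path(cfg$out_dir, paste0("distance_", m, ".tsv")),
                         tag = paste("metric", m, "config", hash))
      write_matrix_tsv(res$pca$scores, file.path(cfg$out_dir, "pca_scores.tsv"),
                       tag = paste("config", hash))
      utils::write.table(res$heterochronic,
                         file.path(cfg$out_dir, "heterochronic_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      write_matrix_tsv(res$onehot_distances,
                       file.path(cfg$out_dir, "onehot_distances.tsv"),
                       tag = paste("config", hash))
      utils::write.table(
        data.frame(stage = names(res$conserved), fraction = res$conserved),
        file.path(cfg$out_dir, "conserved_fraction.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  res
}
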