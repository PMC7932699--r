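uniform_counts <- function(n) {
  setNames(rep(n, 7), c("housekeeping", "conserved_early", "conserved_late",
                        "heterochronic1", "heterochronic2",
                        "species_specific_a", "species_specific_b"))
}

test_that("noise-free housekeeping genes are exactly flat at their base level", {
  cfg <- expression_sim_config(
    n_genes_per_class = c(housekeeping = 1, conserved_early = 0,
                          conserved_late = 0, heterochronic1 = 0,
                          heterochronic2 = 0, species_specific_a = 0,
                          species_specific_b = 0),
    noise_cv = 0, base_tpm_range = c(10, 10), hourglass_strength = 0, seed = 1)
  sim <- simulate_expression(cfg)
  expect_true(all(sim$a$replicate_tpm == 10))
  expect_true(all(sim$b$replicate_tpm == 10))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- expression_sim_config(n_genes_per_class = uniform_counts(10), seed = 1)
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_identical(simulate_hit_tables(30, seed = 5),
                   simulate_hit_tables(30, seed = 5))
  g <- small_genome()
  expect_identical(simulate_peak_data(g, n_peaks_per_stage = 40, seed = 9),
                   simulate_peak_data(g, n_peaks_per_stage = 40, seed = 9))
})

test_that("class proportions in the truth labels match the request exactly", {
  counts <- c(housekeeping = 12, conserved_early = 5, conserved_late = 7,
              heterochronic1 = 3, heterochronic2 = 4,
              species_specific_a = 2, species_specific_b = 6)
  sim <- simulate_expression(expression_sim_config(n_genes_per_class = counts,
                                                   seed = 2))
  got <- table(sim$truth$classes$class)
  expect_equal(as.vector(got[names(counts)]), unname(counts))
  expect_false(anyDuplicated(sim$truth$classes$gene_a) > 0)
})

test_that("heterochronic2 genes rise with stage rank in B and fall in A", {
  counts <- uniform_counts(0); counts["heterochronic2"] <- 50
  counts["housekeeping"] <- 5
  sim <- simulate_expression(expression_sim_config(
    n_genes_per_class = counts, noise_cv = 0.05, hourglass_strength = 0,
    seed = 3))
  h2a <- sim$truth$classes$gene_a[sim$truth$classes$class == "heterochronic2"]
  h2b <- sim$truth$classes$gene_b[sim$truth$classes$class == "heterochronic2"]
  pcc_a <- apply(sim$a$mean_tpm[h2a, ], 1,
                 function(v) cor(v, seq_along(sim$a$stages)))
  pcc_b <- apply(sim$b$mean_tpm[h2b, ], 1,
                 function(v) cor(v, seq_along(sim$b$stages)))
  expect_true(all(pcc_b > 0.5))
  expect_true(all(pcc_a < -0.5))
})

test_that("species-specific genes stay below 1 TPM in the other species", {
  sim <- simulate_expression(expression_sim_config(
    n_genes_per_class = uniform_counts(20), noise_cv = 0, seed = 4))
  cls <- sim$truth$classes
  ssa_b <- cls$gene_b[cls$class == "species_specific_a"]
  ssb_a <- cls$gene_a[cls$class == "species_specific_b"]
  expect_true(all(apply(sim$b$mean_tpm[ssa_b, ], 1, max) < 1))
  expect_true(all(apply(sim$a$mean_tpm[ssb_a, ], 1, max) < 1))
  # and expressed in their own species
  ssa_a <- cls$gene_a[cls$class == "species_specific_a"]
  expect_true(all(apply(sim$a$mean_tpm[ssa_a, ], 1, max) >= 1))
})

test_that("replicate noise has the configured coefficient of variation", {
  sim <- simulate_expression(expression_sim_config(
    n_genes_per_class = uniform_counts(60), n_replicates = 30,
    noise_cv = 0.2, hourglass_strength = 0, seed = 5))
  # pool replicate CVs over genes x stages of species A
  cvs <- apply(sim$a$replicate_tpm, c(1, 2),
               function(v) sd(v) / mean(v))
  expect_equal(mean(cvs), 0.2, tolerance = 0.02)
})

test_that("hit tables plant recoverable orthologs and lineage-specific genes", {
  ht <- simulate_hit_tables(100, paralog_rate = 0, dropout_rate = 0,
                            lineage_specific_frac = 0.2, seed = 6)
  # noise-free: every A gene's cross-species best hit is its true proxy
  b <- cross_species_best_hit(ht$a_hits, exclude = "elephantfish")
  ts <- ht$truth$true_subject
  key <- paste(ts$gene_a, ts$species)
  want <- setNames(ts$subject_id, key)
  expect_true(all(b$subject_id == want[paste(b$query_id, b$subject_species)]))
  # lineage-specific genes hit only the fallback lineage
  ls <- ht$truth$lineage_specific
  expect_equal(length(ls), 20)
  ls_rows <- ht$a_hits[ht$a_hits$query_id %in% ls, ]
  expect_true(all(ls_rows$subject_species == "elephantfish"))
})

test_that("paralog recovery equals a brute-force enumeration of the tables", {
  ht <- simulate_hit_tables(200, paralog_rate = 0.05, dropout_rate = 0, seed = 7)
  om <- assign_orthologs(ht$a_hits, ht$b_hits, fallback_species = "elephantfish")
  rec <- evaluate_accuracy(om, ht$truth$ortholog_truth)
  # oracle: exhaustive per-query scans of both tables under the tie rules
  a_best <- oracle_best_hits(ht$a_hits[ht$a_hits$subject_species !=
                                         "elephantfish", ])
  n_ok <- 0
  for (i in seq_len(nrow(ht$truth$ortholog_truth))) {
    ga <- ht$truth$ortholog_truth$gene_a[i]
    gb <- ht$truth$ortholog_truth$gene_b[i]
    ab <- a_best[a_best$query_id == ga, ]
    if (nrow(ab) == 0) next
    bh <- oracle_best_hits(ht$b_hits[ht$b_hits$query_id == gb &
                                       ht$b_hits$subject_species ==
                                       ab$subject_species, ])
    if (!is.null(bh) && nrow(bh) == 1 && bh$subject_id == ab$subject_id)
      n_ok <- n_ok + 1
  }
  expect_equal(rec, n_ok / nrow(ht$truth$ortholog_truth))
})

test_that("peak simulator honors its planted structure", {
  g <- small_genome()
  # conserved_fraction = 0: no hit reaches the conservation score
  ps0 <- simulate_peak_data(g, n_peaks_per_stage = 50,
                            conserved_fraction = 0, seed = 8)
  expect_true(all(vapply(ps0$hits, function(h)
    nrow(h) == 0 || max(h$score) < 40, logical(1))))
  # shared_fraction = 1: identical peak sets, one-hot distance 0
  ps1 <- simulate_peak_data(g, n_peaks_per_stage = 50,
                            shared_fraction = 1, seed = 9)
  expect_identical(ps1$peaks[[1]], ps1$peaks[[2]])
  g500 <- bin_grid(g, 500)
  expect_equal(onehot_distance(assign_to_bins(ps1$peaks[[1]], g500),
                               assign_to_bins(ps1$peaks[[3]], g500)), 0)
  # geometry: peaks within bounds, positive length, recorded summits
  p <- ps1$peaks[[1]]
  expect_true(all(p$end > p$start & p$start >= 0))
  expect_true(all(p$summit >= 0 & p$summit < p$end - p$start))
  expect_error(simulate_peak_data(g[0, ], n_peaks_per_stage = 5), "empty")
  expect_error(simulate_peak_data(g, n_peaks_per_stage = 5, peak_width = 0),
               "length")
})

test_that("planted conserved fraction is recovered within one bin quantum", {
  g <- small_genome()
  ps <- simulate_peak_data(g, n_peaks_per_stage = 200,
                           conserved_fraction = 0.4, seed = 10)
  g100 <- bin_grid(g, 100)
  for (s in names(ps$peaks)) {
    bp <- assign_to_bins(ps$peaks[[s]], g100)
    cf <- conserved_fraction(bp, ps$hits[[s]], score_min = 40)
    expect_equal(cf$fraction, 0.4, tolerance = 1 / nrow(bp$bins) + 1e-9)
    # and equals direct interval arithmetic on the planted truth
    expect_equal(cf$fraction,
                 length(ps$truth$conserved_bins[[s]]) / nrow(bp$bins))
  }
})

test_that("toy fixture obeys its qualitative contract", {
  toy <- toy_two_gene_example()
  expect_equal(dim(toy$a$mean_tpm), c(2, 3))
  expect_equal(dim(toy$b$mean_tpm), c(2, 3))
  for (m in list(toy$a, toy$b)) {
    g1 <- m$mean_tpm["gene1", ]
    expect_lte(max(g1) / min(g1), 1.5)
  }
  # t2 is the most similar time point under Max-1 scaling
  sa <- scale_expression(toy$a, "max1")
  sb <- scale_expression(toy$b, "max1")
  d <- diag(stage_distance(sa, sb, toy$pairs, "euclidean")$d)
  expect_equal(which.min(d), 2L, ignore_attr = TRUE)
})
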