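#' Configuration for the two-species expression simulator
#'
#' The defaults mirror the study design the package targets: a shark-like
#' species A with six ordered fin-bud stages (st27..st32) and a mouse-like
#' species B with four limb-bud stages (E9.5..E12.5), three biological
#' replicates per stage.
#'
#' @param n_genes_per_class named or unnamed counts per planted gene
#'   class, in the order `housekeeping`, `conserved_early`,
#'   `conserved_late`, `heterochronic1`, `heterochronic2`,
#'   `species_specific_a`, `species_specific_b`; a single number is
#'   recycled over the seven classes. The default (600/250/250/150/150/
#'   300/300, 2000 genes) mirrors a realistic composition: stable
#'   housekeeping expression dominates, conserved dynamic genes are
#'   common, heterochronically shifted genes are a small minority, and
#'   a substantial fraction of each species' genes has no counterpart
#'   dynamics in the other.
#' @param stages_a,stages_b ordered, duplicate-free stage labels.
#' @param n_replicates biological replicates per stage (default 3).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal replicate noise (default 0.1; 0 = noise-free).
#' @param base_tpm_range positive interval the per-gene base expression
#'   level is drawn from (log-uniform), default 5..500 TPM.
#' @param hourglass_strength fraction of conserved-class genes
#'   (conserved_early + conserved_late) whose expression peak is forced
#'   to the designated mid stage in both species, planting a mid-stage
#'   conservation signal (default 0.5).
#' @param conserved_stage_pair integer indices (stage of A, stage of B)
#'   of the planted most-conserved stage pair; default mid stages
#'   (3rd of 6, 2nd of 4 -- the E10.5 analogue).
#' @param seed integer seed; every run with the same config is
#'   bit-identical.
#' @return a validated `ExpressionSimConfig` list.
#' @export
expression_sim_config <- function(n_genes_per_class = c(housekeeping = 600,
                                      conserved_early = 250,
                                      conserved_late = 250,
                                      heterochronic1 = 150,
                                      heterochronic2 = 150,
                                      species_specific_a = 300,
                                      species_specific_b = 300),
                                  stages_a = paste0("st", 27:32),
                                  stages_b = paste0("E", c("9.5", "10.5", "11.5", "12.5")),
                                  n_replicates = 3,
                                  noise_cv = 0.1,
                                  base_tpm_range = c(5, 500),
                                  hourglass_strength = 0.5,
                                  conserved_stage_pair = NULL,
                                  seed = 1L) {
  classes <- c("housekeeping", "conserved_early", "conserved_late",
               "heterochronic1", "heterochronic2",
               "species_specific_a", "species_specific_b")
  if (length(n_genes_per_class) == 1) {
    n_genes_per_class <- stats::setNames(rep(n_genes_per_class, 7), classes)
  }
  assert_that(all(classes %in% names(n_genes_per_class)) ||
                length(n_genes_per_class) == 7,
              "n_genes_per_class must cover the seven gene classes")
  if (is.null(names(n_genes_per_class))) names(n_genes_per_class) <- classes
  n_genes_per_class <- n_genes_per_class[classes]
  assert_that(all(n_genes_per_class >= 0), "class counts must be >= 0")
  assert_that(length(stages_a) > 0 && length(stages_b) > 0,
              "stage lists must be non-empty")
  assert_that(!anyDuplicated(stages_a) && !anyDuplicated(stages_b),
              "stage lists must be duplicate-free")
  assert_that(noise_cv >= 0, "noise_cv must be >= 0")
  assert_that(n_replicates >= 1, "need at least one replicate")
  assert_that(length(base_tpm_range) == 2 && all(base_tpm_range > 0) &&
                base_tpm_range[1] <= base_tpm_range[2],
              "base_tpm_range must be a positive interval")
  assert_that(hourglass_strength >= 0 && hourglass_strength <= 1,
              "hourglass_strength must be in [0,1]")
  conserved_stage_pair <- conserved_stage_pair %||%
    c(ceiling(length(stages_a) / 2), ceiling(length(stages_b) / 2))
  assert_that(conserved_stage_pair[1] >= 1 &&
                conserved_stage_pair[1] <= length(stages_a) &&
                conserved_stage_pair[2] >= 1 &&
                conserved_stage_pair[2] <= length(stages_b),
              "conserved_stage_pair out of stage range")
  structure(list(n_genes_per_class = n_genes_per_class,
                 stages_a = stages_a, stages_b = stages_b,
                 n_replicates = n_replicates, noise_cv = noise_cv,
                 base_tpm_range = base_tpm_range,
                 hourglass_strength = hourglass_strength,
                 conserved_stage_pair = conserved_stage_pair,
                 seed = as.integer(seed)),
            class = "ExpressionSimConfig")
}

# class mean profiles over T stages, on a [low, 1] relative scale
# (multiplied by the per-gene base TPM afterwards)
ramp_up <- function(T, low = 0.2) seq(low, 1, length.out = T)
ramp_down <- function(T, low = 0.2) seq(1, low, length.out = T)

#' Simulate a paired two-species developmental expression data set
#'
#' Generates replicate TPM matrices for two species over their own stage
#' series, with seven planted gene classes and a planted mid-stage
#' conservation signal, plus the truth labels needed to score every
#' downstream analysis.
#'
#' Class profiles (per-gene base level b drawn log-uniformly from
#' `base_tpm_range`):
#' \itemize{
#'   \item housekeeping: flat at b in both species.
#'   \item conserved_early: falling ramp (b -> 0.2 b) in both species.
#'   \item conserved_late: rising ramp (0.2 b -> b) in both species.
#'   \item heterochronic1: rising in A, falling in B.
#'   \item heterochronic2: falling in A, rising in B.
#'   \item species_specific_a / _b: flat at b in the own species, flat
#'     below 1 TPM (0.01..0.3) in the other.
#' }
#' A fraction `hourglass_strength` of the conserved_early/late genes
#' instead follows a smooth Gaussian of normalized stage rank peaking at
#' the designated conserved stage of each species: both species share
#' the shape but sample it on different stage grids, so the designated
#' stage pair is the unique combination where both sit at the peak.
#' Housekeeping genes are flat in expectation plus a smooth
#' species-shared drift of amplitude ~2 x `noise_cv` (exactly flat when
#' noise-free). Replicate values are mean x multiplicative log-normal
#' noise with the stated CV.
#'
#' @param cfg an [expression_sim_config()].
#' @return list with `a`, `b` (`ExpressionMatrix`) and `truth`
#'   (`TruthLabels`: `classes` data.frame with `gene_a`, `gene_b`,
#'   `class`; `ortholog_truth` pair table excluding species-specific
#'   classes; `planted_conserved_stage_pair` of stage labels;
#'   `hourglass_genes` the bumped gene_a ids).
#' @export
simulate_expression <- function(cfg = expression_sim_config()) {
  stopifnot(inherits(cfg, "ExpressionSimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_genes_per_class
  Ta <- length(cfg$stages_a); Tb <- length(cfg$stages_b)
  mid_a <- cfg$conserved_stage_pair[1]; mid_b <- cfg$conserved_stage_pair[2]
  classes <- rep(names(n), n)
  n_tot <- length(classes)
  assert_that(n_tot > 0, "no genes requested")
  idx_in_class <- unlist(lapply(n, seq_len), use.names = FALSE)
  gene_a <- sprintf("A_%s_%03d", classes, idx_in_class)
  gene_b <- sprintf("B_%s_%03d", classes, idx_in_class)
  base <- runif_log(n_tot, cfg$base_tpm_range[1], cfg$base_tpm_range[2])

  mu_a <- matrix(0, n_tot, Ta); mu_b <- matrix(0, n_tot, Tb)
  low_other <- stats::runif(n_tot, 0.01, 0.3)  # other-species level of specifics
  # which conserved-class genes carry the planted mid-stage peak
  is_cons <- classes %in% c("conserved_early", "conserved_late")
  bumped <- is_cons & stats::runif(n_tot) < cfg$hourglass_strength
  # Mid-peaked genes follow a smooth Gaussian of normalized stage rank
  # centered on the planted stage of each species. Both species share
  # the profile shape, so the planted pair agrees (both at the peak),
  # while the two species' different stage spacings put every other
  # near-diagonal pairing at different heights on the curve. The signal
  # sits in the class-mean structure (low-rank), so it survives
  # truncation to the top principal components; small independent
  # jitter keeps profiles generic.
  bump_profile <- function(T, mid, width = 0.25) {
    r <- (seq_len(T) - 1) / (T - 1)
    prof <- 0.2 + 0.8 * exp(-(r - r[mid])^2 / (2 * width^2)) +
      stats::runif(T, -0.03, 0.03)
    prof
  }
  # Housekeeping genes: flat in expectation, plus a small stage drift of
  # the same order as the replicate noise (amplitude ~ 2*noise_cv),
  # smooth in normalized stage rank and conserved in shape between the
  # species -- constitutive genes in real time courses are stable but
  # not frozen, and their residual dynamics are shared across taxa.
  # Exactly flat when noise_cv = 0.
  hk_wobble <- function(T, c1, c2) {
    r <- (seq_len(T) - 1) / (T - 1)
    1 + 2 * cfg$noise_cv * (c1 * (r - 0.5) + c2 * (r^2 - 1 / 3))
  }
  for (i in seq_len(n_tot)) {
    c1 <- stats::runif(1, -1, 1); c2 <- stats::runif(1, -1, 1)
    pa <- switch(classes[i],
      housekeeping = hk_wobble(Ta, c1, c2),
      conserved_early = ramp_down(Ta),
      conserved_late = ramp_up(Ta),
      heterochronic1 = ramp_up(Ta),
      heterochronic2 = ramp_down(Ta),
      species_specific_a = rep(1, Ta),
      species_specific_b = rep(low_other[i] / base[i], Ta))
    pb <- switch(classes[i],
      housekeeping = hk_wobble(Tb, c1, c2),
      conserved_early = ramp_down(Tb),
      conserved_late = ramp_up(Tb),
      heterochronic1 = ramp_down(Tb),
      heterochronic2 = ramp_up(Tb),
      species_specific_a = rep(low_other[i] / base[i], Tb),
      species_specific_b = rep(1, Tb))
    if (bumped[i]) {
      pa <- bump_profile(Ta, mid_a)
      pb <- bump_profile(Tb, mid_b)
    }
    mu_a[i, ] <- base[i] * pa
    mu_b[i, ] <- base[i] * pb
  }

  make_reps <- function(mu, genes, stages) {
    arr <- array(0, dim = c(nrow(mu), ncol(mu), cfg$n_replicates))
    for (r in seq_len(cfg$n_replicates)) {
      arr[, , r] <- mu * matrix(rlnorm_cv(length(mu), cfg$noise_cv),
                                nrow(mu), ncol(mu))
    }
    expression_matrix(arr, species = NA, genes = genes, stages = stages)
  }
  ma <- make_reps(mu_a, gene_a, cfg$stages_a); ma$species <- "species_a"
  mb <- make_reps(mu_b, gene_b, cfg$stages_b); mb$species <- "species_b"

  cls <- data.frame(gene_a = gene_a, gene_b = gene_b, class = classes,
                    stringsAsFactors = FALSE)
  orth <- !(classes %in% c("species_specific_a", "species_specific_b"))
  truth <- structure(list(
    classes = cls,
    ortholog_truth = cls[orth, c("gene_a", "gene_b")],
    planted_conserved_stage_pair = c(cfg$stages_a[mid_a], cfg$stages_b[mid_b]),
    hourglass_genes = gene_a[bumped],
    conserved_bins = NULL), class = "TruthLabels")
  list(a = ma, b = mb, truth = truth)
}

#' Two-gene, three-timepoint toy fixture for scaling comparisons
#'
#' A minimal paired data set for developing intuition about the scaling
#' methods: gene 1 is constitutively active (fluctuations within a
#' max/min ratio of 1.5 in each species, with a severalfold absolute
#' level offset between the species, as real housekeeping genes show
#' across distant taxa) and gene 2 is differentially regulated --
#' expressed at t2 in both species, and additionally at t1 in species A
#' / t3 in species B. t2 is therefore the planted most-similar time
#' point under every scaling, and the Max-1 method separates the two
#' gene classes most sharply (see [sensitivity_ratio()]).
#'
#' @return list with `a`, `b` (single-replicate `ExpressionMatrix`
#'   objects, genes `gene1`/`gene2`, stages `t1`,`t2`,`t3`) and `pairs`
#'   (the ortholog pair table).
#' @export
toy_two_gene_example <- function() {
  stages <- c("t1", "t2", "t3")
  a <- rbind(gene1 = c(96, 142, 96),
             gene2 = c(49, 48, 0.8))
  b <- rbind(gene1 = c(297, 304.5, 442.5),
             gene2 = c(0.8, 48, 49))
  to_em <- function(m, sp) {
    arr <- array(m, dim = c(2, 3, 1))
    expression_matrix(arr, species = sp, genes = rownames(m), stages = stages)
  }
  list(a = to_em(a, "species_1"), b = to_em(b, "species_2"),
       pairs = data.frame(gene_a = c("gene1", "gene2"),
                          gene_b = c("gene1", "gene2"),
                          stringsAsFactors = FALSE))
}
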