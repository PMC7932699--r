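#' Simulate multi-species homology hit tables with known ortholog truth
#'
#' Generates BLAST-tabular-like hit tables for two focal species (A, a
#' shark analogue; B, a mouse analogue) against a panel of bridge
#' species plus a fallback lineage, with planted true orthologs,
#' controllable paralog confusion and per-species dropout, and a
#' fraction of species-A genes restricted to the fallback lineage.
#'
#' Score model: for each (query, panel species) the true subject's
#' bitscore is drawn N(mu_q, sigma) and its paralog's N(mu_q - delta,
#' sigma); with probability `paralog_rate` the two are swapped if needed
#' so the paralog outscores the true hit (and with the complementary
#' probability the true hit is guaranteed on top), giving exact control
#' of the confusion probability. The direct A-B comparison uses
#' `paralog_rate_direct` (default twice the panel rate): a direct
#' comparison of two distantly related species is noisier than one
#' routed through slowly evolving bridge lineages, which is the premise
#' of the cross-species best-hit algorithm.
#'
#' @param n_orthologs number of true ortholog pairs.
#' @param panel_species bridge species ids (non-empty; excludes the two
#'   focal species and the fallback).
#' @param fallback_species fallback lineage id.
#' @param paralog_rate probability, per query x panel species, that a
#'   paralog outscores the true subject.
#' @param dropout_rate probability that a query has no hits at all
#'   against a given panel species.
#' @param lineage_specific_frac fraction (of `n_orthologs`) of extra
#'   species-A genes hitting only the fallback lineage.
#' @param paralog_rate_direct confusion probability for the direct
#'   A-vs-B / B-vs-A tables (default `min(1, 2 * paralog_rate)`).
#' @param sigma,delta score model spread and true-paralog score gap.
#' @param seed integer seed.
#' @return list with `a_hits` (A vs panel + fallback), `b_hits` (B vs
#'   panel), `a_vs_b`, `b_vs_a` (direct tables for the RBH baseline),
#'   and `truth` (`TruthLabels`: `ortholog_truth` with `gene_a`,
#'   `gene_b`; `lineage_specific` gene ids; `true_subject` per-panel
#'   truth map used by oracle tests).
#' @export
simulate_hit_tables <- function(n_orthologs,
                                panel_species = c("gar", "coelacanth", "chicken", "human"),
                                fallback_species = "elephantfish",
                                paralog_rate = 0,
                                dropout_rate = 0,
                                lineage_specific_frac = 0.1,
                                paralog_rate_direct = min(1, 2 * paralog_rate),
                                sigma = 5, delta = 15,
                                seed = 1L) {
  assert_that(length(panel_species) > 0, "panel must be non-empty")
  assert_that(paralog_rate >= 0 && paralog_rate <= 1 &&
                dropout_rate >= 0 && dropout_rate <= 1,
              "rates must be in [0,1]")
  assert_that(n_orthologs >= 1, "need at least one ortholog pair")
  set.seed(seed)
  ga <- sprintf("shkA_%04d", seq_len(n_orthologs))
  gb <- sprintf("musB_%04d", seq_len(n_orthologs))
  proxy <- function(sp) sprintf("%s_%04d", sp, seq_len(n_orthologs))
  mu <- stats::runif(n_orthologs, 150, 300)  # per-gene conservation level

  # one direction of hits for queries `q` against species `sp`
  hits_vs <- function(q, sp, rate, drop) {
    keep <- stats::runif(length(q)) >= drop
    if (!any(keep)) {
      return(data.frame(query_id = character(), subject_species = character(),
                        subject_id = character(), evalue = numeric(),
                        bitscore = numeric(), stringsAsFactors = FALSE))
    }
    i <- which(keep)
    subj_true <- if (sp == "B") gb[i] else if (sp == "A") ga[i] else proxy(sp)[i]
    s_true <- stats::rnorm(length(i), mu[i], sigma)
    s_par <- stats::rnorm(length(i), mu[i] - delta, sigma)
    confuse <- stats::runif(length(i)) < rate
    hi <- pmax(s_true, s_par); lo <- pmin(s_true, s_par)
    s_true2 <- ifelse(confuse, lo, hi)
    s_par2 <- ifelse(confuse, hi, lo)
    out <- data.frame(
      query_id = rep(q[i], 2),
      subject_species = sp,
      subject_id = c(subj_true, paste0(subj_true, "_par")),
      bitscore = round(c(s_true2, s_par2), 1),
      stringsAsFactors = FALSE)
    out$evalue <- 10^(-out$bitscore / 2)
    out[, c("query_id", "subject_species", "subject_id", "evalue", "bitscore")]
  }

  a_hits <- do.call(rbind, lapply(panel_species, function(sp)
    hits_vs(ga, sp, paralog_rate, dropout_rate)))
  b_hits <- do.call(rbind, lapply(panel_species, function(sp)
    hits_vs(gb, sp, paralog_rate, dropout_rate)))
  # fallback hits for all A genes (never dropped: the fallback lineage is
  # the close relative every gene still matches)
  a_fb <- hits_vs(ga, fallback_species, 0, 0)
  # lineage-specific A genes: hits only against the fallback
  n_ls <- round(lineage_specific_frac * n_orthologs)
  if (n_ls > 0) {
    gls <- sprintf("shkA_ls_%04d", seq_len(n_ls))
    ls_hits <- data.frame(
      query_id = gls, subject_species = fallback_species,
      subject_id = sprintf("%s_ls_%04d", fallback_species, seq_len(n_ls)),
      bitscore = round(stats::runif(n_ls, 80, 200), 1),
      stringsAsFactors = FALSE)
    ls_hits$evalue <- 10^(-ls_hits$bitscore / 2)
    a_fb <- rbind(a_fb, ls_hits[, names(a_fb)])
  } else {
    gls <- character()
  }
  a_hits <- rbind(a_hits, a_fb)

  a_vs_b <- hits_vs(ga, "B", paralog_rate_direct, 0)
  b_vs_a <- hits_vs(gb, "A", paralog_rate_direct, 0)

  true_subject <- do.call(rbind, lapply(panel_species, function(sp)
    data.frame(gene_a = ga, gene_b = gb, species = sp, subject_id = proxy(sp),
               stringsAsFactors = FALSE)))
  truth <- structure(list(
    ortholog_truth = data.frame(gene_a = ga, gene_b = gb,
                                stringsAsFactors = FALSE),
    lineage_specific = gls,
    true_subject = true_subject), class = "TruthLabels")
  list(a_hits = a_hits, b_hits = b_hits, a_vs_b = a_vs_b, b_vs_a = b_vs_a,
       truth = truth)
}
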