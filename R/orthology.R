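#' @name orthology
#' @title Cross-species best-hit ortholog assignment
#'
#' @description
#' Assignment of orthologous gene pairs between two focal species from
#' tabular protein homology hits against a panel of bridge species, the
#' approach motivated by the observation that comparisons routed through
#' slowly evolving intermediate lineages resolve homology better than a
#' direct comparison of two distant species. The algorithm: (1) for each
#' query gene of species A, concatenate its hits against all panel
#' species (minus any excluded lineage) and take the single best-scoring
#' subject (the cross-species best hit); (2) confirm a pair (a, b) when
#' a species-B gene b has, as its best hit within the same panel
#' species, the very same subject; (3) queries with no cross-species
#' best hit fall back to their best hit in a designated close lineage,
#' catching lineage-restricted genes.
#'
#' Hit tables use the 12-column BLAST tabular dialect; only query id,
#' subject id, e-value and bitscore are consumed, and the subject
#' species is carried as a per-table tag, never parsed from gene ids.
#' All selections share one total tie rule: highest bitscore, then
#' smallest e-value, then lexicographically smallest subject id, which
#' makes every result independent of input row order.
NULL

# normalize a hit table: required columns, e-value prefilter, validity
prepare_hits <- function(hits, evalue_max) {
  req <- c("query_id", "subject_species", "subject_id", "evalue", "bitscore")
  assert_that(all(req %in% names(hits)),
              paste("hit table needs columns:", paste(req, collapse = ", ")))
  assert_that(all(hits$bitscore >= 0), "negative bitscore in hit table")
  assert_that(all(hits$evalue >= 0), "negative e-value in hit table")
  hits[hits$evalue <= evalue_max, , drop = FALSE]
}

# per-query best row under the total tie order:
# max bitscore, then min evalue, then lexicographic subject_id
best_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Cross-species best hit
#'
#' For each query, the single best-scoring subject over all non-excluded
#' panel species (ties: smaller e-value, then lexicographic subject id).
#'
#' @param hits data.frame of hits of one query species against the panel
#'   (columns `query_id`, `subject_species`, `subject_id`, `evalue`,
#'   `bitscore`).
#' @param exclude character vector of panel species to ignore (e.g. the
#'   fallback lineage).
#' @param evalue_max e-value prefilter, default `1e-30` matching the
#'   homology-search setting the tables come from.
#' @return data.frame `query_id`, `subject_species`, `subject_id`,
#'   `bitscore`, `evalue`; queries with no remaining hits are absent.
#' @export
cross_species_best_hit <- function(hits, exclude = character(), evalue_max = 1e-30) {
  hits <- prepare_hits(hits, evalue_max)
  hits <- hits[!(hits$subject_species %in% exclude), , drop = FALSE]
  out <- best_per_query(hits)
  rownames(out) <- NULL
  out[, c("query_id", "subject_species", "subject_id", "bitscore", "evalue")]
}

#' Fallback best hit for queries without a cross-species best hit
#'
#' @param hits full hit table of the query species (same columns as
#'   [cross_species_best_hit()]).
#' @param unassigned query ids that obtained no cross-species best hit.
#' @param fallback_species the fallback lineage species id.
#' @param evalue_max e-value prefilter.
#' @return data.frame `query_id`, `subject_id`, `bitscore`, `evalue`
#'   restricted to the fallback species; queries with no fallback hit
#'   remain absent (the no-orthology class).
#' @export
fallback_best_hit <- function(hits, unassigned, fallback_species,
                              evalue_max = 1e-30) {
  hits <- prepare_hits(hits, evalue_max)
  hits <- hits[hits$subject_species == fallback_species &
                 hits$query_id %in% unassigned, , drop = FALSE]
  out <- best_per_query(hits)
  rownames(out) <- NULL
  out[, c("query_id", "subject_id", "bitscore", "evalue")]
}

#' Species-wise confirmation of cross-species best hits
#'
#' Emits a pair (a, b) when query a's cross-species best hit is subject
#' h in panel species S, and species-B gene b's best hit restricted to S
#' is that same h. All qualifying b are emitted; uniqueness of each pair
#' is classified from the resulting pair multiset.
#'
#' @param a_best result of [cross_species_best_hit()] for species A.
#' @param b_hits hit table of species-B queries against the panel.
#' @param evalue_max e-value prefilter applied to `b_hits`.
#' @return An `OrthologyMap`: list with `pairs` (data.frame `gene_a`,
#'   `gene_b`, `via_species`, `provenance`, `uniqueness`), `unpaired_a`
#'   (species-A queries whose best hit no B gene confirmed), and
#'   `missing_species` (panel species required by `a_best` but absent
#'   from `b_hits`, whose candidate pairs cannot be confirmed --
#'   reported, not silently dropped).
#' @export
species_wise_confirm <- function(a_best, b_hits, evalue_max = 1e-30) {
  b_hits <- prepare_hits(b_hits, evalue_max)
  need <- unique(a_best$subject_species)
  have <- unique(b_hits$subject_species)
  missing_species <- setdiff(need, have)
  # best hit of every B query within each panel species separately
  b_by_sp <- do.call(rbind, lapply(intersect(need, have), function(sp) {
    best_per_query(b_hits[b_hits$subject_species == sp, , drop = FALSE])
  }))
  pairs <- if (is.null(b_by_sp) || nrow(b_by_sp) == 0) {
    data.frame(gene_a = character(), gene_b = character(),
               via_species = character(), stringsAsFactors = FALSE)
  } else {
    key_a <- paste(a_best$subject_species, a_best$subject_id, sep = "\r")
    key_b <- paste(b_by_sp$subject_species, b_by_sp$subject_id, sep = "\r")
    hit_idx <- split(seq_along(key_b), key_b)
    rows <- lapply(seq_along(key_a), function(i) {
      j <- hit_idx[[key_a[i]]]
      if (is.null(j)) return(NULL)
      data.frame(gene_a = a_best$query_id[i], gene_b = b_by_sp$query_id[j],
                 via_species = a_best$subject_species[i],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) data.frame(gene_a = character(), gene_b = character(),
                                 via_species = character(),
                                 stringsAsFactors = FALSE) else out
  }
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
    rownames(pairs) <- NULL
    na <- table(pairs$gene_a)[pairs$gene_a]
    nb <- table(pairs$gene_b)[pairs$gene_b]
    pairs$provenance <- "cross_species_best_hit"
    pairs$uniqueness <- ifelse(na == 1 & nb == 1, "unique",
                        ifelse(na > 1 & nb == 1, "one_to_many",
                        ifelse(na == 1 & nb > 1, "many_to_one", "many_to_many")))
  } else {
    pairs$provenance <- character()
    pairs$uniqueness <- character()
  }
  structure(list(pairs = pairs,
                 unpaired_a = setdiff(a_best$query_id, pairs$gene_a),
                 missing_species = missing_species),
            class = "OrthologyMap")
}

#' @export
print.OrthologyMap <- function(x, ...) {
  cat(sprintf("OrthologyMap: %d pairs (%d unique), %d unconfirmed A queries\n",
              nrow(x$pairs), sum(x$pairs$uniqueness == "unique"),
              length(x$unpaired_a)))
  if (length(x$missing_species))
    cat("warning: b_hits missing for panel species:",
        paste(x$missing_species, collapse = ", "), "\n")
  if (!is.null(x$fallback) && nrow(x$fallback))
    cat(sprintf("fallback assignments: %d\n", nrow(x$fallback)))
  invisible(x)
}

#' Full ortholog assignment: cross-species best hit + confirmation + fallback
#'
#' Convenience driver chaining [cross_species_best_hit()],
#' [species_wise_confirm()] and [fallback_best_hit()]. Every species-A
#' query ends in exactly one of three classes: paired, fallback-assigned,
#' or unassigned (no orthology).
#'
#' @param a_hits hit table of species-A queries vs the panel (fallback
#'   species included as one panel member).
#' @param b_hits hit table of species-B queries vs the panel.
#' @param fallback_species fallback lineage id, excluded from the
#'   cross-species best hit scan.
#' @param evalue_max e-value prefilter.
#' @return An `OrthologyMap` with additional fields `fallback`
#'   (data.frame `gene_a`, `subject_id`) and `unassigned` (species-A
#'   queries with no hits anywhere), plus a `summary` count table.
#' @export
assign_orthologs <- function(a_hits, b_hits, fallback_species = NULL,
                             evalue_max = 1e-30) {
  a_best <- cross_species_best_hit(a_hits,
                                   exclude = fallback_species %||% character(),
                                   evalue_max = evalue_max)
  om <- species_wise_confirm(a_best, b_hits, evalue_max = evalue_max)
  all_a <- unique(prepare_hits(a_hits, evalue_max)$query_id)
  no_csbh <- setdiff(all_a, a_best$query_id)
  fb <- if (!is.null(fallback_species)) {
    fallback_best_hit(a_hits, no_csbh, fallback_species, evalue_max)
  } else {
    data.frame(query_id = character(), subject_id = character())
  }
  om$fallback <- data.frame(gene_a = fb$query_id, gene_b_fallback = fb$subject_id,
                            stringsAsFactors = FALSE)
  # a query whose cross-species best hit no B gene confirmed is not
  # eligible for the fallback route (that is reserved for queries with
  # no cross-species best hit at all); it ends in the no-orthology class
  om$unassigned <- setdiff(all_a, c(unique(om$pairs$gene_a), fb$query_id))
  om$summary <- data.frame(
    class = c("paired", "fallback_assigned", "no_orthology"),
    n = c(length(unique(om$pairs$gene_a)), nrow(om$fallback),
          length(om$unassigned)))
  om
}

#' Reciprocal best hit baseline
#'
#' The classical RBH rule between the two focal species directly:
#' (a, b) is a pair iff b is a's best hit in B and a is b's best hit in
#' A, under the same total tie rules as the cross-species method.
#'
#' @param a_vs_b,b_vs_a hit tables for the two directions.
#' @param evalue_max e-value prefilter.
#' @return data.frame `gene_a`, `gene_b`.
#' @export
reciprocal_best_hit <- function(a_vs_b, b_vs_a, evalue_max = 1e-30) {
  ba <- best_per_query(prepare_hits(a_vs_b, evalue_max))
  bb <- best_per_query(prepare_hits(b_vs_a, evalue_max))
  m <- match(ba$subject_id, bb$query_id)
  ok <- !is.na(m) & bb$subject_id[m] == ba$query_id
  out <- data.frame(gene_a = ba$query_id[ok], gene_b = ba$subject_id[ok],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of a curated truth set recovered by an assignment
#'
#' @param pairs pair table (`gene_a`, `gene_b`) or an `OrthologyMap`.
#' @param truth curated truth pair table (`gene_a`, `gene_b`), non-empty.
#' @param family optional vector (same length as truth rows) for a
#'   per-family breakdown.
#' @return fraction |assigned intersect truth| / |truth|; with `family`,
#'   a named vector of per-family fractions plus `"overall"`.
#' @export
evaluate_accuracy <- function(pairs, truth, family = NULL) {
  if (inherits(pairs, "OrthologyMap")) pairs <- pairs$pairs
  assert_that(nrow(truth) > 0, "empty truth set")
  key_p <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  key_t <- paste(truth$gene_a, truth$gene_b, sep = "\r")
  hit <- key_t %in% key_p
  if (is.null(family)) return(mean(hit))
  c(tapply(hit, family, mean), overall = mean(hit))
}
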