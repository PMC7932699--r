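# shared fixture builders; everything is generated in code

em_from_means <- function(means, species = "sp", stages = NULL) {
  means <- as.matrix(means)
  stages <- stages %||% colnames(means) %||% paste0("s", seq_len(ncol(means)))
  arr <- array(means, dim = c(nrow(means), ncol(means), 1))
  expression_matrix(arr, species = species,
                    genes = rownames(means) %||% paste0("g", seq_len(nrow(means))),
                    stages = stages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hit_df <- function(...) {
  # rows of (query_id, subject_species, subject_id, evalue, bitscore)
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(query_id = r[[1]], subject_species = r[[2]], subject_id = r[[3]],
               evalue = as.numeric(r[[4]]), bitscore = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)))
  out
}

# independent brute-force best-hit oracle: plain loop over queries,
# re-implementing the tie order (score desc, evalue asc, subject asc)
oracle_best_hits <- function(hits, species = NULL) {
  if (!is.null(species)) hits <- hits[hits$subject_species %in% species, ]
  out <- list()
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q, ]
    h <- h[h$bitscore == max(h$bitscore), ]
    h <- h[h$evalue == min(h$evalue), ]
    h <- h[order(h$subject_id), ][1, ]
    out[[q]] <- h
  }
  do.call(rbind, out)
}

# independent Jensen-Shannon divergence via the entropy identity
jsd_oracle <- function(p, q) {
  H <- function(x) { x <- x[x > 0]; -sum(x * log(x)) }
  m <- (p + q) / 2
  H(m) - (H(p) + H(q)) / 2
}

small_genome <- function() data.frame(chrom = c("chr1", "chr2"),
                                      size = c(2000000L, 2000000L))
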