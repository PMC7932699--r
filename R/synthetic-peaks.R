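#' Simulate staged ATAC-seq peak sets with planted conservation and FRiP
#'
#' Generates per-stage peak sets on a given genome with controllable
#' sharing between stages, alignment-hit tables planting an exact
#' conserved fraction of peak bases (at grid resolution), and synthetic
#' reads achieving a target FRiP, plus truth labels for oracle tests.
#'
#' Peaks are placed on a non-overlapping slot grid (slot = peak width +
#' gap), uniformly at random without replacement: `shared_fraction` of
#' each stage's peaks are a common set present in all stages, the rest
#' are private to their stage. Per stage, the occupied fine-grid bins
#' are computed exactly as the downstream pipeline would
#' ([assign_to_bins()]), and a `conserved_fraction` share of those bins
#' (rounded to a whole bin; per-stage values may be a vector) receives
#' an alignment hit scoring in [score_min, 100]; half of the remaining
#' bins receive a sub-threshold hit, the rest none.
#'
#' @param genome data.frame (`chrom`, `size`), chrom.sizes-like.
#' @param n_peaks_per_stage peaks per stage (scalar or one per stage).
#' @param stages stage labels (default 4 stages, E9.5-E12.5 analogue).
#' @param shared_fraction fraction of peaks common to all stages.
#' @param conserved_fraction target conserved fraction of peak bases
#'   per stage (scalar or per-stage vector).
#' @param n_reads reads simulated per stage.
#' @param frip_target fraction of reads placed inside peaks; the rest
#'   land in peak-free sequence.
#' @param peak_width,gap,read_len geometry in bp.
#' @param fine_width fine bin width for the conservation truth
#'   (default 100).
#' @param score_min conservation score threshold being planted against.
#' @param target_genome label written into the hit table.
#' @param seed integer seed.
#' @return list with `peaks` (per-stage list of peak data.frames with
#'   `summit` column), `reads` (per-stage list), `hits` (per-stage list
#'   of alignment-hit tables), and `truth` (`TruthLabels`:
#'   `conserved_bins` per stage, `planted_conserved_fraction`,
#'   `planted_frip`, `shared_peaks`).
#' @export
simulate_peak_data <- function(genome,
                               n_peaks_per_stage = 200,
                               stages = paste0("E", c("9.5", "10.5", "11.5", "12.5")),
                               shared_fraction = 0.5,
                               conserved_fraction = 0.4,
                               n_reads = 10000,
                               frip_target = 0.3,
                               peak_width = 400, gap = 600,
                               read_len = 50,
                               fine_width = 100,
                               score_min = 40,
                               target_genome = "shark",
                               seed = 1L) {
  assert_that(nrow(genome) > 0, "genome empty")
  assert_that(peak_width > 0, "peak length <= 0")
  n_stage <- length(stages)
  n_peaks <- rep_len(n_peaks_per_stage, n_stage)
  cons <- rep_len(conserved_fraction, n_stage)
  assert_that(all(shared_fraction >= 0 & shared_fraction <= 1) &&
                all(cons >= 0 & cons <= 1), "fractions must be in [0,1]")
  set.seed(seed)

  slot <- peak_width + gap
  slots <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    k <- genome$size[i] %/% slot
    if (k < 1) return(NULL)
    data.frame(chrom = as.character(genome$chrom[i]),
               start = (seq_len(k) - 1L) * slot, stringsAsFactors = FALSE)
  }))
  n_shared <- round(shared_fraction * n_peaks[1])
  need <- n_shared + sum(n_peaks - n_shared)
  assert_that(!is.null(slots) && nrow(slots) >= need,
              "genome too small for the requested peaks; peaks must fit within chromosome bounds")
  pick_idx <- sample.int(nrow(slots), need)
  picks <- slots[pick_idx, , drop = FALSE]
  # random offset of each peak inside its slot
  picks$start <- picks$start + sample.int(gap, nrow(picks), replace = TRUE) - 1L
  make_peaks <- function(rows) {
    p <- data.frame(chrom = rows$chrom, start = rows$start,
                    end = rows$start + peak_width, stringsAsFactors = FALSE)
    p$summit <- peak_width %/% 2L
    p[order(p$chrom, p$start), , drop = FALSE]
  }
  shared <- picks[seq_len(n_shared), , drop = FALSE]
  used <- n_shared
  fine <- bin_grid(genome, fine_width)
  peaks <- reads <- hits <- vector("list", n_stage)
  names(peaks) <- names(reads) <- names(hits) <- stages
  conserved_bins <- stats::setNames(vector("list", n_stage), stages)

  for (s in seq_len(n_stage)) {
    n_priv <- n_peaks[s] - n_shared
    priv <- picks[used + seq_len(n_priv), , drop = FALSE]
    used <- used + n_priv
    p <- make_peaks(rbind(shared, priv))
    rownames(p) <- NULL
    peaks[[s]] <- p

    # plant conservation on the exact fine-grid bin set of this stage
    bp <- assign_to_bins(p, fine)
    nb <- nrow(bp$bins)
    n_cons <- round(cons[s] * nb)
    cons_idx <- if (n_cons > 0) sample.int(nb, n_cons) else integer()
    rest <- setdiff(seq_len(nb), cons_idx)
    low_idx <- rest[stats::runif(length(rest)) < 0.5]
    h <- rbind(
      if (length(cons_idx)) data.frame(
        chrom = bp$bins$chrom[cons_idx], start = bp$bins$start[cons_idx],
        end = bp$bins$end[cons_idx], target = target_genome,
        score = round(stats::runif(length(cons_idx), score_min, 100), 1),
        stringsAsFactors = FALSE),
      if (length(low_idx)) data.frame(
        chrom = bp$bins$chrom[low_idx], start = bp$bins$start[low_idx],
        end = bp$bins$end[low_idx], target = target_genome,
        score = round(stats::runif(length(low_idx), 10, score_min - 0.5), 1),
        stringsAsFactors = FALSE))
    hits[[s]] <- h %||% data.frame(chrom = character(), start = integer(),
                                   end = integer(), target = character(),
                                   score = numeric())
    conserved_bins[[s]] <- bin_key(bp$bins$chrom[cons_idx],
                                   bp$bins$start[cons_idx])

    # reads: frip_target of them inside peaks, the rest in the slot gaps
    # beyond any peak (slot layout guarantees peak-free sequence there)
    in_peak <- stats::runif(n_reads) < frip_target
    n_in <- sum(in_peak)
    ri <- p[sample.int(nrow(p), n_in, replace = TRUE), , drop = FALSE]
    off <- sample.int(peak_width - read_len, n_in, replace = TRUE) - 1L
    rin <- data.frame(chrom = ri$chrom, start = ri$start + off,
                      stringsAsFactors = FALSE)
    # out-of-peak reads: place inside unused slots (never overlapping peaks)
    free <- slots[-pick_idx, , drop = FALSE]
    assert_that(nrow(free) > 0, "no peak-free slots left for background reads")
    ro <- free[sample.int(nrow(free), n_reads - n_in, replace = TRUE), , drop = FALSE]
    off2 <- sample.int(slot - read_len, n_reads - n_in, replace = TRUE) - 1L
    rout <- data.frame(chrom = ro$chrom, start = ro$start + off2,
                       stringsAsFactors = FALSE)
    rr <- rbind(rin, rout)
    rr$end <- rr$start + read_len
    reads[[s]] <- rr[order(rr$chrom, rr$start), , drop = FALSE]
  }

  truth <- structure(list(
    conserved_bins = conserved_bins,
    planted_conserved_fraction = stats::setNames(
      vapply(seq_len(n_stage), function(s) {
        nb <- nrow(assign_to_bins(peaks[[s]], fine)$bins)
        if (nb == 0) 0 else length(conserved_bins[[s]]) / nb
      }, numeric(1)), stages),
    planted_frip = frip_target,
    shared_peaks = make_peaks(shared)), class = "TruthLabels")
  list(peaks = peaks, reads = reads, hits = hits, truth = truth)
}
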