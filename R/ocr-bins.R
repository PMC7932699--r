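#' Fixed-width genome bin grid
#'
#' Tiles each chromosome with bins of `bin_width` bp anchored at
#' coordinate 0 (0-based, half-open); the last bin of a chromosome may
#' be short.
#'
#' @param chrom_sizes data.frame with columns `chrom`, `size`.
#' @param bin_width bin width in bp (500 for occupancy vectors, 100 for
#'   the conservation analysis).
#' @return a `BinGrid` list with `chrom_sizes`, `bin_width`.
#' @export
bin_grid <- function(chrom_sizes, bin_width) {
  assert_that(nrow(chrom_sizes) > 0, "empty genome")
  assert_that(all(c("chrom", "size") %in% names(chrom_sizes)),
              "chrom_sizes needs columns chrom, size")
  assert_that(all(chrom_sizes$size > 0) && bin_width >= 1,
              "sizes and bin_width must be positive")
  chrom_sizes$chrom <- as.character(chrom_sizes$chrom)
  assert_that(!anyDuplicated(chrom_sizes$chrom), "duplicated chromosome")
  structure(list(chrom_sizes = chrom_sizes, bin_width = as.integer(bin_width)),
            class = "BinGrid")
}

grid_size <- function(g, chrom) {
  g$chrom_sizes$size[match(chrom, g$chrom_sizes$chrom)]
}

# bin id encoding "chrom:start"; all bin bookkeeping goes through these
bin_key <- function(chrom, start) paste0(chrom, ":", start)

bin_length <- function(g, chrom, start) {
  pmin(start + g$bin_width, grid_size(g, chrom)) - start
}

validate_peaks <- function(peaks, g = NULL) {
  assert_that(all(c("chrom", "start", "end") %in% names(peaks)),
              "peaks need columns chrom, start, end")
  assert_that(all(peaks$end > peaks$start), "peak with length <= 0")
  assert_that(all(peaks$start >= 0), "negative peak start")
  if (!is.null(g)) {
    sz <- grid_size(g, as.character(peaks$chrom))
    assert_that(!anyNA(sz), "peak on a chromosome absent from the grid")
    assert_that(all(peaks$end <= sz), "peak beyond chromosome end")
  }
  invisible(peaks)
}

#' Assign peaks to fixed-width genome bins
#'
#' Reproduces the reciprocal-overlap binning rule (bedtools
#' `intersect -F 0.4 -f 0.4 -e` semantics): a bin is occupied iff some
#' peak overlaps it by at least `min_frac` of the bin length OR at
#' least `min_frac` of the peak length (`either = TRUE`; with
#' `either = FALSE` both conditions must hold). Long peaks thereby
#' occupy every bin they cover by >= 40%, and short peaks snap to the
#' bin(s) holding at least 40% of their length. Thresholds are
#' inclusive (>=). Idempotent and independent of peak order.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open, within grid chromosomes).
#' @param g a [bin_grid()].
#' @param min_frac reciprocal overlap fraction, default 0.4.
#' @param either one overlap condition suffices (default TRUE).
#' @return a `BinnedPeaks` list: `bins` data.frame (`chrom`, `start`,
#'   `end`, sorted, unique), `grid`, and the `sample` label if present
#'   on `peaks` (attribute `sample`).
#' @export
assign_to_bins <- function(peaks, g, min_frac = 0.4, either = TRUE) {
  stopifnot(inherits(g, "BinGrid"))
  validate_peaks(peaks, g)
  w <- g$bin_width
  rows <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$start[i]; e <- peaks$end[i]; chrom <- as.character(peaks$chrom[i])
    first <- (s %/% w) * w
    starts <- seq(first, e - 1, by = w)
    ovl <- pmin(e, starts + w) - pmax(s, starts)
    blen <- bin_length(g, chrom, starts)
    cond_bin <- ovl >= min_frac * blen
    cond_peak <- ovl >= min_frac * (e - s)
    keep <- if (either) cond_bin | cond_peak else cond_bin & cond_peak
    if (any(keep)) {
      rows[[i]] <- data.frame(chrom = chrom, start = starts[keep],
                              stringsAsFactors = FALSE)
    }
  }
  bins <- unique(do.call(rbind, rows) %||%
                   data.frame(chrom = character(), start = integer()))
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  bins$end <- bins$start + bin_length(g, bins$chrom, bins$start)
  rownames(bins) <- NULL
  structure(list(bins = bins, grid = g,
                 sample = attr(peaks, "sample") %||% NA_character_),
            class = "BinnedPeaks")
}

#' @export
print.BinnedPeaks <- function(x, ...) {
  cat(sprintf("BinnedPeaks: %d occupied %d-bp bins (sample %s)\n",
              nrow(x$bins), x$grid$bin_width, x$sample))
  invisible(x)
}

occupied_keys <- function(b) {
  stopifnot(inherits(b, "BinnedPeaks"))
  bin_key(b$bins$chrom, b$bins$start)
}

#' Euclidean distance between one-hot bin occupancy vectors
#'
#' Peaks converted to 0/1 vectors over the bin grid (1 = the bin
#' harbors a peak); bins lacking a peak in all samples are omitted via
#' the `universe` argument. The Euclidean distance between two 0/1
#' vectors equals the square root of their symmetric-difference size.
#'
#' @param a,b `BinnedPeaks` on the same grid.
#' @param universe optional character vector of bin keys
#'   (`"chrom:start"`) to restrict to, e.g. bins occupied in any
#'   sample; by default all bins of either sample are used (identical
#'   result, since bins outside the union contribute zero).
#' @return the Euclidean distance.
#' @export
onehot_distance <- function(a, b, universe = NULL) {
  assert_that(identical(a$grid$bin_width, b$grid$bin_width),
              "grids differ between samples")
  ka <- occupied_keys(a); kb <- occupied_keys(b)
  if (!is.null(universe)) {
    ka <- intersect(ka, universe); kb <- intersect(kb, universe)
  }
  sqrt(length(setdiff(ka, kb)) + length(setdiff(kb, ka)))
}

#' Occupancy universe over a list of binned samples
#' @param samples list of `BinnedPeaks`.
#' @return character vector of bin keys occupied in at least one sample.
#' @export
bin_universe <- function(samples) {
  unique(unlist(lapply(samples, occupied_keys)))
}

#' Tissue-specific peak bins
#'
#' Bins occupied in the focal sample but in none of a panel of other
#' tissues/cell types; optionally summarised as the specific fraction
#' per cluster of focal bins.
#'
#' @param focal `BinnedPeaks` for the focal tissue.
#' @param panel list of `BinnedPeaks` from other tissues (an empty
#'   panel makes every focal bin trivially specific, with a warning).
#' @param clusters optional vector of cluster labels, one per focal
#'   bin (in `focal$bins` row order).
#' @return list with `specific` (logical per focal bin), `bins` (the
#'   specific subset of `focal$bins`), `fraction` (overall), and, with
#'   `clusters`, `fraction_by_cluster`.
#' @export
tissue_specific_peaks <- function(focal, panel, clusters = NULL) {
  stopifnot(inherits(focal, "BinnedPeaks"))
  if (length(panel) == 0) {
    warning("empty panel: every focal peak is trivially tissue-specific")
    pan_keys <- character()
  } else {
    pan_keys <- bin_universe(panel)
  }
  keys <- occupied_keys(focal)
  specific <- !(keys %in% pan_keys)
  out <- list(specific = specific,
              bins = focal$bins[specific, , drop = FALSE],
              fraction = if (length(specific)) mean(specific) else NA_real_)
  if (!is.null(clusters)) {
    assert_that(length(clusters) == length(specific),
                "clusters must have one label per focal bin")
    out$fraction_by_cluster <- tapply(specific, clusters, mean)
  }
  out
}
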