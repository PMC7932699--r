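grid1 <- function(width = 500) bin_grid(data.frame(chrom = "chr1",
                                                   size = 100000L), width)

test_that("bin assignment reproduces the reciprocal-overlap rule", {
  g <- grid1()
  # long peak: occupies every bin covered >= 40% of the bin
  b <- assign_to_bins(data.frame(chrom = "chr1", start = 0, end = 1200), g)
  expect_equal(b$bins$start, c(0L, 500L, 1000L))  # 200/500 = 0.4 >= 0.4
  # short peak fully inside one bin: 100% of the peak
  b2 <- assign_to_bins(data.frame(chrom = "chr1", start = 120, end = 220), g)
  expect_equal(b2$bins$start, 0L)
  # straddling peak split 20/30: peak fractions 0.4 and 0.6, both >= 0.4
  b3 <- assign_to_bins(data.frame(chrom = "chr1", start = 480, end = 530), g)
  expect_equal(b3$bins$start, c(0L, 500L))
  # and just under the boundary: 19/50 < 0.4 of peak and of bin
  b4 <- assign_to_bins(data.frame(chrom = "chr1", start = 481, end = 531), g)
  expect_equal(b4$bins$start, 500L)
})

test_that("bin assignment is idempotent, order-independent, and bounded", {
  g <- grid1()
  set.seed(41)
  starts <- sample(0:99000, 50)
  peaks <- data.frame(chrom = "chr1", start = starts, end = starts + 700)
  b <- assign_to_bins(peaks, g)
  # re-binning the occupied bins maps them onto themselves
  b2 <- assign_to_bins(b$bins, g)
  expect_equal(b2$bins, b$bins)
  # permutation invariance
  b3 <- assign_to_bins(peaks[sample(nrow(peaks)), ], g)
  expect_equal(b3$bins, b$bins)
  # occupied count bounded by total ceiling(span / width) over peaks
  expect_lte(nrow(b$bins), sum(ceiling((peaks$end - peaks$start) / 500) + 1))
  expect_error(assign_to_bins(data.frame(chrom = "chrX", start = 0, end = 10), g),
               "absent")
})

test_that("bin assignment equals an interval-arithmetic oracle", {
  g <- grid1()
  set.seed(42)
  starts <- sample(0:98000, 80)
  widths <- sample(c(50, 200, 500, 900, 1700), 80, replace = TRUE)
  peaks <- data.frame(chrom = "chr1", start = starts,
                      end = pmin(starts + widths, 100000))
  got <- assign_to_bins(peaks, g)$bins$start
  occ <- logical(200)
  for (i in seq_len(nrow(peaks))) {
    for (bs in seq(0, 99500, by = 500)) {
      ov <- min(peaks$end[i], bs + 500) - max(peaks$start[i], bs)
      if (ov <= 0) next
      if (ov >= 0.4 * 500 || ov >= 0.4 * (peaks$end[i] - peaks$start[i]))
        occ[bs / 500 + 1] <- TRUE
    }
  }
  expect_equal(got, seq(0, 99500, by = 500)[occ])
})

test_that("one-hot distance equals the symmetric-difference square root", {
  g <- grid1()
  mk <- function(starts) assign_to_bins(
    data.frame(chrom = "chr1", start = starts, end = starts + 400), g)
  a <- mk(c(0, 1000, 2000, 3000))
  b <- mk(c(5000, 6000, 7000, 8000, 9000))
  expect_equal(onehot_distance(a, a), 0)
  expect_equal(onehot_distance(a, b), 3)  # disjoint 4 vs 5: sqrt(9)
  set.seed(43)
  for (i in 1:20) {
    sa <- sample(seq(0, 99000, 500), 30) + 10
    sb <- sample(seq(0, 99000, 500), 40) + 10
    A <- mk(sa); B <- mk(sb)
    ka <- paste(A$bins$chrom, A$bins$start)
    kb <- paste(B$bins$chrom, B$bins$start)
    expect_equal(onehot_distance(A, B),
                 sqrt(length(setdiff(ka, kb)) + length(setdiff(kb, ka))))
  }
})

test_that("conserved fraction applies the inclusive score threshold per bin", {
  g <- grid1(100)
  starts <- seq(0, 900, by = 100)
  binned <- assign_to_bins(data.frame(chrom = "chr1", start = starts,
                                      end = starts + 100), g)
  expect_equal(nrow(binned$bins), 10)
  hits <- data.frame(chrom = "chr1", start = starts[1:5], end = starts[1:5] + 100,
                     target = "shark", score = c(80, 50, 40, 39.9, 10))
  cf <- conserved_fraction(binned, hits, score_min = 40)
  expect_equal(cf$fraction, 0.3)  # 40 counts, 39.9 does not
  expect_equal(cf$not_conserved_fraction, 0.5)  # five bins with no hit
  # best-hit reduction: a second weak hit never demotes a conserved bin
  hits2 <- rbind(hits, data.frame(chrom = "chr1", start = 0, end = 100,
                                  target = "gator", score = 5))
  expect_equal(conserved_fraction(binned, hits2)$fraction, 0.3)
  expect_equal(unname(conserved_fraction(binned, hits2,
                                         by_target = TRUE)$fraction_by_target["gator"]), 0)
  expect_error(conserved_fraction(assign_to_bins(
    data.frame(chrom = character(), start = integer(), end = integer()), g),
    hits), "empty")
})

test_that("FRiP scores reads in peaks against the total", {
  peaks <- data.frame(chrom = "chr1", start = c(1000, 5000), end = c(1400, 5400))
  reads_in <- data.frame(chrom = "chr1", start = seq(1000, 1390, length.out = 50),
                         end = seq(1000, 1390, length.out = 50) + 10)
  reads_out <- data.frame(chrom = "chr1", start = seq(20000, 60000, length.out = 150),
                          end = seq(20000, 60000, length.out = 150) + 10)
  f <- frip(rbind(reads_in, reads_out), peaks)
  expect_equal(f$score, 0.25)
  expect_true(f$pass)
  f0 <- frip(reads_out, peaks)
  expect_equal(f0$score, 0)
  expect_false(f0$pass)
  expect_equal(frip(50, total_reads = 200)$score, 0.25)
  expect_error(frip(reads_in, peaks, total_reads = 0), "positive")
})

test_that("simulated reads reproduce the target FRiP at 10^4 reads", {
  ps <- simulate_peak_data(small_genome(), n_peaks_per_stage = 150,
                           n_reads = 10000, frip_target = 0.3, seed = 44)
  f <- frip(ps$reads[[1]], ps$peaks[[1]])
  expect_equal(f$score, 0.30, tolerance = 0.02 / 0.30)
})

test_that("differential bin counts come from a two-sided t test", {
  # identical replicate sets across stages: nothing significant
  db <- differential_bins(rbind(b1 = c(5, 5.1, 4.9, 5, 5.1, 4.9)),
                          list(s1 = 1:3, s2 = 4:6))
  expect_equal(db$counts$increased + db$counts$decreased, 0)
  # clear increase is counted at alpha 0.05 and matches t.test
  x <- c(1, 1.02, 0.98); y <- c(5, 5.1, 4.9)
  db2 <- differential_bins(rbind(b1 = c(x, y)), list(s1 = 1:3, s2 = 4:6))
  expect_equal(db2$counts$increased, 1)
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(db2$tests[[1]]$p, tt$p.value)
  expect_equal(db2$tests[[1]]$t, unname(tt$statistic))
  # zero variance in both groups: skipped and logged
  db3 <- differential_bins(rbind(b1 = c(1, 1, 1, 2, 2, 2)),
                           list(s1 = 1:3, s2 = 4:6))
  expect_equal(db3$counts$skipped, 1)
  expect_equal(db3$counts$tested, 0)
})

test_that("type-I error of differential bins is calibrated on null data", {
  set.seed(45)
  sig <- matrix(rnorm(1000 * 6, 10, 2), 1000, 6)
  db <- differential_bins(sig, list(s1 = 1:3, s2 = 4:6), alpha = 0.05)
  n_sig <- db$counts$increased + db$counts$decreased
  # binomial(1000, 0.05): mean 50, sd ~6.9; allow 2 sigma
  expect_gte(n_sig, 50 - 2 * sqrt(1000 * 0.05 * 0.95))
  expect_lte(n_sig, 50 + 2 * sqrt(1000 * 0.05 * 0.95))
})

test_that("motif counting matches consensus, N handling, and the 75% rule", {
  mat <- matrix(0.01, 4, 6)
  consensus <- c(1, 3, 3, 2, 4, 1)  # ACGT indexing: A G G C T A
  for (j in 1:6) mat[consensus[j], j] <- 0.97
  p <- pwm(mat, id = "m1")
  seq_hit <- "TTTAGGCTATTT"
  expect_gte(motif_occurrences(seq_hit, p)$counts, 1)
  expect_equal(motif_occurrences("NNNNNNNNNN", p)$counts, 0L)
  expect_equal(motif_occurrences("ACG", p)$counts, 0L)  # shorter than motif
  # reverse strand is scanned: the reverse complement of the consensus
  expect_gte(motif_occurrences("TTTAGCCTATTT", p)$counts, 1)
})

test_that("motif counts equal an exhaustive per-window rescoring oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(46)
  mat <- matrix(runif(4 * 8), 4, 8)
  p <- pwm(mat, id = "m2")
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = ""),
    character(1))
  got <- motif_occurrences(seqs, p, frac = 0.75)$counts
  thr <- 0.75 * p$max_score
  oracle <- vapply(seqs, function(s) {
    n <- 0L
    for (str in c(s, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s))))) {
      sc <- Biostrings::PWMscoreStartingAt(p$log_odds, Biostrings::DNAString(str),
                                           starting.at = 1:(nchar(str) - 7))
      n <- n + sum(sc >= thr)
    }
    n
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(got, oracle)
})

test_that("tissue-specific peaks are the panel set difference", {
  g <- grid1()
  mk <- function(starts) assign_to_bins(
    data.frame(chrom = "chr1", start = starts, end = starts + 400), g)
  focal <- mk(c(0, 1000, 2000, 3000))
  panel <- list(mk(c(0, 1000)), mk(c(2000, 50000)))
  ts <- tissue_specific_peaks(focal, panel)
  expect_equal(ts$bins$start, 3000L)
  expect_equal(ts$fraction, 0.25)
  # focal contained in panel: nothing specific
  expect_equal(tissue_specific_peaks(mk(0), list(mk(0)))$fraction, 0)
  # disjoint: all specific; empty panel warns
  expect_equal(tissue_specific_peaks(mk(9000), list(mk(0)))$fraction, 1)
  expect_warning(tissue_specific_peaks(focal, list()), "empty panel")
  # per-cluster fractions
  ts2 <- tissue_specific_peaks(focal, panel,
                               clusters = c("c1", "c1", "c2", "c2"))
  expect_equal(unname(ts2$fraction_by_cluster["c1"]), 0)
  expect_equal(unname(ts2$fraction_by_cluster["c2"]), 0.5)
  # random sets equal the set-difference oracle
  set.seed(47)
  for (i in 1:10) {
    f <- mk(sample(seq(0, 99000, 500), 25) + 5)
    pan <- list(mk(sample(seq(0, 99000, 500), 30) + 5))
    got <- tissue_specific_peaks(f, pan)
    kf <- paste(f$bins$chrom, f$bins$start)
    kp <- paste(pan[[1]]$bins$chrom, pan[[1]]$bins$start)
    expect_equal(sum(got$specific), length(setdiff(kf, kp)))
  }
})

test_that("per-stage conservation peaks at the stage with the planted maximum", {
  # 4 stages; the 2nd has the largest planted conserved fraction and the
  # most stage-specific peaks
  ps <- simulate_peak_data(small_genome(),
                           n_peaks_per_stage = c(120, 200, 120, 120),
                           shared_fraction = 0.4,
                           conserved_fraction = c(0.2, 0.5, 0.2, 0.2),
                           seed = 48)
  g100 <- bin_grid(small_genome(), 100)
  consv <- vapply(names(ps$peaks), function(s)
    conserved_fraction(assign_to_bins(ps$peaks[[s]], g100),
                       ps$hits[[s]])$fraction, numeric(1))
  expect_equal(unname(which.max(consv)), 2L)
  # and stage 2 has the most specific peaks against the other stages
  g500 <- bin_grid(small_genome(), 500)
  binned <- lapply(ps$peaks, assign_to_bins, g = g500)
  nspec <- vapply(seq_along(binned), function(i)
    nrow(tissue_specific_peaks(binned[[i]], binned[-i])$bins), numeric(1))
  expect_equal(unname(which.max(nspec)), 2L)
})
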