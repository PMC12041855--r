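test_that("deduplication keys on chrom, strand, position and length", {
  rs <- reads_at("chr1", c("+", "+", "+", "-"), pos5 = c(100, 100, 100, 100),
                 length = c(30, 30, 31, 30))
  dd <- deduplicate(rs)
  expect_equal(nrow(dd$reads), 3)       # identical pair collapsed
  empty <- reads_at(character(0), character(0), numeric(0), numeric(0))
  expect_equal(nrow(deduplicate(empty)$reads), 0)
  # order independence
  perm <- read_end_set(rs$reads[c(4, 2, 3, 1)])
  expect_identical(deduplicate(perm)$reads, dd$reads)
})

test_that("coverage bins 5' ends, conserves counts, matches per-base oracle", {
  rs <- reads_at("chr1", "+", pos5 = 25)
  tr <- coverage(rs, c(chr1 = 100), bin = 10)
  expect_equal(tr$bins[["chr1|+"]][3], 1)
  withr::with_seed(8, {
    pos <- sample(0:999, 1000, replace = TRUE)
    rs2 <- reads_at("chr1", "+", pos5 = pos)
    tr2 <- coverage(rs2, c(chr1 = 1000), bin = 10)
    expect_equal(sum(unlist(tr2$bins)), 1000)
    # bin size 1 equals a per-base histogram
    tr1 <- coverage(rs2, c(chr1 = 1000), bin = 1)
    expect_equal(tr1$bins[["chr1|+"]], tabulate(pos + 1, nbins = 1000))
  })
  expect_error(coverage(reads_at("chr1", "+", 150), c(chr1 = 100)),
               "beyond chromosome end")
})

test_that("peak significance follows the Poisson tail and FE cutoffs", {
  # uniform control of 2 per bin so every lambda component equals 2
  mk <- function(v, total) {
    structure(list(bins = list(`chr1|+` = v), bin_size = 10, total = total,
                   chrom_sizes = c(chr1 = 10 * length(v))),
              class = "CoverageTrack")
  }
  ctrl <- mk(rep(2, 200), 400)
  # direct-summation oracle for the Poisson upper tail
  tail_p <- function(k, lam) 1 - sum(exp(-lam) * lam^(0:(k - 1)) /
                                       factorial(0:(k - 1)))
  expect_equal(ppois(8 - 1, 2, lower.tail = FALSE), tail_p(8, 2),
               tolerance = 1e-12)
  expect_lt(tail_p(8, 2), 0.0015)

  treat <- mk(rep(2, 200), 400); treat$bins[["chr1|+"]][50] <- 8
  pk <- call_peaks(treat, ctrl)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$fold_enrichment, 4, tolerance = 1e-9)
  expect_equal(pk$p_value, tail_p(8, 2), tolerance = 1e-9)
  expect_equal(pk$summit, 495)

  # FE 1.5 < 2 is never a peak regardless of p
  treat2 <- mk(rep(2, 200), 400); treat2$bins[["chr1|+"]][50] <- 3
  expect_equal(nrow(call_peaks(treat2, ctrl, p_cutoff = 1)), 0)

  # identical tracks: FE = 1 everywhere, empty set
  expect_equal(nrow(call_peaks(ctrl, ctrl)), 0)

  expect_error(call_peaks(mk(rep(1, 10), 10),
                          structure(list(bins = list(), bin_size = 5,
                                         total = 10, chrom_sizes = c(chr1 = 50)),
                                    class = "CoverageTrack")),
               "bin sizes")
})

test_that("calling equals an exhaustive per-bin brute-force evaluation", {
  withr::with_seed(19, {
    for (rep_i in 1:5) {
      nb <- 400
      cv <- rpois(nb, rep(c(0, 8, 0, 15, 2), each = 80))
      tv <- rpois(nb, rep(c(0, 8, 0, 15, 2), each = 80)) +
        rbinom(nb, 1, 0.02) * rpois(nb, 40)
      mk <- function(v) structure(
        list(bins = list(`chr1|+` = v), bin_size = 10, total = sum(v) + 1,
             chrom_sizes = c(chr1 = 10 * nb)), class = "CoverageTrack")
      treat <- mk(tv); ctrl <- mk(cv)
      oracle <- brute_eval_bins(treat, ctrl, "chr1|+")
      pk <- call_peaks(treat, ctrl)
      sig_bins <- sort(unique(unlist(lapply(seq_len(nrow(pk)), function(i)
        which(oracle$sig & seq_len(nb) >= pk$start[i] / 10 + 1 &
                seq_len(nb) <= pk$end[i] / 10)))))
      expect_identical(which(oracle$sig), sig_bins)
      # every significant bin lies inside a called peak and vice versa
      for (b in which(oracle$sig))
        expect_true(any(pk$start <= (b - 1) * 10 & pk$end >= b * 10))
      fr <- significant_bin_fraction(treat, ctrl)
      expect_equal(fr$n_significant, sum(oracle$sig))
    }
  })
})

test_that("relaxing cutoffs never loses a called peak", {
  withr::with_seed(23, {
    nb <- 300
    cv <- rpois(nb, 5)
    tv <- rpois(nb, 5) + rbinom(nb, 1, 0.05) * rpois(nb, 25)
    mk <- function(v) structure(
      list(bins = list(`chr1|+` = v), bin_size = 10, total = sum(v) + 1,
           chrom_sizes = c(chr1 = 10 * nb)), class = "CoverageTrack")
    strict <- call_peaks(mk(tv), mk(cv), p_cutoff = 0.01, fe_cutoff = 3)
    loose <- call_peaks(mk(tv), mk(cv), p_cutoff = 0.05, fe_cutoff = 2)
    for (i in seq_len(nrow(strict))) {
      expect_true(any(loose$start <= strict$start[i] &
                        loose$end >= strict$end[i]))
    }
  })
})

test_that("peak annotation applies the feature precedence rule", {
  # two isoforms: summit 350 is CDS of iso1 but 5'UTR of iso2 -> utr5 wins
  iso1 <- transcript_model("iso1", "gA", "chr1", "+", cbind(100, 1100),
                           cds_start = 300, cds_end = 900)
  iso2 <- transcript_model("iso2", "gB", "chr1", "+", cbind(300, 1300),
                           cds_start = 500, cds_end = 1100)
  iso3 <- transcript_model("iso3", "gD", "chr1", "+",
                           rbind(c(1500, 1600), c(1700, 1800)),
                           cds_start = 1520, cds_end = 1780)
  cat_ <- transcript_catalog(list(iso1, iso2, iso3), c(chr1 = 50000))
  mkpk <- function(summits) {
    structure(data.table::data.table(
      chrom = "chr1", strand = "+", start = summits - 5, end = summits + 5,
      summit = summits, fold_enrichment = 3, p_value = 1e-4, q_value = 1e-3,
      treatment_count = 30, control_lambda = 10),
      class = c("PeakSet", "data.table", "data.frame"))
  }
  # 350: CDS of iso1 but 5'UTR of iso2 -> utr5; 650: CDS of both isoforms
  # (3'UTR of neither) -> cds; 1650: intron of iso3; 20000: nothing near
  anno <- annotate_peaks(mkpk(c(350, 650, 1650, 20000)), cat_)
  expect_equal(anno$feature, c("utr5", "cds", "intron", "intergenic"))
  # 500 nt upstream of a plus-strand TSS
  far <- transcript_model("far", "gC", "chr1", "+", cbind(30000, 31000),
                          cds_start = 30200, cds_end = 30800)
  cat2 <- transcript_catalog(list(far), c(chr1 = 50000))
  anno2 <- annotate_peaks(mkpk(c(29500, 27000)), cat2)
  expect_equal(anno2$feature, c("upstream", "intergenic"))
  # repeat co-labelling
  reps <- data.frame(chrom = "chr1", start = 29400, end = 29600,
                     class = "LTR/ERVL-MaLR")
  anno3 <- annotate_peaks(mkpk(29500), cat2, repeats = reps)
  expect_equal(anno3$repeat_class, "LTR/ERVL-MaLR")
})

test_that("narrowPeak and bedGraph writers emit well-formed text", {
  rs <- reads_at("chr1", "+", pos5 = c(25, 26, 27, 500))
  tr <- coverage(rs, c(chr1 = 1000), bin = 10)
  paths <- write_bedgraph(tr, tempfile())
  bg <- read.table(paths[1], sep = "\t")
  expect_equal(sum(bg$V4), 4)
  mkpk <- structure(data.table::data.table(
    chrom = "chr1", strand = "+", start = 20, end = 30, summit = 25,
    fold_enrichment = 3.5, p_value = 1e-6, q_value = 1e-4,
    treatment_count = 30, control_lambda = 8.5),
    class = c("PeakSet", "data.table", "data.frame"))
  np <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(mkpk, np)
  row <- read.table(np, sep = "\t")
  expect_equal(ncol(row), 10)
  expect_equal(row$V10, 5)   # summit offset from start
})
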