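mk_track <- function(v, strand = "+", bin = 10, total = sum(v),
                     chrom = "chr1") {
  structure(list(bins = setNames(list(v), paste(chrom, strand, sep = "|")),
                 bin_size = bin, total = total,
                 chrom_sizes = setNames(bin * length(v), chrom)),
            class = "CoverageTrack")
}

test_that("metaprofile is flat on uniform signal and peaked on a delta", {
  v <- rep(5, 500)
  tr <- mk_track(v, total = sum(v))
  anchors <- data.frame(chrom = "chr1", pos = c(1000, 2000, 3000),
                        strand = "+")
  mp <- metaprofile(tr, anchors, w = 200)
  expect_equal(length(mp$profile), 40)
  expect_true(all(abs(mp$profile - 5 * 1e7 / sum(v)) < 1e-9))

  v2 <- rep(0, 500); v2[101] <- 10
  tr2 <- mk_track(v2, total = 10)
  mp2 <- metaprofile(tr2, data.frame(chrom = "chr1", pos = 1005,
                                     strand = "+"), w = 100)
  expect_equal(which(mp2$profile > 0), 11)  # the anchor bin (first of right half)
  expect_equal(max(mp2$profile), 10 * 1e7 / 10)
})

test_that("metaprofile is linear: pooled anchors equal the mean of singles", {
  withr::with_seed(31, {
    v <- rpois(1000, 4)
    tr <- mk_track(v, total = sum(v))
    anchors <- data.frame(chrom = "chr1", pos = sample(2000:8000, 6),
                          strand = "+")
    pooled <- metaprofile(tr, anchors, w = 300)$profile
    singles <- sapply(seq_len(nrow(anchors)), function(i)
      metaprofile(tr, anchors[i, ], w = 300)$profile)
    expect_equal(pooled, rowMeans(singles), tolerance = 1e-12)
  })
})

test_that("minus-strand anchors reverse the bin axis to 5'->3'", {
  v <- rep(0, 500); v[60] <- 8   # genomic bin 60, left of the anchor
  tr <- mk_track(v, strand = "-", total = 8)
  mp <- metaprofile(tr, data.frame(chrom = "chr1", pos = 645, strand = "-"),
                    w = 100)
  # on the minus strand, genomically-left signal is downstream (right half)
  expect_gt(which(mp$profile > 0), 10)
})

test_that("peak matrix rows sort by mean and columns match the profile", {
  withr::with_seed(37, {
    v <- rpois(2000, 3); v[500] <- 60; v[1200] <- 90
    tr <- mk_track(v, total = sum(v))
    pk <- structure(data.table::data.table(
      chrom = "chr1", strand = "+",
      start = c(4990, 11990), end = c(5000, 12000),
      summit = c(4995, 11995), fold_enrichment = c(5, 9),
      p_value = 1e-9, q_value = 1e-6, treatment_count = c(60, 90),
      control_lambda = 3), class = c("PeakSet", "data.table", "data.frame"))
    mat <- peak_matrix(tr, pk, w = 200)
    expect_equal(nrow(mat), 2)
    expect_gt(mean(mat[1, ]), mean(mat[2, ]))   # 90-peak row first
    mp <- metaprofile(tr, data.frame(chrom = pk$chrom,
                                     pos = floor((pk$start + pk$end) / 2),
                                     strand = pk$strand), w = 200)
    expect_equal(unname(colMeans(mat, na.rm = TRUE)), unname(mp$profile),
                 tolerance = 1e-12)
  })
})

test_that("region RPKM follows the formula and brute-force counting", {
  # 10 reads in a 500 nt 5'UTR with 1e6 total mapped -> RPKM 20
  m <- transcript_model("t1", "g1", "chr1", "+", cbind(0, 2000),
                        cds_start = 500, cds_end = 1500)
  cat_ <- transcript_catalog(list(m), c(chr1 = 5000))
  rs <- read_end_set(data.table::data.table(
    chrom = "chr1", strand = "+", pos5 = seq(10, 460, by = 50), length = 30),
    total = 1e6)
  dt <- region_density(rs, cat_)
  expect_equal(dt[dt$region == "utr5"]$rpkm, 10 * 1e9 / (500 * 1e6))
  expect_equal(dt[dt$region == "utr5"]$rpkm, 20)
  expect_equal(dt[dt$region == "cds"]$reads, 0)
  expect_equal(dt[dt$region == "cds"]$rpkm, 0)

  withr::with_seed(41, {
    ms <- lapply(1:20, function(k) random_model(sprintf("q%d", k)))
    cat2 <- transcript_catalog(ms, c(chr1 = 50000))
    rs2 <- reads_at("chr1", sample(c("+", "-"), 400, replace = TRUE),
                    pos5 = sample(0:4000, 400, replace = TRUE))
    dt2 <- region_density(rs2, cat2)
    oracle <- brute_region_counts(rs2, cat2)
    for (id in names(oracle)) {
      got <- dt2[dt2$transcript_id == id]
      for (rg in c("utr5", "cds", "utr3", "full")) {
        expect_equal(got[got$region == rg]$reads, unname(oracle[[id]][rg]))
        len <- got[got$region == rg]$length
        expect_equal(got[got$region == rg]$rpkm,
                     unname(oracle[[id]][rg]) * 1e9 / (len * rs2$total),
                     tolerance = 1e-9)
      }
      # conservation: region counts sum to the exonic total
      expect_equal(sum(got[got$region != "full"]$reads),
                   got[got$region == "full"]$reads)
    }
  })
})

test_that("PQS scanning matches the canonical pattern greedily", {
  hits <- scan_pqs("GGGAGGGAGGGAGGG")
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$start, hits$end), c(0, 15))
  expect_equal(hits$loops, "1,1,1")
  expect_equal(nrow(scan_pqs("ACACACAC")), 0)
  # U/T equivalence
  expect_equal(nrow(scan_pqs("GGGUGGGUGGGUGGG")), 1)
  # five tracts: exactly one greedy match, leftmost-anchored
  s5 <- "GGGAGGGAGGGAGGGAGGG"
  h5 <- scan_pqs(s5)
  expect_equal(nrow(h5), 1)
  expect_equal(h5$start, 0)
  # exhaustive window oracle: the leftmost matching start is 0
  starts <- which(vapply(seq_len(nchar(s5)), function(i)
    grepl("^G{3,}([ACTN]{1,7}G{3,}){3}", substr(s5, i, nchar(s5))),
    TRUE)) - 1
  expect_equal(min(starts), h5$start)
  # two separated sites are both found
  s2 <- paste0("GGGAGGGAGGGAGGG", strrep("ACT", 10), "GGGTTGGGTTGGGTTGGG")
  expect_equal(nrow(scan_pqs(s2)), 2)
})

test_that("peak sequences extend 30 nt to the strand-aware 5' side", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("A", "C", "G", "T"), 100), collapse = "")))
  pk <- structure(data.table::data.table(
    chrom = "chr1", strand = c("+", "-"), start = c(100, 100),
    end = c(150, 150), summit = c(120, 120), fold_enrichment = 3,
    p_value = 1e-5, q_value = 1e-4, treatment_count = 10, control_lambda = 2),
    class = c("PeakSet", "data.table", "data.frame"))
  seqs <- peak_upstream_sequences(pk, genome, ext = 30)
  g <- as.character(genome[[1]])
  expect_equal(unname(seqs[1]), substr(g, 71, 150))       # [70, 150) extended left
  expect_equal(unname(seqs[2]), as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(
      substr(g, 101, 180)))))                             # [100, 180) revcomp
})

test_that("k-mer enrichment recovers G-rich motifs from planted PQS", {
  withr::with_seed(43, {
    fg <- vapply(1:40, function(i) paste0(
      paste(sample(c("A", "C", "T"), 10, replace = TRUE), collapse = ""),
      "GGGAGGGAGGGAGGG",
      paste(sample(c("A", "C", "T"), 10, replace = TRUE), collapse = "")), "")
    bg <- vapply(fg, function(s) paste(sample(strsplit(s, "")[[1]]),
                                       collapse = ""), "")
    enr <- g_enrichment(fg, bg)
    top <- enr$kmer[1]
    expect_gte(sum(strsplit(top, "")[[1]] == "G"), 4)
    expect_gt(enr$log2_enrichment[1], 1)
  })
})
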