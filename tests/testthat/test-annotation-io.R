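test_that("BED12 ingestion derives UTR/CDS lengths on both strands", {
  lines <- c(
    "chr1\t100\t1100\ttxp\t0\t+\t300\t900\t0\t1\t1000,\t0,",
    "chr1\t100\t1100\ttxm\t0\t-\t300\t900\t0\t1\t1000,\t0,"
  )
  path <- write_lines_tmp(lines, ".bed")
  cat_ <- load_transcripts(path, "bed12", chrom_sizes = c(chr1 = 10000))
  p <- cat_$transcripts$txp
  expect_equal(c(p$utr5_len, p$cds_len, p$utr3_len), c(200, 600, 200))
  m <- cat_$transcripts$txm
  expect_equal(c(m$utr5_len, m$cds_len, m$utr3_len), c(200, 600, 200))
  # on the minus strand the 5'UTR occupies the genomic [900, 1100) side
  expect_identical(transcript_region(m, genomic_to_transcript(m, 950)), "utr5")
  expect_identical(transcript_region(m, genomic_to_transcript(m, 250)), "utr3")
})

test_that("GTF ingestion matches a per-base labelling oracle", {
  lines <- c(
    "chr1\tsrc\texon\t1\t50\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
    "chr1\tsrc\texon\t101\t150\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
    "chr1\tsrc\tCDS\t121\t140\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";"
  )
  path <- write_lines_tmp(lines, ".gtf")
  cat_ <- load_transcripts(path, "gtf", chrom_sizes = c(chr1 = 10000))
  m <- cat_$transcripts$t1
  # oracle: label every exonic base by comparing with the CDS genomic span
  exonic <- c(0:49, 100:149)
  lab <- ifelse(exonic < 120, "utr5", ifelse(exonic < 140, "cds", "utr3"))
  expect_equal(m$mature_length, length(exonic))
  expect_equal(m$utr5_len, sum(lab == "utr5"))
  expect_equal(m$cds_len, sum(lab == "cds"))
  expect_equal(m$utr3_len, sum(lab == "utr3"))
  expect_equal(unname(c(m$utr5_len, m$cds_len, m$utr3_len)), c(70, 20, 10))
})

test_that("malformed records error with a line number; bad CDS is rejected", {
  bad <- write_lines_tmp(c("chr1\t100\t1100\ttx\t0\t+\t300\t900\t0\t1\t1000,\t0,",
                           "chr1\tonly\tthree"), ".bed")
  expect_error(load_transcripts(bad, "bed12", chrom_sizes = c(chr1 = 1e4)),
               "line 2")
  # CDS outside the exon: record dropped with a warning, others kept
  mix <- write_lines_tmp(c(
    "chr1\t100\t1100\tok\t0\t+\t300\t900\t0\t1\t1000,\t0,",
    "chr1\t100\t1100\tbadcds\t0\t+\t1200\t1400\t0\t1\t1000,\t0,"
  ), ".bed")
  expect_warning(cat_ <- load_transcripts(mix, "bed12",
                                          chrom_sizes = c(chr1 = 1e4)),
                 "rejected")
  expect_identical(names(cat_$transcripts), "ok")
})

test_that("genomic_to_transcript handles strands, introns and misses", {
  mp <- transcript_model("t", "g", "chr1", "+", cbind(100, 200))
  expect_equal(genomic_to_transcript(mp, 100), 0)
  mm <- transcript_model("t", "g", "chr1", "-", cbind(100, 200))
  expect_equal(genomic_to_transcript(mm, 199), 0)
  ms <- split_model("+")
  # per-base walk oracle: 110 is the 11th base of the second exon
  expect_equal(genomic_to_transcript(ms, 110), 60)
  expect_true(is.na(genomic_to_transcript(ms, 75)))   # intronic
  expect_true(is.na(genomic_to_transcript(ms, 500)))  # outside
})

test_that("exonic coordinates map bijectively onto [0, mature length)", {
  withr::with_seed(42, {
    for (k in 1:20) {
      m <- random_model(sprintf("r%d", k))
      gpos <- unlist(lapply(seq_len(nrow(m$exons)), function(i)
        seq(m$exons[i, 1], m$exons[i, 2] - 1)))
      tp <- genomic_to_transcript(m, gpos)
      expect_setequal(tp, 0:(m$mature_length - 1))
      expect_equal(transcript_to_genomic(m, tp), gpos)
      # region lengths always partition the mature transcript
      expect_equal(m$utr5_len + m$cds_len + m$utr3_len, m$mature_length)
    }
  })
})

test_that("read ingestion honours the 5'-end convention per dialect", {
  bed <- write_lines_tmp(c("chr1\t100\t130\tr1\t0\t+",
                           "chr1\t100\t130\tr2\t0\t-",
                           "chr1\t200\t230\tr3\t0\t."), ".bed")
  rs <- read_read_ends(bed, "bed6")
  expect_equal(nrow(rs$reads), 2)
  expect_equal(rs$n_skipped, 1L)
  expect_equal(rs$total, 3)
  expect_equal(rs$reads$pos5, c(100, 129))
  expect_equal(rs$reads$length, c(30, 30))

  sam <- write_lines_tmp(c(
    "@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000",
    "r1\t0\tchr1\t101\t255\t30M\t*\t0\t0\t*\t*",
    "r2\t16\tchr1\t101\t255\t10M5N20M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), ".sam")
  ss <- read_read_ends(sam, "sam")
  expect_equal(nrow(ss$reads), 2)
  expect_equal(ss$n_skipped, 1L)
  expect_equal(ss$reads$pos5, c(100, 100 + 35 - 1))
  expect_equal(ss$reads$strand, c("+", "-"))
})

test_that("BED6 write/read round trip is coordinate-exact", {
  withr::with_seed(7, {
    rs <- reads_at("chr1", sample(c("+", "-"), 50, replace = TRUE),
                   pos5 = sample(100:5000, 50),
                   length = sample(20:60, 50, replace = TRUE))
    path <- tempfile(fileext = ".bed")
    write_bed(rs, path)
    back <- read_read_ends(path, "bed6")
    expect_equal(back$reads$pos5, rs$reads$pos5)
    expect_equal(back$reads$length, rs$reads$length)
    expect_equal(back$reads$strand, rs$reads$strand)
  })
})

test_that("BED12 writer round-trips through the loader", {
  withr::with_seed(11, {
    ms <- lapply(1:8, function(k) random_model(sprintf("w%d", k)))
    cat0 <- transcript_catalog(ms, c(chr1 = 50000))
    path <- tempfile(fileext = ".bed")
    write_bed12(cat0, path)
    cat1 <- load_transcripts(path, "bed12", chrom_sizes = c(chr1 = 50000))
    for (id in names(cat0$transcripts)) {
      expect_equal(cat1$transcripts[[id]]$exons, cat0$transcripts[[id]]$exons)
      expect_equal(cat1$transcripts[[id]]$cds_start,
                   cat0$transcripts[[id]]$cds_start)
      expect_equal(cat1$transcripts[[id]]$utr5_len,
                   cat0$transcripts[[id]]$utr5_len)
    }
  })
})

test_that("longest CDS isoform is selected per gene", {
  m1 <- transcript_model("a1", "gA", "chr1", "+", cbind(0, 300),
                         cds_start = 50, cds_end = 250)
  m2 <- transcript_model("a2", "gA", "chr1", "+", cbind(0, 400),
                         cds_start = 50, cds_end = 150)
  kept <- longest_cds_isoform(transcript_catalog(list(m1, m2)))
  expect_identical(names(kept$transcripts), "a1")
})
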