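small_cfg <- function(seed = 5, ...) {
  defaults <- list(seed = seed, n_transcripts = 10, n_sites = 8,
                   lace_depth = 2e4, expr_depth = 1e5)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

test_that("zero planting probability yields a PQS-free transcriptome", {
  cfg <- small_cfg(n_sites = 0)
  sim <- simulate_transcriptome(cfg)
  expect_equal(nrow(sim$truth$sites), 0)
  for (m in sim$catalog$transcripts) {
    expect_equal(nrow(scan_pqs(mature_sequence(m, sim$genome))), 0)
  }
})

test_that("planted sites carry a canonical PQS at the truth coordinates", {
  cfg <- sim_config(seed = 9, n_transcripts = 1, n_sites = 1,
                    site_region_weights = c(utr5 = 1, cds = 0, utr3 = 0,
                                            upstream = 0),
                    lace_depth = 1e4)
  sim <- simulate_transcriptome(cfg)
  st <- sim$truth$sites
  expect_equal(nrow(st), 1)
  expect_identical(st$region, "utr5")
  m <- sim$catalog$transcripts[[st$transcript_id]]
  seqc <- mature_sequence(m, sim$genome)
  sub <- substr(seqc, st$tpos + 1, st$tpos + (st$gend - st$gstart))
  expect_true(grepl("^G{3,}([ACTN]{1,7}G{3,}){3}$", sub))
  # and scan_pqs locates exactly this site
  hits <- scan_pqs(seqc)
  expect_equal(hits$start, st$tpos)
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- small_cfg()
  s1 <- simulate_transcriptome(cfg)
  s2 <- simulate_transcriptome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$sites, s2$truth$sites)
  expect_identical(s1$truth$transcripts, s2$truth$transcripts)
  r1 <- simulate_lace_reads(s1, cfg, "GV", "BG4")
  r2 <- simulate_lace_reads(s2, cfg, "GV", "BG4")
  expect_identical(r1$reads, r2$reads)
  e1 <- simulate_expression(s1, cfg, "MII_DMSO")
  e2 <- simulate_expression(s2, cfg, "MII_DMSO")
  expect_identical(e1$mrna, e2$mrna)
})

test_that("site-bin read counts follow the closed-form enrichment mean", {
  # expected count in the 10 nt stop bin: mu*10 (background) + mu*10*50*f,
  # averaged over many seeds; dup_rate 0 so records = unique reads
  tot_obs <- 0; tot_exp <- 0
  for (seed in 1:100) {
    cfg <- sim_config(seed = seed, n_transcripts = 1, n_sites = 1,
                      site_region_weights = c(utr5 = 0, cds = 1, utr3 = 0,
                                              upstream = 0),
                      lace_depth = 1500, dup_rate = 0, abundance_sdlog = 0,
                      stop_jitter = 0)
    sim <- simulate_transcriptome(cfg)
    st <- sim$truth$sites
    if (nrow(st) != 1) next
    tt <- sim$truth$transcripts
    mu <- cfg$lace_depth * tt$abundance / (tt$abundance * tt$mature_length)
    bg4 <- simulate_lace_reads(sim, cfg, "GV", "BG4")
    b0 <- floor(st$stop_gpos / 10) * 10
    inbin <- bg4$reads[chrom == st$chrom & pos5 >= b0 & pos5 < b0 + 10]
    tot_obs <- tot_obs + nrow(inbin)
    tot_exp <- tot_exp + mu * 10 + mu * 10 * cfg$lambda_fold * 1
  }
  expect_gt(tot_exp, 0)
  expect_lt(abs(tot_obs / tot_exp - 1), 0.05)
})

test_that("PCR duplication expands records and deduplication restores them", {
  withr::with_seed(3, {
    rs <- reads_at("chr1", "+", pos5 = sample(1:100000, 1000),
                   length = 30)
    dup <- add_pcr_duplicates(rs, 0.5)
    expect_gt(nrow(dup$reads), 1400)
    expect_lt(nrow(dup$reads), 1600)
    dd <- deduplicate(dup)
    expect_equal(nrow(dd$reads), 1000)
  })
})

test_that("TE suppression follows the stated log-linear model", {
  # alpha = beta = 0: true TE identical across conditions
  cfg0 <- small_cfg(te_alpha = 0, te_beta = 0)
  sim0 <- simulate_transcriptome(cfg0)
  tt <- sim0$truth$transcripts
  expect_equal(tt$tau_GV, tt$tau_MII_DMSO)
  expect_equal(tt$tau_GV, tt$tau_MII_BYBX)

  # one 5'UTR site, f 1 -> 0, alpha = 1: true TE doubles
  cfg1 <- sim_config(seed = 21, n_transcripts = 1, n_sites = 1,
                     site_region_weights = c(utr5 = 1, cds = 0, utr3 = 0,
                                             upstream = 0),
                     foldedness = c(GV = 1, MII = 0),
                     te_alpha = 1, te_beta = 0, lace_depth = 1e4)
  sim1 <- simulate_transcriptome(cfg1)
  expect_equal(nrow(sim1$truth$sites), 1)
  tt1 <- sim1$truth$transcripts
  expect_equal(tt1$tau_MII / tt1$tau_GV, 2)
})

test_that("null TE model yields all-unchanged fold-change classes", {
  cfg <- sim_config(seed = 13, n_transcripts = 40, n_sites = 20,
                    te_alpha = 0, te_beta = 0,
                    lace_depth = 1e4, expr_depth = 1e6)
  sim <- simulate_transcriptome(cfg)
  ed <- simulate_expression(sim, cfg, "MII_DMSO")
  eb <- simulate_expression(sim, cfg, "MII_BYBX")
  te <- translational_efficiency(
    fpkm(cbind(d = ed$rpf, b = eb$rpf), ed$cds_lengths),
    fpkm(cbind(d = ed$mrna, b = eb$mrna), ed$tx_lengths))
  cls <- fold_change_classes(te$te[, "d"], te$te[, "b"])
  expect_true(all(cls == "unchanged"))
})

test_that("RBP intensity tables realize the planted classes", {
  cfg <- small_cfg()
  tab <- simulate_rbp_intensities(cfg)
  expect_equal(nrow(tab), sum(cfg$rbp_classes))
  blocked <- tab[tab$true_class == "blocked"]
  expect_true(all(blocked$IP_bybx == 0 & blocked$IP_mock > 0 &
                    blocked$input > 0))
  absent <- tab[tab$true_class == "input_absent"]
  expect_true(all(absent$input == 0))
  cls <- classify_rbp_binding(tab)
  expect_true(all(cls$class[tab$true_class == "input_absent"] == "excluded"))
  # 20 planted down-regulated proteins recovered almost completely
  planted_down <- tab$true_class == "down"
  expect_gte(sum(cls$class[planted_down] == "down"), 18)
})

test_that("simulation artifacts are written as plain text", {
  cfg <- small_cfg()
  sim <- simulate_transcriptome(cfg)
  dir <- tempfile()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "transcripts.bed12", "chrom.sizes",
    "truth_sites.tsv", "truth_transcripts.tsv", "config.json")))))
  # catalog round trip through the written BED12
  cat1 <- load_transcripts(file.path(dir, "transcripts.bed12"), "bed12",
                           chrom_sizes = file.path(dir, "chrom.sizes"))
  expect_setequal(names(cat1$transcripts), names(sim$catalog$transcripts))
})
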