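# Synthetic transcriptome and library generator with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a toy genome whose transcripts carry planted canonical PQS
# (putative quadruplex sequence) sites with condition-dependent foldedness,
# stranded read-5'-end libraries where the treatment (BG4) piles reads at the
# RT-stop point of each folded site on top of a uniform background, mRNA/RPF
# count tables where translational efficiency is suppressed by UTR rG4 load,
# ERCC-like spike-in rows with a per-sample nuisance depth factor, and RBP
# intensity tables with planted binding-loss classes.

string_seed <- function(tag) {
  sum(utf8ToInt(tag) * (seq_along(utf8ToInt(tag)) %% 7 + 1)) %% 99991L
}

derived_seed <- function(cfg, tag) {
  (as.integer(cfg$seed) %% 20000L) * 100000L + string_seed(tag)
}

rcounts <- function(n, mu, dispersion = 0) {
  if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
  else rpois(n, mu)
}

#' Simulation configuration
#'
#' All tunables of the synthetic-data generator in one validated record.
#' Defaults describe the study conditions the package's recovery tests run
#' under: 50 planted sites allocated with a 5'UTR-enriched weighting, a
#' 50-fold RT-stop enrichment of folded sites over background, half a
#' million background read ends per library, and site foldedness that is
#' high at the GV stage, largely removed at MII under vehicle (DMSO), and
#' re-raised at MII under the stabilizing ligand (BYBX).
#'
#' @param seed mandatory integer seed; every generator draw derives from it.
#' @param n_transcripts number of transcripts (one per toy chromosome).
#' @param utr5_len,cds_len,utr3_len mean region lengths in nt; each
#'   transcript draws its lengths uniformly in 0.5-1.5x the mean.
#' @param exon_range integer range for the exon count per transcript.
#' @param intron_range intron length range in nt.
#' @param pad intergenic pad on both sides of each transcript span (nt);
#'   hosts the upstream (TSS-proximal) planting region.
#' @param n_sites total planted PQS sites.
#' @param site_region_weights allocation weights over
#'   `c(utr5, cds, utr3, upstream)`; 5'UTR-enriched by default so that the
#'   per-kilobase site density is highest in 5'UTRs.
#' @param foldedness named per-condition foldedness f in \[0,1\] applied to
#'   every planted site; names define the conditions.
#' @param lace_depth expected background read ends per RT-stop library.
#' @param lambda_fold RT-stop enrichment multiplier of a fully folded site
#'   over local background.
#' @param site_scale_nt nt of local background the enrichment multiplier
#'   references (the expected extra reads at a stop are
#'   `per-base background x site_scale_nt x lambda_fold x f`).
#' @param stop_offset offset (nt, transcript 5'->3') added to the RT-stop
#'   point; 0 places the read pile at the base immediately 3' of the site.
#' @param stop_jitter positional jitter of RT stops in nt: each site read
#'   lands uniformly within +/- this many bases of the stop point,
#'   emulating polymerase slippage around a single-nucleotide-resolution
#'   stop. Jitter spreads the stop pile over several bases so that
#'   deduplication (whose key includes the position) retains the site's
#'   dynamic range.
#' @param dup_rate PCR duplication rate: each unique record gains one extra
#'   copy with this probability.
#' @param read_len_range range the simulated read length is drawn uniformly
#'   from (nt). Variable lengths emulate the variable fragmentation 3' ends
#'   of real libraries; because the deduplication key includes the length,
#'   the range also sets how many stacked RT-stop records per base survive
#'   deduplication.
#' @param genome_bg_frac fraction of `lace_depth` spread uniformly over the
#'   whole genome (intergenic noise), in both libraries.
#' @param abundance_sdlog log-sd of per-transcript abundance.
#' @param expr_depth expected non-spike-in fragments per expression library.
#' @param te_alpha,te_beta TE suppression per unit of summed foldedness of
#'   5'UTR (`alpha`) and 3'UTR (`beta`) sites, in log2 units.
#' @param te_baseline_sd log2-sd of the per-transcript baseline TE.
#' @param spike_frac fraction of `expr_depth` allotted to spike-in species.
#' @param n_spikes number of spike-in species (2^k concentration ladder).
#' @param sf_sdlog log-sd of the per-sample nuisance depth factor that
#'   spike-in normalization must cancel.
#' @param dispersion negative-binomial over-dispersion for counts
#'   (0 = Poisson).
#' @param rbp_classes named integer allocation of RBPs over planted classes
#'   `down`, `up`, `blocked`, `unchanged`, `input_absent`.
#' @param rbp_noise_sd lognormal (sdlog) intensity noise for RBP tables.
#' @return validated list of class `SimulationConfig`.
#' @export
sim_config <- function(seed,
                       n_transcripts = 100,
                       utr5_len = 200, cds_len = 600, utr3_len = 400,
                       exon_range = c(1L, 3L),
                       intron_range = c(200L, 800L),
                       pad = 2500,
                       n_sites = 50,
                       site_region_weights = c(utr5 = 0.45, cds = 0.15,
                                               utr3 = 0.30, upstream = 0.10),
                       foldedness = c(GV = 1, MII_DMSO = 0.1, MII_BYBX = 0.9),
                       lace_depth = 5e5,
                       lambda_fold = 50,
                       site_scale_nt = 10,
                       stop_offset = 0,
                       stop_jitter = 2,
                       dup_rate = 0.1,
                       read_len_range = c(20L, 170L),
                       genome_bg_frac = 0.02,
                       abundance_sdlog = 0.5,
                       expr_depth = 1e6,
                       te_alpha = 2, te_beta = 1,
                       te_baseline_sd = 1,
                       spike_frac = 0.05,
                       n_spikes = 20,
                       sf_sdlog = 0.3,
                       dispersion = 0,
                       rbp_classes = c(down = 20, up = 10, blocked = 10,
                                       unchanged = 55, input_absent = 5),
                       rbp_noise_sd = 0.1) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  rates <- c(cfg$lace_depth, cfg$lambda_fold, cfg$expr_depth, cfg$n_sites,
             cfg$genome_bg_frac, cfg$dispersion, cfg$site_scale_nt)
  if (any(rates < 0)) stop("sim_config: rates must be >= 0")
  if (cfg$dup_rate < 0 || cfg$dup_rate > 1)
    stop("sim_config: dup_rate must be in [0,1]")
  if (any(cfg$foldedness < 0 | cfg$foldedness > 1))
    stop("sim_config: foldedness must be in [0,1]")
  if (is.null(names(cfg$foldedness)))
    stop("sim_config: foldedness must be named by condition")
  if (cfg$spike_frac <= 0 || cfg$spike_frac >= 1)
    stop("sim_config: spike_frac must be in (0,1)")
  if (any(cfg$site_region_weights < 0))
    stop("sim_config: site_region_weights must be >= 0")
  structure(cfg, class = "SimulationConfig")
}

# Random sequence free of G- and C-runs (>= 3), so that no unplanted PQS can
# arise on either strand.
rand_seq_vec <- function(n) {
  if (n <= 0) return(character(0))
  v <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  repeat {
    r <- rle(v)
    bad <- which(r$lengths >= 3 & r$values %in% c("G", "C"))
    if (!length(bad)) break
    ends <- cumsum(r$lengths)
    for (b in bad) {
      st <- ends[b] - r$lengths[b] + 1
      pos <- seq(st + 2, ends[b], by = 3)
      v[pos] <- sample(c("A", "T"), length(pos), replace = TRUE)
    }
  }
  v
}

# One canonical PQS: four G3 tracts, three loops of 1-7 nt drawn from A/C/T
# (C-runs broken so the complement stays G-run-free).
rand_pqs <- function() {
  loops <- lapply(sample(1:7, 3, replace = TRUE), function(l) {
    lp <- sample(c("A", "C", "T"), l, replace = TRUE)
    r <- rle(lp)
    if (any(r$lengths >= 3 & r$values == "C")) lp[3] <- "A"
    lp
  })
  c("G", "G", "G", loops[[1]], "G", "G", "G", loops[[2]],
    "G", "G", "G", loops[[3]], "G", "G", "G")
}

revcomp_chars <- function(v) {
  rev(c(A = "T", C = "G", G = "C", T = "A")[v])
}

#' Simulate a toy transcriptome with planted rG4 sites
#'
#' Builds one chromosome per transcript (intergenic pads on both sides),
#' draws region lengths and exon/intron structure, fills all sequence with
#' G-run-free background, and plants `n_sites` canonical PQS sites into
#' 5'UTR / CDS / 3'UTR / upstream regions according to the configured
#' weights. Sites that cannot be hosted (region too short, no free slot)
#' are skipped and counted. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list of class `SyntheticRg4Data` with elements `genome`
#'   (named `DNAStringSet`), `catalog` (a [transcript_catalog()]), and
#'   `truth` (list with `sites` and `transcripts` tables, per-condition
#'   foldedness and true TE, and the config echo).
#' @export
simulate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  withr::with_seed(derived_seed(cfg, "transcriptome"), {
    conds <- names(cfg$foldedness)
    n <- cfg$n_transcripts
    u5 <- pmax(40L, round(runif(n, 0.5, 1.5) * cfg$utr5_len))
    cd <- pmax(60L, round(runif(n, 0.5, 1.5) * cfg$cds_len))
    u3 <- pmax(40L, round(runif(n, 0.5, 1.5) * cfg$utr3_len))
    L <- u5 + cd + u3
    strand <- sample(c("+", "-"), n, replace = TRUE)
    abundance <- rlnorm(n, 0, cfg$abundance_sdlog)
    tau0 <- rnorm(n, 0, cfg$te_baseline_sd)

    txs <- vector("list", n)
    seqs <- vector("list", n)           # transcript sense sequence, char vec
    chrom_sizes <- numeric(n)
    exon_cuts <- vector("list", n)      # transcript-coordinate exon cut points
    for (i in seq_len(n)) {
      ne <- sample(seq(cfg$exon_range[1], cfg$exon_range[2]), 1)
      cuts <- if (ne > 1) sort(sample(seq(20, L[i] - 20), ne - 1)) else integer(0)
      seg <- diff(c(0, cuts, L[i]))     # exon lengths in transcript order
      introns <- if (ne > 1)
        sample(seq(cfg$intron_range[1], cfg$intron_range[2]), ne - 1,
               replace = TRUE) else integer(0)
      # genomic exon layout, left to right; transcript order follows strand
      seg_g <- if (strand[i] == "-") rev(seg) else seg
      gstart <- cfg$pad
      ex <- matrix(0, nrow = ne, ncol = 2)
      pos <- gstart
      for (k in seq_len(ne)) {
        ex[k, ] <- c(pos, pos + seg_g[k])
        pos <- ex[k, 2] + if (k < ne) introns[k] else 0
      }
      span_end <- ex[ne, 2]
      chrom <- sprintf("chrT%03d", i)
      chrom_sizes[i] <- span_end + cfg$pad
      tid <- sprintf("tx%03d", i)
      # CDS genomic span from transcript coordinates [u5, u5+cd)
      m0 <- structure(list(transcript_id = tid, chrom = chrom,
                           strand = strand[i], exons = ex,
                           mature_length = L[i]), class = "TranscriptModel")
      g_a <- transcript_to_genomic(m0, u5[i])
      g_b <- transcript_to_genomic(m0, u5[i] + cd[i] - 1)
      txs[[i]] <- transcript_model(tid, sprintf("gene%03d", i), chrom,
                                   strand[i], ex,
                                   cds_start = min(g_a, g_b),
                                   cds_end = max(g_a, g_b) + 1)
      seqs[[i]] <- rand_seq_vec(L[i])
      exon_cuts[[i]] <- c(0, cuts, L[i])
    }
    names(chrom_sizes) <- sprintf("chrT%03d", seq_len(n))
    catalog <- transcript_catalog(txs, chrom_sizes)

    # ---- site planting ----
    w <- cfg$site_region_weights / sum(cfg$site_region_weights)
    alloc <- if (cfg$n_sites > 0)
      as.vector(stats::rmultinom(1, cfg$n_sites, w)) else rep(0L, 4)
    names(alloc) <- names(w)
    occupied <- replicate(n, matrix(numeric(0), ncol = 2), simplify = FALSE)
    upstream_sites <- list()
    site_rows <- list()
    n_skipped <- 0L
    plant_one <- function(region) {
      pq <- rand_pqs()
      len <- length(pq)
      for (try_i in 1:25) {
        t <- sample.int(n, 1)
        model <- txs[[t]]
        bounds <- switch(region,
          utr5 = c(0, u5[t]), cds = c(u5[t], u5[t] + cd[t]),
          utr3 = c(u5[t] + cd[t], L[t]), upstream = NULL)
        if (region == "upstream") {
          # genomic window 30..2000 nt upstream of the TSS, same strand
          if (strand[t] == "+") {
            lo <- cfg$pad - 2000; hi <- cfg$pad - 30 - len
          } else {
            span_end <- max(model$exons[, 2])
            lo <- span_end + 30; hi <- span_end + 2000 - len
          }
          gs <- sample(seq(lo, hi), 1)
          clash <- any(vapply(upstream_sites, function(s)
            s$chrom == model$chrom && gs < s$gend + 60 && gs + len > s$gstart - 60,
            TRUE))
          if (clash) next
          stop_g <- if (strand[t] == "+") gs + len + cfg$stop_offset
                    else gs - 1 - cfg$stop_offset
          upstream_sites[[length(upstream_sites) + 1L]] <<- list(
            chrom = model$chrom, gstart = gs, gend = gs + len,
            strand = strand[t], pq = pq, tx = t, stop_gpos = stop_g)
          return(data.table(transcript_id = model$transcript_id,
                            region = "upstream", tpos = NA_real_,
                            chrom = model$chrom, gstart = gs, gend = gs + len,
                            stop_gpos = stop_g))
        }
        # site plus 1 nt non-G flank on each side inside one exon segment
        cuts <- exon_cuts[[t]]
        segs <- cbind(head(cuts, -1), tail(cuts, -1))
        segs[, 1] <- pmax(segs[, 1], bounds[1])
        segs[, 2] <- pmin(segs[, 2], bounds[2])
        segs <- segs[segs[, 2] - segs[, 1] >= len + 2, , drop = FALSE]
        if (!nrow(segs)) next
        k <- sample.int(nrow(segs), 1)
        ts <- sample(seq(segs[k, 1] + 1, segs[k, 2] - len - 1), 1)
        occ <- occupied[[t]]
        if (nrow(occ) && any(ts < occ[, 2] + 60 & ts + len > occ[, 1] - 60)) next
        occupied[[t]] <<- rbind(occ, c(ts, ts + len))
        s <- seqs[[t]]
        s[(ts + 1):(ts + len)] <- pq
        s[ts] <- sample(c("A", "T"), 1)
        s[ts + len + 1] <- sample(c("A", "T"), 1)
        seqs[[t]] <<- s
        g1 <- transcript_to_genomic(model, ts)
        g2 <- transcript_to_genomic(model, ts + len - 1)
        stop_t <- min(ts + len + cfg$stop_offset, L[t] - 1)
        return(data.table(transcript_id = model$transcript_id,
                          region = region, tpos = ts,
                          chrom = model$chrom,
                          gstart = min(g1, g2), gend = max(g1, g2) + 1,
                          stop_gpos = transcript_to_genomic(model, stop_t)))
      }
      NULL
    }
    for (region in names(alloc)) {
      for (s in seq_len(alloc[[region]])) {
        row <- plant_one(region)
        if (is.null(row)) {
          n_skipped <- n_skipped + 1L
          message("simulate_transcriptome: skipped one ", region,
                  " site (no room)")
        } else site_rows[[length(site_rows) + 1L]] <- row
      }
    }
    sites <- if (length(site_rows)) rbindlist(site_rows) else
      data.table(transcript_id = character(0), region = character(0),
                 tpos = numeric(0), chrom = character(0), gstart = numeric(0),
                 gend = numeric(0), stop_gpos = numeric(0))
    if (nrow(sites)) sites[, site_id := sprintf("site%03d", .I)]
    for (cond in conds)
      sites[, (paste0("f_", cond)) := rep(cfg$foldedness[[cond]], .N)]

    # ---- genome assembly ----
    genome <- lapply(seq_len(n), function(i) {
      v <- rand_seq_vec(chrom_sizes[i])
      model <- txs[[i]]
      tx_chars <- seqs[[i]]
      g_chars <- if (strand[i] == "-") revcomp_chars(tx_chars) else tx_chars
      off <- 0
      for (k in seq_len(nrow(model$exons))) {
        w_k <- model$exons[k, 2] - model$exons[k, 1]
        v[(model$exons[k, 1] + 1):model$exons[k, 2]] <-
          g_chars[(off + 1):(off + w_k)]
        off <- off + w_k
      }
      v
    })
    for (s in upstream_sites) {
      i <- s$tx
      pq_g <- if (s$strand == "-") revcomp_chars(s$pq) else s$pq
      genome[[i]][(s$gstart + 1):s$gend] <- pq_g
      genome[[i]][s$gstart] <- sample(c("A", "T"), 1)
      genome[[i]][s$gend + 1] <- sample(c("A", "T"), 1)
    }
    genome <- Biostrings::DNAStringSet(vapply(genome, paste, "", collapse = ""))
    names(genome) <- names(chrom_sizes)

    # ---- transcript truth incl. true TE per condition ----
    transcripts <- data.table(
      transcript_id = vapply(txs, `[[`, "", "transcript_id"),
      chrom = names(chrom_sizes), strand = strand,
      mature_length = L, cds_length = cd,
      abundance = abundance, tau0_log2 = tau0
    )
    for (cond in conds) {
      fcol <- paste0("f_", cond)
      load5 <- load3 <- numeric(n)
      if (nrow(sites)) {
        agg5 <- sites[region == "utr5", sum(get(fcol)), by = transcript_id]
        agg3 <- sites[region == "utr3", sum(get(fcol)), by = transcript_id]
        load5[match(agg5$transcript_id, transcripts$transcript_id)] <- agg5$V1
        load3[match(agg3$transcript_id, transcripts$transcript_id)] <- agg3$V1
      }
      transcripts[, (paste0("tau_", cond)) :=
        2^(tau0 - cfg$te_alpha * load5 - cfg$te_beta * load3)]
    }
    structure(list(genome = genome, catalog = catalog,
                   truth = list(sites = sites, transcripts = transcripts,
                                n_skipped_sites = n_skipped,
                                conditions = conds, config = unclass(cfg))),
              class = "SyntheticRg4Data")
  })
}

#' Append PCR duplicates to a read set
#'
#' Each record gains one extra identical copy with probability `rate`, so a
#' set of `u` unique records expands to about `u * (1 + rate)` records and
#' deduplication restores exactly the unique ones.
#'
#' @param reads a [read_end_set()].
#' @param rate duplication probability per record.
#' @return a [read_end_set()] with duplicates appended.
#' @export
add_pcr_duplicates <- function(reads, rate) {
  r <- reads$reads
  if (!nrow(r) || rate <= 0) return(reads)
  extra <- r[rbinom(nrow(r), 1, rate) == 1]
  out <- rbind(r, extra)
  read_end_set(out, total = nrow(out), library = reads$library,
               condition = reads$condition, n_skipped = reads$n_skipped)
}

#' Simulate an RT-stop read-end library
#'
#' Background read 5' ends fall uniformly over each transcript's exonic
#' positions at a rate proportional to its abundance; a small uniform
#' genomic background is added to both libraries. For the treatment library
#' (`BG4`) each planted site additionally receives Poisson-distributed reads
#' at its RT-stop point with expected count
#' `per-base background x site_scale_nt x lambda_fold x f`, where `f` is the
#' site's foldedness in `condition`. The control (`IgG`) has no site term.
#' PCR duplicates are appended at the configured rate. Deterministic given
#' the config seed, condition and library.
#'
#' @param sim a [simulate_transcriptome()] result.
#' @param cfg the [sim_config()] used to build `sim`.
#' @param condition condition name (must be one of the configured ones).
#' @param library `"BG4"` or `"IgG"`.
#' @return a [read_end_set()].
#' @export
simulate_lace_reads <- function(sim, cfg, condition, library = c("BG4", "IgG")) {
  library <- match.arg(library)
  if (!condition %in% names(cfg$foldedness))
    stop("condition ", condition, " has no configured foldedness")
  withr::with_seed(derived_seed(cfg, paste("lace", condition, library)), {
    txs <- sim$catalog$transcripts
    tt <- sim$truth$transcripts
    denom <- sum(tt$abundance * tt$mature_length)
    rl <- function(n) sample(seq(cfg$read_len_range[1], cfg$read_len_range[2]),
                             n, replace = TRUE)
    rows <- vector("list", length(txs) + 2)
    for (i in seq_along(txs)) {
      m <- txs[[i]]
      mu <- cfg$lace_depth * tt$abundance[i] / denom
      nb <- rpois(1, mu * m$mature_length)
      if (nb == 0) next
      tpos <- sample.int(m$mature_length, nb, replace = TRUE) - 1
      rows[[i]] <- data.table(chrom = m$chrom, strand = m$strand,
                              pos5 = transcript_to_genomic(m, tpos),
                              length = rl(nb))
    }
    # intergenic / nonspecific background, both libraries
    sizes <- sim$catalog$chrom_sizes
    maxlen <- cfg$read_len_range[2]
    nbg <- rpois(1, cfg$genome_bg_frac * cfg$lace_depth)
    if (nbg > 0) {
      ch <- sample(names(sizes), nbg, replace = TRUE, prob = sizes)
      pos <- floor(runif(nbg, maxlen, sizes[ch] - maxlen))
      rows[[length(txs) + 1]] <- data.table(
        chrom = ch, strand = sample(c("+", "-"), nbg, replace = TRUE),
        pos5 = pos, length = rl(nbg))
    }
    sites <- sim$truth$sites
    if (library == "BG4" && nrow(sites)) {
      fcol <- paste0("f_", condition)
      idx <- match(sites$transcript_id, tt$transcript_id)
      mu_site <- cfg$lace_depth * tt$abundance[idx] / denom *
        cfg$site_scale_nt * cfg$lambda_fold * sites[[fcol]]
      ns <- rpois(nrow(sites), mu_site)
      keep <- ns > 0
      if (any(keep)) {
        n_site_reads <- sum(ns[keep])
        j <- cfg$stop_jitter
        jit <- if (j > 0) sample(seq(-j, j), n_site_reads, replace = TRUE)
               else rep(0L, n_site_reads)
        chrom_site <- rep(sites$chrom[keep], ns[keep])
        pos_site <- rep(sites$stop_gpos[keep], ns[keep]) + jit
        pos_site <- pmax(0, pmin(pos_site, sizes[chrom_site] - 1))
        rows[[length(txs) + 2]] <- data.table(
          chrom = chrom_site,
          strand = rep(tt$strand[idx][keep], ns[keep]),
          pos5 = pos_site,
          length = rl(n_site_reads))
      }
    }
    r <- rbindlist(rows[!vapply(rows, is.null, TRUE)])
    out <- read_end_set(r, total = nrow(r), library = library,
                        condition = condition)
    add_pcr_duplicates(out, cfg$dup_rate)
  })
}

#' Simulate spike-in-bearing mRNA and RPF count tables
#'
#' mRNA counts are Poisson (or negative-binomial) with mean proportional to
#' abundance x mature length; RPF counts with mean proportional to
#' abundance x true TE x CDS length. The true TE is
#' `log2 tau = tau0 - alpha x sum(f, 5'UTR sites) - beta x sum(f, 3'UTR
#' sites)`. Twenty spike-in species follow a 2^k concentration ladder; every
#' count in a sample is multiplied by a lognormal nuisance depth factor that
#' spike-in normalization ([fpkm()]) must cancel.
#'
#' @param sim a [simulate_transcriptome()] result.
#' @param cfg the [sim_config()] used to build `sim`.
#' @param condition condition name.
#' @return list with `mrna` and `rpf` named count vectors (transcripts plus
#'   `ERCC-*` rows), `tx_lengths`, `cds_lengths`, and the nuisance factors
#'   `sf` actually applied.
#' @export
simulate_expression <- function(sim, cfg, condition) {
  if (!condition %in% names(cfg$foldedness))
    stop("condition ", condition, " has no configured foldedness")
  withr::with_seed(derived_seed(cfg, paste("expr", condition)), {
    tt <- sim$truth$transcripts
    tau <- tt[[paste0("tau_", condition)]]
    sf <- rlnorm(2, 0, cfg$sf_sdlog)           # mrna, rpf nuisance factors
    mu_m <- cfg$expr_depth * tt$abundance * tt$mature_length /
      sum(tt$abundance * tt$mature_length)
    mu_r <- cfg$expr_depth * tt$abundance * tau * tt$cds_length /
      sum(tt$abundance * tau * tt$cds_length)
    conc <- 2^(seq_len(cfg$n_spikes) - 1)
    spike_depth <- cfg$spike_frac / (1 - cfg$spike_frac) * cfg$expr_depth
    mu_s <- spike_depth * conc / sum(conc)
    ercc_ids <- sprintf("ERCC-%04d", seq_len(cfg$n_spikes))
    mrna <- c(setNames(rcounts(nrow(tt), sf[1] * mu_m, cfg$dispersion),
                       tt$transcript_id),
              setNames(rcounts(cfg$n_spikes, sf[1] * mu_s, cfg$dispersion),
                       ercc_ids))
    rpf <- c(setNames(rcounts(nrow(tt), sf[2] * mu_r, cfg$dispersion),
                      tt$transcript_id),
             setNames(rcounts(cfg$n_spikes, sf[2] * mu_s, cfg$dispersion),
                      ercc_ids))
    list(mrna = mrna, rpf = rpf,
         tx_lengths = setNames(tt$mature_length, tt$transcript_id),
         cds_lengths = setNames(tt$cds_length, tt$transcript_id),
         sf = setNames(sf, c("mrna", "rpf")), condition = condition)
  })
}

#' Simulate RBP intensity tables with planted binding-change classes
#'
#' Realizes the planted classes `down` (IP ratio well below 0.5), `up`
#' (well above 2), `blocked` (IP under treatment exactly 0), `unchanged`,
#' and `input_absent` (input 0, to be excluded downstream), with lognormal
#' intensity noise.
#'
#' @param cfg a [sim_config()].
#' @return `data.table` with columns `protein_id`, `input`, `IP_mock`,
#'   `IP_bybx`, `true_class`.
#' @export
simulate_rbp_intensities <- function(cfg) {
  withr::with_seed(derived_seed(cfg, "rbp"), {
    classes <- rep(names(cfg$rbp_classes), cfg$rbp_classes)
    nr <- length(classes)
    input <- rlnorm(nr, log(100), 1)
    ip_mock <- input * rlnorm(nr, 0, cfg$rbp_noise_sd)
    lfc <- numeric(nr)
    lfc[classes == "down"] <- runif(sum(classes == "down"), -3, -1.5)
    lfc[classes == "up"] <- runif(sum(classes == "up"), 1.5, 3)
    lfc[classes == "unchanged"] <- runif(sum(classes == "unchanged"), -0.7, 0.7)
    ip_bybx <- ip_mock * 2^lfc * rlnorm(nr, 0, cfg$rbp_noise_sd)
    ip_bybx[classes == "blocked"] <- 0
    input[classes == "input_absent"] <- 0
    data.table(protein_id = sprintf("RBP%03d", seq_len(nr)),
               input = input, IP_mock = ip_mock, IP_bybx = ip_bybx,
               true_class = classes)
  })
}

#' Write simulation artifacts as plain-text files
#'
#' FASTA genome, BED12 catalog, chrom.sizes, truth tables (TSV) and a JSON
#' config echo (seed included).
#'
#' @param sim a [simulate_transcriptome()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_bed12(sim$catalog, file.path(dir, "transcripts.bed12"))
  fwrite(data.table(chrom = names(sim$catalog$chrom_sizes),
                    size = as.integer(sim$catalog$chrom_sizes)),
         file.path(dir, "chrom.sizes"), sep = "\t", col.names = FALSE)
  fwrite(sim$truth$sites, file.path(dir, "truth_sites.tsv"), sep = "\t")
  fwrite(sim$truth$transcripts, file.path(dir, "truth_transcripts.tsv"),
         sep = "\t")
  jsonlite::write_json(sim$truth$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
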