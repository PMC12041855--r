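# Shared in-code fixtures: tiny transcript models, read sets and files.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Single-exon coding transcript: exon [100, 1100), CDS [300, 900).
simple_model <- function(strand = "+", id = "tx1") {
  transcript_model(id, "gene1", "chr1", strand,
                   exons = cbind(100, 1100), cds_start = 300, cds_end = 900)
}

# Two-exon model matching the worked GTF example:
# exons [0,50) and [100,150), CDS [120,140).
split_model <- function(strand = "+", id = "tx2") {
  transcript_model(id, "gene2", "chr1", strand,
                   exons = rbind(c(0, 50), c(100, 150)),
                   cds_start = 120, cds_end = 140)
}

# Random valid multi-exon coding model for property-style loops.
random_model <- function(id, chrom = "chr1") {
  n_ex <- sample(1:4, 1)
  widths <- sample(30:200, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1) sample(50:300, n_ex - 1, replace = TRUE) else integer(0)
  starts <- sample(0:500, 1) + cumsum(c(0, head(widths, -1) + gaps))
  ex <- cbind(starts, starts + widths)
  L <- sum(widths)
  strand <- sample(c("+", "-"), 1)
  m0 <- structure(list(transcript_id = id, chrom = chrom, strand = strand,
                       exons = ex, mature_length = L),
                  class = "TranscriptModel")
  a <- sample.int(L - 10, 1)
  b <- a + sample.int(min(L - a, 60), 1) - 1
  g <- sort(c(transcript_to_genomic(m0, a), transcript_to_genomic(m0, b)))
  transcript_model(id, paste0("g", id), chrom, strand, ex,
                   cds_start = g[1], cds_end = g[2] + 1)
}

# Read set from a plain data.frame of positions.
reads_at <- function(chrom, strand, pos5, length = 30, ...) {
  read_end_set(data.table::data.table(chrom = chrom, strand = strand,
                                      pos5 = pos5, length = length), ...)
}

# Per-base brute-force region counting oracle for region_density.
brute_region_counts <- function(reads, catalog) {
  out <- list()
  for (id in names(catalog$transcripts)) {
    m <- catalog$transcripts[[id]]
    cnt <- c(utr5 = 0, cds = 0, utr3 = 0, full = 0)
    r <- reads$reads
    for (i in seq_len(nrow(r))) {
      if (r$chrom[i] != m$chrom || r$strand[i] != m$strand) next
      tp <- genomic_to_transcript(m, r$pos5[i])
      if (is.na(tp)) next
      cnt["full"] <- cnt["full"] + 1
      lab <- transcript_region(m, tp)
      if (!is.na(lab)) cnt[lab] <- cnt[lab] + 1
    }
    out[[id]] <- cnt
  }
  out
}

# Independent per-bin re-evaluation of the peak-calling rule with plain
# loops (no cumsum tricks), used as the brute-force oracle.
brute_eval_bins <- function(treat, ctrl, key, p_cutoff = 0.05,
                            fe_cutoff = 2, slocal = 200, llocal = 2000) {
  bin <- treat$bin_size
  floorv <- treat$total * bin / sum(treat$chrom_sizes)
  ratio <- if (is.null(ctrl)) 0 else treat$total / ctrl$total
  tv <- treat$bins[[key]]
  cv <- if (is.null(ctrl)) rep(0, length(tv)) else ctrl$bins[[key]]
  side_mean <- function(v) if (!length(v) || !any(v > 0)) 0 else
    sum(v) / sum(v > 0)
  n <- length(tv)
  sig <- logical(n); lam_out <- numeric(n)
  for (i in seq_len(n)) {
    lam <- cv[i] * ratio
    for (w in c(slocal, llocal)) {
      h <- max(1, round(w / bin / 2))
      left <- if (i > 1) cv[max(1, i - h):(i - 1)] else numeric(0)
      right <- if (i < n) cv[(i + 1):min(n, i + h)] else numeric(0)
      lam <- max(lam, side_mean(left) * ratio, side_mean(right) * ratio)
    }
    lam <- max(lam, floorv)
    p <- ppois(tv[i] - 1, lam, lower.tail = FALSE)
    sig[i] <- tv[i] > 0 && p <= p_cutoff && tv[i] / lam >= fe_cutoff
    lam_out[i] <- lam
  }
  list(sig = sig, lambda = lam_out)
}
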