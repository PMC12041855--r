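# Quantification of rG4 signal: metagene profiles, peak-centred matrices,
# per-region RPKM densities, PQS scanning and k-mer enrichment.

profile_rows <- function(track, anchors, w) {
  b <- track$bin_size
  if (w %% b != 0) stop("window must be a multiple of the bin size")
  nb <- 2L * as.integer(w / b)
  half <- nb / 2
  mat <- matrix(NA_real_, nrow = nrow(anchors), ncol = nb)
  for (i in seq_len(nrow(anchors))) {
    key <- cov_key(anchors$chrom[i], anchors$strand[i])
    v <- track$bins[[key]]
    if (is.null(v)) next
    a0 <- floor(anchors$pos[i] / b) + 1L
    jj <- (a0 - half):(a0 + half - 1L)
    ok <- jj >= 1 & jj <= length(v)
    row <- rep(NA_real_, nb)
    row[ok] <- v[jj[ok]]
    if (anchors$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  mat * (1e7 / track$total)
}

#' Metagene profile of binned signal around anchors
#'
#' Signal per bin is averaged over anchors after per-sample depth
#' normalization (counts per 10 million mapped reads). Minus-strand anchors
#' are reversed so the bin axis always runs 5'->3'. Windows clipped at a
#' chromosome edge contribute their available bins only; the anchor is
#' retained.
#'
#' @param track a [coverage()] track.
#' @param anchors `data.frame` with columns `chrom`, `pos` (0-based anchor
#'   base), `strand`.
#' @param w half-window in nt (default 1000); must be a multiple of the
#'   track's bin size.
#' @return object of class `MetaProfile`: list with `profile` (mean
#'   normalized signal per bin, length `2w/bin`), `offsets` (bin-start
#'   offsets relative to the anchor), `n_anchors`, `w`, `bin_size`.
#' @export
metaprofile <- function(track, anchors, w = 1000) {
  anchors <- as.data.frame(anchors)
  if (!nrow(anchors)) stop("metaprofile needs at least one anchor")
  mat <- profile_rows(track, anchors, w)
  b <- track$bin_size
  structure(list(profile = colMeans(mat, na.rm = TRUE),
                 offsets = seq(-w, w - b, by = b),
                 n_anchors = nrow(anchors), w = w, bin_size = b,
                 normalization = "per 1e7 mapped reads"),
            class = "MetaProfile")
}

#' Peak-centred signal matrix
#'
#' One row per peak (anchored at the peak centre), columns the window bins,
#' rows sorted by row mean descending with ties broken by peak id
#' ascending. The column means of the matrix equal the [metaprofile()] over
#' the peak centres.
#'
#' @param track a [coverage()] track.
#' @param peaks a [call_peaks()] result.
#' @param w half-window in nt (default 500).
#' @return numeric matrix (peaks x bins), rownames `chrom:start-end`,
#'   normalized per 1e7 mapped reads.
#' @export
peak_matrix <- function(track, peaks, w = 500) {
  if (!nrow(peaks)) stop("peak_matrix needs a non-empty peak set")
  anchors <- data.frame(chrom = peaks$chrom,
                        pos = floor((peaks$start + peaks$end) / 2),
                        strand = peaks$strand)
  mat <- profile_rows(track, anchors, w)
  ids <- sprintf("%s:%d-%d", peaks$chrom, as.integer(peaks$start),
                 as.integer(peaks$end))
  rownames(mat) <- ids
  o <- order(-rowMeans(mat, na.rm = TRUE), ids)
  mat[o, , drop = FALSE]
}

#' Per-region rG4 read density (RPKM)
#'
#' Counts each deduplicated read 5' end into the 5'UTR / CDS / 3'UTR (and
#' `full` mature transcript) of every overlapping transcript via
#' [genomic_to_transcript()], and converts counts to
#' `RPKM = reads x 1e9 / (region_length x total_mapped_reads)` with the
#' set's deduplicated record count as the total. Reads overlapping several
#' transcripts are counted in each (no expectation-maximization rescue).
#' Zero-length regions get `NA`, not 0.
#'
#' @param reads a deduplicated [read_end_set()].
#' @param catalog a [transcript_catalog()].
#' @param regions regions to tabulate (default 5'UTR, CDS, 3'UTR, full).
#' @param peaks optional peak table (`chrom`, `strand`, `start`, `end`):
#'   when given, only reads whose 5' end falls inside a same-strand peak
#'   interval are counted, so the density reflects called rG4 signal
#'   rather than total library background. The RPKM denominator (the
#'   set's total mapped reads) is unchanged.
#' @return `data.table` with columns `transcript_id`, `region`, `reads`,
#'   `length`, `rpkm`; attribute `total_mapped` records the denominator.
#' @export
region_density <- function(reads, catalog,
                           regions = c("utr5", "cds", "utr3", "full"),
                           peaks = NULL) {
  r <- reads$reads
  total <- reads$total
  if (!is.null(peaks) && nrow(r)) {
    if (!nrow(peaks)) {
      r <- r[0]
    } else {
      gr_r <- GenomicRanges::GRanges(r$chrom,
                                     IRanges::IRanges(start = r$pos5 + 1,
                                                      width = 1),
                                     strand = r$strand)
      gr_p <- GenomicRanges::GRanges(peaks$chrom,
                                     IRanges::IRanges(start = peaks$start + 1,
                                                      end = peaks$end),
                                     strand = peaks$strand)
      keep <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr_r, gr_p, ignore.strand = FALSE)))
      r <- r[sort(keep)]
    }
  }
  gr_reads <- GenomicRanges::GRanges(
    seqnames = r$chrom, ranges = IRanges::IRanges(start = r$pos5 + 1, width = 1),
    strand = r$strand)
  gr_ex <- exon_granges(catalog)
  hits <- GenomicRanges::findOverlaps(gr_reads, gr_ex, ignore.strand = FALSE)
  txs <- catalog$transcripts
  counts <- matrix(0, nrow = length(txs), ncol = length(regions),
                   dimnames = list(names(txs), regions))
  if (length(hits)) {
    hit_tx <- gr_ex$tx_id[S4Vectors::subjectHits(hits)]
    hit_pos <- r$pos5[S4Vectors::queryHits(hits)]
    by_tx <- split(hit_pos, hit_tx)
    for (id in names(by_tx)) {
      m <- txs[[id]]
      tp <- genomic_to_transcript(m, by_tx[[id]])
      tp <- tp[!is.na(tp)]
      if ("full" %in% regions) counts[id, "full"] <- length(tp)
      lab <- transcript_region(m, tp)
      for (rg in intersect(regions, c("utr5", "cds", "utr3")))
        counts[id, rg] <- sum(lab == rg, na.rm = TRUE)
    }
  }
  rows <- lapply(names(txs), function(id) {
    m <- txs[[id]]
    len <- c(utr5 = m$utr5_len, cds = m$cds_len, utr3 = m$utr3_len,
             full = m$mature_length)[regions]
    data.table(transcript_id = id, region = regions,
               reads = counts[id, regions], length = as.numeric(len))
  })
  out <- rbindlist(rows)
  out[, rpkm := ifelse(is.na(length) | length == 0, NA_real_,
                       reads * 1e9 / (length * total))]
  setattr(out, "total_mapped", total)
  out[]
}

#' Scan a nucleotide sequence for canonical putative quadruplex sequences
#'
#' Matches the canonical PQS pattern of four runs of >= 3 guanines
#' separated by loops of 1-7 nt (`G{3,}(N{1,7}G{3,}){3}`), greedily and
#' non-overlapping left to right. T and U are equivalent.
#'
#' @param seq nucleotide string over ACGTUN (case-insensitive).
#' @return `data.table` with columns `start`, `end` (0-based half-open),
#'   `n_tracts` (always 4) and `loops` (comma-separated loop lengths
#'   between the four maximal G-runs of the match).
#' @export
scan_pqs <- function(seq) {
  s <- chartr("uU", "tT", seq)
  s <- toupper(s)
  m <- gregexpr("G{3,}(?:[ACTN]{1,7}G{3,}){3}", s, perl = TRUE)[[1]]
  empty <- data.table(start = integer(0), end = integer(0),
                      n_tracts = integer(0), loops = character(0))
  if (m[1] == -1) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  loops <- vapply(seq_along(starts), function(i) {
    sub <- substr(s, starts[i] + 1, starts[i] + lens[i])
    runs <- rle(strsplit(sub, "")[[1]] == "G")
    gl <- runs$lengths[runs$values]          # G-run lengths
    ll <- runs$lengths[!runs$values]         # loop lengths
    paste(ll[seq_len(min(3, length(ll)))], collapse = ",")
  }, "")
  data.table(start = starts, end = starts + lens,
             n_tracts = 4L, loops = loops)
}

#' Extract strand-aware peak sequences extended 30 nt to the 5' side
#'
#' Each peak's interval is extended 30 nt (configurable) toward its 5'
#' upstream side and the corresponding genome sequence is returned,
#' reverse-complemented for minus-strand peaks so sequences read 5'->3'.
#' Slices beyond a contig end are clipped.
#'
#' @param peaks a [call_peaks()] result.
#' @param genome named `DNAStringSet`.
#' @param ext extension in nt (default 30).
#' @return named character vector of sequences (names `chrom:start-end(strand)`).
#' @export
peak_upstream_sequences <- function(peaks, genome, ext = 30) {
  out <- character(nrow(peaks))
  nm <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    chrom_seq <- genome[[peaks$chrom[i]]]
    if (peaks$strand[i] == "+") {
      s0 <- max(0, peaks$start[i] - ext); e0 <- peaks$end[i]
    } else {
      s0 <- peaks$start[i]
      e0 <- min(length(chrom_seq), peaks$end[i] + ext)
    }
    sq <- Biostrings::subseq(chrom_seq, s0 + 1, e0)
    if (peaks$strand[i] == "-") sq <- Biostrings::reverseComplement(sq)
    out[i] <- as.character(sq)
    nm[i] <- sprintf("%s:%d-%d(%s)", peaks$chrom[i], as.integer(s0),
                     as.integer(e0), peaks$strand[i])
  }
  setNames(out, nm)
}

#' Per-k-mer log2 enrichment of foreground over background sequences
#'
#' k-mer frequencies are pooled over each sequence collection and compared
#' as `log2((freq_fg + eps) / (freq_bg + eps))` with the pseudo-frequency
#' `eps = 1 / (total k-mers counted over both collections)`.
#'
#' @param seqs foreground sequences (character vector).
#' @param background_seqs background sequences (character vector).
#' @param k k-mer size (default 6).
#' @return `data.table` with columns `kmer`, `fg_freq`, `bg_freq`,
#'   `log2_enrichment`, sorted by enrichment descending.
#' @export
g_enrichment <- function(seqs, background_seqs, k = 6) {
  count_kmers <- function(x) {
    ss <- Biostrings::DNAStringSet(toupper(chartr("uU", "tT", x)))
    Biostrings::oligonucleotideFrequency(ss, width = k,
                                         simplify.as = "collapse")
  }
  fg <- count_kmers(seqs)
  bg <- count_kmers(background_seqs)
  eps <- 1 / (sum(fg) + sum(bg))
  out <- data.table(kmer = names(fg),
                    fg_freq = as.numeric(fg) / sum(fg),
                    bg_freq = as.numeric(bg) / sum(bg))
  out[, log2_enrichment := log2((fg_freq + eps) / (bg_freq + eps))]
  setorder(out, -log2_enrichment, kmer)
  out[]
}
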