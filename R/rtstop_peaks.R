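# Deduplication, binned stranded coverage, and Poisson enrichment peak
# calling of treatment (BG4) RT stops over the IgG control.

#' Remove PCR duplicates from a read-end set
#'
#' Keeps at most one record per `(chrom, strand, pos5, length)` key; the
#' result does not depend on input order. The set's `total` is reset to the
#' retained record count, which is the denominator all downstream
#' depth normalization uses.
#'
#' @param reads a [read_end_set()].
#' @return deduplicated [read_end_set()].
#' @export
deduplicate <- function(reads) {
  r <- unique(reads$reads, by = c("chrom", "strand", "pos5", "length"))
  setorder(r, chrom, strand, pos5, length)
  read_end_set(r, total = nrow(r), library = reads$library,
               condition = reads$condition, n_skipped = reads$n_skipped)
}

cov_key <- function(chrom, strand) paste(chrom, strand, sep = "|")

#' Binned stranded coverage of read 5' ends
#'
#' Each read contributes one count to the bin containing its 5' end; plus
#' and minus strands are kept separate.
#'
#' @param reads a [read_end_set()].
#' @param chrom_sizes named numeric vector of chromosome lengths (or a
#'   [transcript_catalog()], whose sizes are used).
#' @param bin bin size in nt (default 10).
#' @return object of class `CoverageTrack`: list with `bins` (named list of
#'   count vectors, one per chromosome x strand), `bin_size`, `total`
#'   mapped reads, and `chrom_sizes`.
#' @export
coverage <- function(reads, chrom_sizes, bin = 10) {
  if (inherits(chrom_sizes, "TranscriptCatalog"))
    chrom_sizes <- chrom_sizes$chrom_sizes
  stopifnot(bin >= 1)
  r <- reads$reads
  if (nrow(r)) {
    if (!all(r$chrom %in% names(chrom_sizes)))
      stop("reads on chromosomes absent from chrom_sizes")
    if (any(r$pos5 >= chrom_sizes[r$chrom]))
      stop("read position beyond chromosome end")
  }
  bins <- list()
  for (ch in names(chrom_sizes)) {
    nb <- as.integer(ceiling(chrom_sizes[[ch]] / bin))
    for (s in c("+", "-")) {
      sub <- r[r$chrom == ch & r$strand == s]
      bins[[cov_key(ch, s)]] <-
        tabulate(floor(sub$pos5 / bin) + 1L, nbins = nb)
    }
  }
  structure(list(bins = bins, bin_size = bin, total = nrow(r),
                 chrom_sizes = chrom_sizes),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack: bin", x$bin_size, "nt,", x$total, "reads on",
      length(x$chrom_sizes), "chromosomes\n")
  invisible(x)
}

#' Write a coverage track as bedGraph (one file per strand)
#'
#' @param track a [coverage()] track.
#' @param prefix output path prefix; `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph` are written.
#' @return the two file paths, invisibly.
#' @export
write_bedgraph <- function(track, prefix) {
  paths <- c(paste0(prefix, ".plus.bedGraph"), paste0(prefix, ".minus.bedGraph"))
  for (si in 1:2) {
    s <- c("+", "-")[si]
    rows <- list()
    for (ch in names(track$chrom_sizes)) {
      v <- track$bins[[cov_key(ch, s)]]
      nz <- which(v != 0)
      if (!length(nz)) next
      rows[[ch]] <- data.table(
        chrom = ch, start = (nz - 1L) * track$bin_size,
        end = pmin(nz * track$bin_size, track$chrom_sizes[[ch]]),
        value = v[nz])
    }
    out <- if (length(rows)) rbindlist(rows) else
      data.table(chrom = character(0), start = integer(0),
                 end = integer(0), value = numeric(0))
    fwrite(out, paths[si], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}

# Per bin, the larger of the mean over the `half` bins to the left
# (excluding the bin itself) and over the `half` bins to the right, where
# each side's mean is taken over its occupied (nonzero) bins only. The
# one-sided maximum keeps the background estimate anchored to the expressed
# side at the edges of expressed blocks; restricting to occupied bins stops
# unexpressed neighbours (pads, introns) from diluting it — a neighbourhood
# with no occupied bins contributes 0 and the genome floor takes over.
# Excluding the centre bin keeps a single-bin signal from inflating its own
# background.
flank_max_mean <- function(v, half) {
  n <- length(v)
  if (half <= 0 || n == 0) return(v)
  cs <- cumsum(c(0, v))
  co <- cumsum(c(0, v > 0))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  left_occ <- co[i] - co[lo]
  left <- (cs[i] - cs[lo]) / pmax(left_occ, 1L)
  hi <- pmin(i + half, n)
  right_occ <- co[hi + 1] - co[i + 1]
  right <- (cs[hi + 1] - cs[i + 1]) / pmax(right_occ, 1L)
  pmax(left, right)
}

# Shared per-bin significance evaluation for one chromosome x strand key.
eval_bins <- function(treat, ctrl, key, p_cutoff, fe_cutoff,
                      slocal, llocal) {
  bin <- treat$bin_size
  lambda_floor <- treat$total * bin / sum(treat$chrom_sizes)
  ratio <- if (is.null(ctrl)) 0 else treat$total / ctrl$total
  tv <- treat$bins[[key]]
  cv <- if (is.null(ctrl) || is.null(ctrl$bins[[key]])) rep(0, length(tv))
        else ctrl$bins[[key]]
  lam_s <- flank_max_mean(cv, max(1L, round(slocal / bin / 2))) * ratio
  lam_l <- flank_max_mean(cv, max(1L, round(llocal / bin / 2))) * ratio
  lam <- pmax(cv * ratio, lam_s, lam_l, lambda_floor)
  p <- ppois(tv - 1, lam, lower.tail = FALSE)
  list(treat = tv, lambda = lam, p = p,
       sig = tv > 0 & p <= p_cutoff & tv / lam >= fe_cutoff)
}

#' Call RT-stop peaks by Poisson enrichment over a control track
#'
#' Per bin, the expected background `lambda` is the largest of the scaled
#' control bin itself, the control rate over a short local window
#' (`slocal`, default 200 nt) and over a long local window (`llocal`,
#' default 2 kb) — all scaled to the treatment depth — and the genome-wide
#' treatment floor (`lambda_floor = treat_total x bin / genome_size`).
#' Each local window rate is the larger of the left-flank and right-flank
#' means (centre bin excluded). Taking the maximum over several window
#' scales stabilizes the background estimate the way sliding local-lambda
#' peak callers do: the raw single-bin control alone is a one-observation
#' Poisson estimate whose downward noise would dominate the test, while
#' centered window means would underestimate the background at the edges
#' of expressed blocks. A bin is significant
#' iff the Poisson upper tail `P(X >= treat_bin; lambda)` is at or below
#' `p_cutoff` and the fold enrichment `treat_bin / lambda` is at least
#' `fe_cutoff`. Significant bins on the same chromosome and strand whose
#' indices differ by at most `min_gap` are merged into one peak; the summit
#' is the leftmost maximal-treatment bin and carries the reported fold
#' enrichment and p-value. A Benjamini-Hochberg q-value over all evaluated
#' bins is emitted for information only; no multiple-testing correction is
#' applied to the calling itself. Calling is strand-aware throughout, and
#' `ctrl = NULL` calls against the uniform genome background alone.
#'
#' @param treat,ctrl [coverage()] tracks with identical bin size (ctrl may
#'   be `NULL`).
#' @param p_cutoff Poisson upper-tail cutoff (default 0.05, uncorrected).
#' @param fe_cutoff minimum fold enrichment (default 2).
#' @param min_gap maximum bin-index gap merged into one peak (default 3).
#' @param slocal,llocal short and long control-averaging windows in nt.
#' @return object of class `PeakSet`: a `data.table` of peaks (`chrom`,
#'   `strand`, `start`, `end`, `summit`, `fold_enrichment`, `p_value`,
#'   `q_value`, `treatment_count`, `control_lambda`) with the calling
#'   parameters in `attr(, "params")`.
#' @export
call_peaks <- function(treat, ctrl = NULL, p_cutoff = 0.05, fe_cutoff = 2.0,
                       min_gap = 3L, slocal = 200, llocal = 2000) {
  if (!is.null(ctrl)) {
    if (treat$bin_size != ctrl$bin_size)
      stop("treatment and control tracks have different bin sizes")
    if (ctrl$total <= 0) stop("control track has zero mapped reads")
  }
  bin <- treat$bin_size
  lambda_floor <- treat$total * bin / sum(treat$chrom_sizes)
  keys <- names(treat$bins)
  per_bin <- lapply(keys, function(k)
    eval_bins(treat, ctrl, k, p_cutoff, fe_cutoff, slocal, llocal))
  names(per_bin) <- keys
  qall <- p.adjust(unlist(lapply(per_bin, `[[`, "p")), method = "BH")
  qsplit <- split(qall, rep(keys, vapply(per_bin, function(x) length(x$p), 0L)))
  peaks <- list()
  for (k in keys) {
    pb <- per_bin[[k]]
    idx <- which(pb$sig)
    if (!length(idx)) next
    grp <- cumsum(c(1, diff(idx) > min_gap))
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    chrom_len <- treat$chrom_sizes[[parts[1]]]
    for (g in unique(grp)) {
      ii <- idx[grp == g]
      lo <- min(ii); hi <- max(ii)
      span <- lo:hi
      smt <- span[which.max(pb$treat[span])]    # leftmost maximal bin
      peaks[[length(peaks) + 1L]] <- data.table(
        chrom = parts[1], strand = parts[2],
        start = (lo - 1) * bin, end = min(hi * bin, chrom_len),
        summit = (smt - 1) * bin + floor(bin / 2),
        fold_enrichment = pb$treat[smt] / pb$lambda[smt],
        p_value = pb$p[smt], q_value = qsplit[[k]][smt],
        treatment_count = pb$treat[smt], control_lambda = pb$lambda[smt])
    }
  }
  out <- if (length(peaks)) rbindlist(peaks) else
    data.table(chrom = character(0), strand = character(0), start = numeric(0),
               end = numeric(0), summit = numeric(0),
               fold_enrichment = numeric(0), p_value = numeric(0),
               q_value = numeric(0), treatment_count = numeric(0),
               control_lambda = numeric(0))
  setorder(out, chrom, strand, start)
  structure(out, class = c("PeakSet", class(out)),
            params = list(p_cutoff = p_cutoff, fe_cutoff = fe_cutoff,
                          min_gap = min_gap, bin = bin,
                          slocal = slocal, llocal = llocal,
                          lambda_floor = lambda_floor,
                          control = !is.null(ctrl)))
}

#' Fraction of significant bins under the peak-calling rule
#'
#' Calibration helper: evaluates the per-bin significance rule of
#' [call_peaks()] without merging and returns the fraction of significant
#' bins, for null false-positive-rate checks.
#'
#' @inheritParams call_peaks
#' @return list with `n_bins`, `n_significant`, `fraction`.
#' @export
significant_bin_fraction <- function(treat, ctrl = NULL, p_cutoff = 0.05,
                                     fe_cutoff = 2.0, slocal = 200,
                                     llocal = 2000) {
  if (!is.null(ctrl) && treat$bin_size != ctrl$bin_size)
    stop("bin size mismatch")
  n_bins <- 0L; n_sig <- 0L
  for (k in names(treat$bins)) {
    pb <- eval_bins(treat, ctrl, k, p_cutoff, fe_cutoff, slocal, llocal)
    n_bins <- n_bins + length(pb$sig)
    n_sig <- n_sig + sum(pb$sig)
  }
  list(n_bins = n_bins, n_significant = n_sig, fraction = n_sig / n_bins)
}

#' Annotate peak summits with genomic feature labels
#'
#' Labels each peak by the feature its summit falls in, with precedence
#' 5'UTR > 3'UTR > CDS > intron > upstream (within 2 kb of a same-strand
#' TSS) > intergenic, taken over all catalog transcripts on the summit's
#' strand. When a repeat interval set is supplied, summits overlapping a
#' repeat get a co-label with the repeat class.
#'
#' @param peaks a [call_peaks()] result.
#' @param catalog a [transcript_catalog()].
#' @param repeats optional `data.frame` of repeat intervals with columns
#'   `chrom`, `start`, `end` (0-based half-open) and optionally `class`.
#' @param upstream_nt upstream window before the TSS (default 2000).
#' @return the peak table with added columns `feature`, `transcript_id`
#'   (an arbitrary transcript witnessing the label, `NA` for intergenic)
#'   and `repeat_class`.
#' @export
annotate_peaks <- function(peaks, catalog, repeats = NULL, upstream_nt = 2000) {
  prec <- c(utr5 = 1, utr3 = 2, cds = 3, intron = 4, upstream = 5,
            intergenic = 6)
  feature <- rep("intergenic", nrow(peaks))
  witness <- rep(NA_character_, nrow(peaks))
  if (nrow(peaks)) {
    for (m in catalog$transcripts) {
      on <- which(peaks$chrom == m$chrom & peaks$strand == m$strand)
      if (!length(on)) next
      s <- peaks$summit[on]
      tp <- genomic_to_transcript(m, s)
      lab <- transcript_region(m, tp)
      lab[is.na(lab) & !is.na(tp)] <- "cds"   # exonic, non-coding model
      span_lo <- m$exons[1, 1]
      span_hi <- m$exons[nrow(m$exons), 2]
      intronic <- is.na(tp) & s >= span_lo & s < span_hi
      lab[intronic] <- "intron"
      if (m$strand == "+") {
        up <- is.na(lab) & s >= span_lo - upstream_nt & s < span_lo
      } else {
        up <- is.na(lab) & s >= span_hi & s < span_hi + upstream_nt
      }
      lab[up] <- "upstream"
      better <- !is.na(lab) & prec[lab] < prec[feature[on]]
      feature[on][better] <- lab[better]
      witness[on][better] <- m$transcript_id
    }
  }
  rep_class <- rep(NA_character_, nrow(peaks))
  if (!is.null(repeats) && nrow(peaks) && nrow(repeats)) {
    rp <- as.data.table(repeats)
    if (!"class" %in% names(rp)) rp[, class := "repeat"]
    for (i in seq_len(nrow(peaks))) {
      hit <- rp$chrom == peaks$chrom[i] & rp$start <= peaks$summit[i] &
        peaks$summit[i] < rp$end
      if (any(hit)) rep_class[i] <- rp$class[which(hit)[1]]
    }
  }
  out <- copy(as.data.table(peaks))
  out[, `:=`(feature = feature, transcript_id = witness,
             repeat_class = rep_class)]
  out
}

#' Write peaks in narrowPeak-style BED6+4
#'
#' Columns: chrom, start, end, name, score (10 x fold enrichment, capped),
#' strand, fold enrichment, -log10 p, -log10 q, summit offset from start.
#'
#' @param peaks a [call_peaks()] result.
#' @param path output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  p <- as.data.table(peaks)
  out <- data.table(
    chrom = p$chrom, start = as.integer(p$start), end = as.integer(p$end),
    name = if (nrow(p)) sprintf("peak%d", seq_len(nrow(p))) else character(0),
    score = as.integer(pmin(1000, round(10 * p$fold_enrichment))),
    strand = p$strand,
    signalValue = round(p$fold_enrichment, 5),
    pValue = round(-log10(pmax(p$p_value, 1e-300)), 5),
    qValue = round(-log10(pmax(p$q_value, 1e-300)), 5),
    peak = as.integer(p$summit - p$start))
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
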