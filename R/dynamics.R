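# Classification of transcripts by rG4 occupancy across stages/treatments
# and overlap statistics.

#' Transcripts containing at least one peak summit in their exons
#'
#' The package's working definition of an "rG4-containing transcript": at
#' least one called peak summit maps into the transcript's exons on the
#' same strand. Set `rule = "overlap"` to accept any peak-interval overlap
#' with the exons instead.
#'
#' @param peaks a [call_peaks()] result.
#' @param catalog a [transcript_catalog()].
#' @param rule `"summit"` (default) or `"overlap"`.
#' @return character vector of transcript ids.
#' @export
rg4_containing_transcripts <- function(peaks, catalog,
                                       rule = c("summit", "overlap")) {
  rule <- match.arg(rule)
  if (!nrow(peaks)) return(character(0))
  gr_ex <- exon_granges(catalog)
  gr_pk <- if (rule == "summit") {
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(start = peaks$summit + 1, width = 1),
                           strand = peaks$strand)
  } else {
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(start = peaks$start + 1,
                                            end = peaks$end),
                           strand = peaks$strand)
  }
  hits <- GenomicRanges::findOverlaps(gr_pk, gr_ex, ignore.strand = FALSE)
  sort(unique(gr_ex$tx_id[S4Vectors::subjectHits(hits)]))
}

#' Classify transcripts into condition-specific and shared rG4 sets
#'
#' Memberships are computed with [rg4_containing_transcripts()] per peak
#' set; transcripts are labelled `A-specific`, `shared`, `B-specific`, or
#' `neither`. The counts obey `|A-specific| + |shared| = |A|` and
#' `|B-specific| + |shared| = |B|` exactly.
#'
#' @param peaksA,peaksB peak sets of the two conditions.
#' @param catalog a [transcript_catalog()].
#' @param rule membership rule, see [rg4_containing_transcripts()].
#' @return list of class `Rg4SetClassification` with `table` (per-transcript
#'   memberships and cluster label), `counts` (named: `A`, `B`,
#'   `A_specific`, `shared`, `B_specific`), and the rule used.
#' @export
rg4_transcript_sets <- function(peaksA, peaksB, catalog,
                                rule = c("summit", "overlap")) {
  if (!length(catalog$transcripts)) stop("empty catalog")
  rule <- match.arg(rule)
  inA <- rg4_containing_transcripts(peaksA, catalog, rule)
  inB <- rg4_containing_transcripts(peaksB, catalog, rule)
  ids <- names(catalog$transcripts)
  a <- ids %in% inA
  b <- ids %in% inB
  label <- ifelse(a & b, "shared",
           ifelse(a, "A-specific", ifelse(b, "B-specific", "neither")))
  tab <- data.table(transcript_id = ids, in_A = a, in_B = b, cluster = label)
  counts <- c(A = sum(a), B = sum(b), A_specific = sum(a & !b),
              shared = sum(a & b), B_specific = sum(b & !a))
  structure(list(table = tab, counts = counts, rule = rule),
            class = "Rg4SetClassification")
}

#' @export
print.Rg4SetClassification <- function(x, ...) {
  cat("rG4 transcript sets (membership rule:", x$rule, ")\n")
  print(x$counts)
  invisible(x)
}

#' Arithmetic of a two-set Venn partition
#'
#' Given the three disjoint cluster sizes of a two-condition Venn diagram,
#' returns the set totals and the shared fractions, the quantities usually
#' printed next to such diagrams.
#'
#' @param a_specific,shared,b_specific disjoint cluster sizes.
#' @return list with `nA`, `nB`, `shared`, `shared_pct_of_A`,
#'   `shared_pct_of_B` (percentages).
#' @export
venn_counts <- function(a_specific, shared, b_specific) {
  nA <- a_specific + shared
  nB <- b_specific + shared
  list(nA = nA, nB = nB, shared = shared,
       shared_pct_of_A = 100 * shared / nA,
       shared_pct_of_B = 100 * shared / nB)
}

#' Hypergeometric upper-tail p-value for a set overlap
#'
#' Probability of observing an overlap of at least `nAB` between a set of
#' size `nA` and an independent draw of size `nB` from a universe of
#' `universe_n` elements. This is the standard enrichment test for Venn
#' overlaps; the output metadata of the pipeline states its use.
#'
#' @param nA,nB set sizes; `nAB` observed overlap; `universe_n` universe size.
#' @return upper-tail p-value `P(X >= nAB)`.
#' @export
overlap_significance <- function(nA, nB, nAB, universe_n) {
  if (nAB > min(nA, nB) || max(nA, nB) > universe_n || nAB < 0)
    stop("impossible overlap counts")
  phyper(nAB - 1, nA, universe_n - nA, nB, lower.tail = FALSE)
}

#' Per-transcript log2 density ratio
#'
#' `log2((dA + eps) / (dB + eps))`, antisymmetric in its arguments.
#'
#' @param dA,dB non-negative density vectors on a shared index.
#' @param eps pseudocount; must be > 0 whenever any density is 0.
#' @return numeric vector of log2 ratios.
#' @export
density_ratio <- function(dA, dB, eps = 0.01) {
  if (length(dA) != length(dB)) stop("density vectors differ in length")
  if (eps <= 0 && any(c(dA, dB) == 0))
    stop("eps must be > 0 when any density is 0")
  log2((dA + eps) / (dB + eps))
}

#' Classify rG4 removal blockade from three-condition densities
#'
#' For transcripts that contained rG4s in the untreated reference stage
#' (GV) and showed normal maturation-coupled removal
#' (`d_GV >= removal_fc x d_MII_DMSO` after pseudocounting), the
#' removal-retention ratio
#' `rho = (d_MII_BYBX - d_MII_DMSO) / (d_GV - d_MII_DMSO)` (clamped to
#' \[0,1\]) measures how much of the removed signal the treatment retained:
#' `rho <= lo` means removal was not affected, `rho >= hi` completely
#' blocked, in between partially blocked. Other transcripts are
#' `not_evaluable`. The classification is invariant to rescaling all three
#' density columns (with `eps` scaled accordingly).
#'
#' @param d_gv,d_mii_dmso,d_mii_bybx density vectors on a shared index.
#' @param gv_positive optional logical vector marking transcripts
#'   rG4-containing at GV (default: `d_gv > 0`).
#' @param removal_fc minimal GV/DMSO fold for "removal occurred" (default 2).
#' @param lo,hi rho cutoffs for the three categories (defaults 0.25 / 0.75).
#' @param eps pseudocount added to all densities (default 0.01).
#' @return `data.table` with columns `rho` and
#'   `category` in `{not_affected, partially_blocked, completely_blocked,
#'   not_evaluable}`.
#' @export
removal_categories <- function(d_gv, d_mii_dmso, d_mii_bybx,
                               gv_positive = NULL, removal_fc = 2,
                               lo = 0.25, hi = 0.75, eps = 0.01) {
  n <- length(d_gv)
  if (length(d_mii_dmso) != n || length(d_mii_bybx) != n)
    stop("density columns differ in length (missing condition column?)")
  if (is.null(gv_positive)) gv_positive <- d_gv > 0
  g <- d_gv + eps; dm <- d_mii_dmso + eps; by <- d_mii_bybx + eps
  evaluable <- gv_positive & g >= removal_fc * dm
  rho <- rep(NA_real_, n)
  rho[evaluable] <- pmin(1, pmax(0, (by[evaluable] - dm[evaluable]) /
                                    (g[evaluable] - dm[evaluable])))
  category <- rep("not_evaluable", n)
  category[evaluable & rho <= lo] <- "not_affected"
  category[evaluable & rho > lo & rho < hi] <- "partially_blocked"
  category[evaluable & rho >= hi] <- "completely_blocked"
  data.table(rho = rho, category = category)
}
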