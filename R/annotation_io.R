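#' @importFrom data.table data.table fread fwrite as.data.table rbindlist
#'   setorder setattr copy := .I .N
#' @importFrom stats ppois phyper rpois rnorm rbinom rnbinom runif rlnorm
#'   rmultinom median cor setNames p.adjust
#' @importFrom utils head tail
NULL

# ---- transcript models -------------------------------------------------------

#' Construct a transcript model
#'
#' A transcript model carries the exon structure of one transcript on the
#' genome, together with an optional coding region from which the 5'UTR /
#' CDS / 3'UTR segmentation of the mature (spliced) transcript is derived.
#' All coordinates are 0-based half-open genomic intervals; `strand` decides
#' the 5'->3' orientation of the mature transcript.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column numeric matrix of `(start, end)` 0-based half-open
#'   genomic intervals; must be sorted and non-overlapping.
#' @param cds_start,cds_end 0-based half-open genomic span of the coding
#'   region, or `NA` for a non-coding transcript. The span must be covered
#'   by the exons.
#' @return object of class `TranscriptModel` with derived fields
#'   `mature_length`, `utr5_len`, `cds_len`, `utr3_len` (the latter three
#'   `NA` for non-coding transcripts). The three region lengths always sum
#'   to the mature length when a CDS is present.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start = NA, cds_end = NA) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0) stop("transcript must have at least one exon")
  if (any(exons[, 2] <= exons[, 1])) stop("empty exon interval")
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in transcript ", transcript_id)
  L <- sum(exons[, 2] - exons[, 1])
  m <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    chrom = chrom, strand = strand, exons = exons,
    cds_start = as.numeric(cds_start), cds_end = as.numeric(cds_end),
    mature_length = L,
    utr5_len = NA_real_, cds_len = NA_real_, utr3_len = NA_real_
  ), class = "TranscriptModel")
  if (!is.na(cds_start) && !is.na(cds_end) && cds_end > cds_start) {
    cov <- sum(pmax(0, pmin(exons[, 2], cds_end) - pmax(exons[, 1], cds_start)))
    ta <- genomic_to_transcript(m, cds_start)
    tb <- genomic_to_transcript(m, cds_end - 1)
    if (is.na(ta) || is.na(tb))
      stop("CDS boundary outside exons in transcript ", transcript_id)
    t_lo <- min(ta, tb)
    t_hi <- max(ta, tb) + 1
    if (cov != t_hi - t_lo)
      stop("CDS not covered by exons in transcript ", transcript_id)
    m$utr5_len <- t_lo
    m$cds_len <- t_hi - t_lo
    m$utr3_len <- L - t_hi
  }
  m
}

#' Map genomic positions onto mature-transcript coordinates
#'
#' Total function: exonic positions map to their 0-based offset along the
#' mature transcript in 5'->3' orientation (so on the minus strand the
#' rightmost exonic base is offset 0); intronic or outside positions map
#' to `NA`.
#'
#' @param model a [transcript_model()].
#' @param gpos numeric vector of 0-based genomic positions.
#' @return numeric vector of transcript offsets in `[0, mature_length)`,
#'   `NA` where `gpos` is not exonic.
#' @export
genomic_to_transcript <- function(model, gpos) {
  ex <- model$exons
  cum <- cumsum(c(0, ex[, 2] - ex[, 1]))
  idx <- findInterval(gpos, ex[, 1])
  ok <- idx >= 1 & !is.na(gpos)
  ok[ok] <- gpos[ok] < ex[idx[ok], 2]
  off <- rep(NA_real_, length(gpos))
  off[ok] <- cum[idx[ok]] + gpos[ok] - ex[idx[ok], 1]
  if (model$strand == "-") off <- model$mature_length - 1 - off
  off
}

#' Map mature-transcript coordinates back to genomic positions
#'
#' Inverse of [genomic_to_transcript()] on `[0, mature_length)`.
#'
#' @param model a [transcript_model()].
#' @param tpos numeric vector of 0-based transcript offsets.
#' @return numeric vector of 0-based genomic positions (`NA` out of range).
#' @export
transcript_to_genomic <- function(model, tpos) {
  ex <- model$exons
  L <- model$mature_length
  plus_off <- if (model$strand == "-") L - 1 - tpos else tpos
  cum <- cumsum(c(0, ex[, 2] - ex[, 1]))
  out <- rep(NA_real_, length(tpos))
  ok <- !is.na(plus_off) & plus_off >= 0 & plus_off < L
  idx <- findInterval(plus_off[ok], cum, rightmost.closed = FALSE)
  out[ok] <- ex[idx, 1] + (plus_off[ok] - cum[idx])
  out
}

#' Region label of a transcript coordinate
#'
#' @param model a coding [transcript_model()].
#' @param tpos transcript offsets (0-based, mature coordinates).
#' @return character vector over `{"utr5","cds","utr3"}`, `NA` out of range
#'   or when the transcript is non-coding.
#' @export
transcript_region <- function(model, tpos) {
  out <- rep(NA_character_, length(tpos))
  if (is.na(model$cds_len)) return(out)
  a <- model$utr5_len
  b <- a + model$cds_len
  inr <- !is.na(tpos) & tpos >= 0 & tpos < model$mature_length
  out[inr & tpos < a] <- "utr5"
  out[inr & tpos >= a & tpos < b] <- "cds"
  out[inr & tpos >= b] <- "utr3"
  out
}

#' Transcription start / end sites of a model
#'
#' @param model a [transcript_model()].
#' @return named numeric vector with elements `tss` and `tes` (0-based
#'   genomic position of the first and last transcribed base).
#' @export
tss_tes <- function(model) {
  if (model$strand == "+") {
    c(tss = model$exons[1, 1], tes = model$exons[nrow(model$exons), 2] - 1)
  } else {
    c(tss = model$exons[nrow(model$exons), 2] - 1, tes = model$exons[1, 1])
  }
}

# ---- transcript catalog ------------------------------------------------------

#' Construct a transcript catalog
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param chrom_sizes named numeric vector of chromosome lengths. When
#'   `NULL`, sizes are inferred as the maximum annotated end per chromosome.
#' @return object of class `TranscriptCatalog`: a list with `transcripts`
#'   (named by transcript id) and `chrom_sizes`.
#' @export
transcript_catalog <- function(transcripts, chrom_sizes = NULL) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript ids in catalog")
  names(transcripts) <- ids
  if (is.null(chrom_sizes)) {
    ends <- vapply(transcripts, function(m) max(m$exons[, 2]), 0)
    chroms <- vapply(transcripts, `[[`, "", "chrom")
    chrom_sizes <- tapply(ends, chroms, max)
    chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  for (m in transcripts) {
    if (!m$chrom %in% names(chrom_sizes))
      stop("transcript ", m$transcript_id, " on unknown chromosome ", m$chrom)
    if (max(m$exons[, 2]) > chrom_sizes[[m$chrom]])
      stop("transcript ", m$transcript_id, " exceeds chromosome bounds")
  }
  structure(list(transcripts = transcripts, chrom_sizes = chrom_sizes),
            class = "TranscriptCatalog")
}

#' @export
print.TranscriptCatalog <- function(x, ...) {
  cat("TranscriptCatalog:", length(x$transcripts), "transcripts on",
      length(x$chrom_sizes), "chromosomes\n")
  invisible(x)
}

#' Exons of a catalog as a GRanges
#'
#' @param catalog a [transcript_catalog()].
#' @return `GRanges` of all exons with metadata column `tx_id`.
#' @export
exon_granges <- function(catalog) {
  txs <- catalog$transcripts
  n_ex <- vapply(txs, function(m) nrow(m$exons), 0L)
  starts <- unlist(lapply(txs, function(m) m$exons[, 1]), use.names = FALSE)
  ends <- unlist(lapply(txs, function(m) m$exons[, 2]), use.names = FALSE)
  GenomicRanges::GRanges(
    seqnames = rep(vapply(txs, `[[`, "", "chrom"), n_ex),
    ranges = IRanges::IRanges(start = starts + 1, end = ends),
    strand = rep(vapply(txs, `[[`, "", "strand"), n_ex),
    tx_id = rep(names(txs), n_ex)
  )
}

#' Read a two-column chrom.sizes file
#'
#' @param path text file with `chrom<TAB>length` rows.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, col.names = c("chrom", "size"))
  setNames(as.numeric(dt$size), dt$chrom)
}

# ---- annotation ingestion ----------------------------------------------------

validate_tabular <- function(path, min_fields, what) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  bad <- which(keep)[nf < min_fields]
  if (length(bad))
    stop("malformed ", what, " record at line ", bad[1], " of ", path,
         " (expected >= ", min_fields, " tab-separated fields)")
  invisible(TRUE)
}

#' Load transcript models from GTF or BED12
#'
#' Coordinates are normalized to 0-based half-open on ingest (GTF is 1-based
#' closed on disk; BED12 is already 0-based half-open). Transcripts whose
#' declared CDS is not covered by their exons are rejected; a single warning
#' reports how many were dropped.
#'
#' @param path annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @param chrom_sizes optional named numeric vector (or a chrom.sizes file
#'   path) giving chromosome lengths; inferred from the annotation if absent.
#' @return a [transcript_catalog()].
#' @export
load_transcripts <- function(path, dialect = c("gtf", "bed12"),
                             chrom_sizes = NULL) {
  dialect <- match.arg(dialect)
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  validate_tabular(path, if (dialect == "gtf") 9 else 12, toupper(dialect))
  rejected <- 0L
  txs <- list()
  if (dialect == "bed12") {
    g <- rtracklayer::import(path, format = "bed")
    for (i in seq_along(g)) {
      rec_start0 <- GenomicRanges::start(g)[i] - 1
      bl <- g$blocks[[i]]
      exons <- cbind(rec_start0 + IRanges::start(bl) - 1,
                     rec_start0 + IRanges::end(bl))
      th <- g$thick[i]
      has_cds <- IRanges::width(th) > 0
      strand_i <- as.character(GenomicRanges::strand(g))[i]
      if (!strand_i %in% c("+", "-"))
        stop("malformed BED12 record ", i, ": strand must be + or -")
      m <- try(transcript_model(
        transcript_id = g$name[i], gene_id = g$name[i],
        chrom = as.character(GenomicRanges::seqnames(g))[i],
        strand = strand_i, exons = exons,
        cds_start = if (has_cds) IRanges::start(th) - 1 else NA,
        cds_end = if (has_cds) IRanges::end(th) else NA
      ), silent = TRUE)
      if (inherits(m, "try-error")) rejected <- rejected + 1L else
        txs[[length(txs) + 1L]] <- m
    }
  } else {
    g <- rtracklayer::import(path, format = "gtf")
    g <- g[g$type %in% c("exon", "CDS")]
    if (!length(g)) stop("no exon/CDS records in GTF ", path)
    ids <- g$transcript_id
    for (id in unique(ids)) {
      sub <- g[ids == id]
      ex <- sub[sub$type == "exon"]
      if (!length(ex)) ex <- sub  # CDS-only records double as exons
      exons <- cbind(GenomicRanges::start(ex) - 1, GenomicRanges::end(ex))
      cds <- sub[sub$type == "CDS"]
      gene <- if (!is.null(sub$gene_id) && !is.na(sub$gene_id[1]))
        sub$gene_id[1] else id
      m <- try(transcript_model(
        transcript_id = id, gene_id = gene,
        chrom = as.character(GenomicRanges::seqnames(sub))[1],
        strand = as.character(GenomicRanges::strand(sub))[1],
        exons = exons,
        cds_start = if (length(cds)) min(GenomicRanges::start(cds)) - 1 else NA,
        cds_end = if (length(cds)) max(GenomicRanges::end(cds)) else NA
      ), silent = TRUE)
      if (inherits(m, "try-error")) rejected <- rejected + 1L else
        txs[[length(txs) + 1L]] <- m
    }
  }
  if (rejected > 0)
    warning(rejected, " transcript(s) rejected (CDS outside exons or invalid)")
  transcript_catalog(txs, chrom_sizes)
}

#' Keep the longest CDS-containing isoform per gene
#'
#' Metagene and region-density summaries use one representative isoform per
#' gene; the default representative is the isoform with the longest CDS
#' (ties broken by mature length, then id).
#'
#' @param catalog a [transcript_catalog()].
#' @return filtered catalog.
#' @export
longest_cds_isoform <- function(catalog) {
  txs <- catalog$transcripts
  genes <- vapply(txs, `[[`, "", "gene_id")
  cdsl <- vapply(txs, function(m) ifelse(is.na(m$cds_len), -1, m$cds_len), 0)
  matl <- vapply(txs, `[[`, 0, "mature_length")
  keep <- unlist(lapply(split(seq_along(txs), genes), function(ii) {
    ii[order(-cdsl[ii], -matl[ii], names(txs)[ii])][1]
  }), use.names = FALSE)
  transcript_catalog(txs[sort(keep)], catalog$chrom_sizes)
}

# ---- read ends ---------------------------------------------------------------

#' Construct a set of read 5'-end records
#'
#' The unit of RT-stop profiling: each record is the 5' end of one aligned
#' read, i.e. the base where reverse transcription terminated.
#'
#' @param reads data.frame with columns `chrom`, `strand`, `pos5` (0-based),
#'   `length`.
#' @param total total mapped-read count of the library before any filtering
#'   (defaults to `nrow(reads)`).
#' @param library `"BG4"` or `"IgG"` (or other label).
#' @param condition condition label (e.g. `"GV"`, `"MII_DMSO"`, `"MII_BYBX"`).
#' @param n_skipped records dropped on ingest (e.g. unknown strand).
#' @return object of class `ReadEndSet`.
#' @export
read_end_set <- function(reads, total = nrow(reads), library = NA_character_,
                         condition = NA_character_, n_skipped = 0L) {
  reads <- as.data.table(reads)
  stopifnot(all(c("chrom", "strand", "pos5", "length") %in% names(reads)))
  if (nrow(reads)) {
    if (any(reads$pos5 < 0)) stop("pos5 must be >= 0")
    if (any(reads$length <= 0)) stop("read length must be > 0")
  }
  if (total < nrow(reads)) stop("total must be >= number of records")
  structure(list(reads = reads, total = total, library = library,
                 condition = condition, n_skipped = as.integer(n_skipped)),
            class = "ReadEndSet")
}

#' @export
print.ReadEndSet <- function(x, ...) {
  cat("ReadEndSet:", nrow(x$reads), "records (total mapped", x$total, ")",
      "library", x$library, "condition", x$condition, "\n")
  invisible(x)
}

cigar_ref_span <- function(cigar) {
  spans <- numeric(length(cigar))
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  for (i in seq_along(cigar)) {
    toks <- regmatches(cigar[i], ops[i])[[1]]
    w <- as.numeric(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    spans[i] <- sum(w[op %in% c("M", "D", "N", "=", "X")])
  }
  spans
}

#' Read aligned read 5'-ends from BED6 or minimal SAM
#'
#' For BED6, the 5' end of a plus-strand read is the interval start and of a
#' minus-strand read the interval's last base (`end - 1`). For SAM, the FLAG
#' strand bit (0x10) is honored and the minus-strand 5' end is the rightmost
#' aligned base (POS + reference span - 1). Records with an unknown strand
#' (BED) or unmapped flag (SAM) are skipped and counted in `n_skipped`;
#' `total` still counts them.
#'
#' @param path input file.
#' @param dialect `"bed6"` or `"sam"`.
#' @param library,condition labels stored on the returned set.
#' @return a [read_end_set()].
#' @export
read_read_ends <- function(path, dialect = c("bed6", "sam"),
                           library = NA_character_, condition = NA_character_) {
  dialect <- match.arg(dialect)
  if (dialect == "bed6") {
    validate_tabular(path, 6, "BED6")
    dt <- fread(path, header = FALSE, sep = "\t",
                col.names = c("chrom", "start", "end", "name", "score",
                              "strand")[1:6])
    n_total <- nrow(dt)
    ok <- dt$strand %in% c("+", "-")
    n_skip <- sum(!ok)
    dt <- dt[ok]
    reads <- data.table(
      chrom = dt$chrom, strand = dt$strand,
      pos5 = ifelse(dt$strand == "+", dt$start, dt$end - 1),
      length = dt$end - dt$start
    )
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^@", lines) & nzchar(lines)]
    n_total <- length(lines)
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 6))
      stop("malformed SAM record at data line ", which(nf < 6)[1])
    flag <- as.integer(vapply(f, `[[`, "", 2))
    mapped <- bitwAnd(flag, 4L) == 0L
    n_skip <- sum(!mapped)
    f <- f[mapped]; flag <- flag[mapped]
    rname <- vapply(f, `[[`, "", 3)
    pos1 <- as.numeric(vapply(f, `[[`, "", 4))
    cigar <- vapply(f, `[[`, "", 6)
    span <- cigar_ref_span(cigar)
    minus <- bitwAnd(flag, 16L) != 0L
    reads <- data.table(
      chrom = rname, strand = ifelse(minus, "-", "+"),
      pos5 = ifelse(minus, pos1 - 1 + span - 1, pos1 - 1),
      length = span
    )
  }
  read_end_set(reads, total = n_total, library = library,
               condition = condition, n_skipped = n_skip)
}

#' Write a ReadEndSet as BED6
#'
#' Inverse of [read_read_ends()] on the BED6 dialect: the written intervals
#' reproduce `pos5` and `length` bit-exactly on re-ingest.
#'
#' @param reads a [read_end_set()].
#' @param path output file.
#' @export
write_bed <- function(reads, path) {
  r <- reads$reads
  start <- ifelse(r$strand == "+", r$pos5, r$pos5 - r$length + 1)
  out <- data.table(chrom = r$chrom, start = as.integer(start),
                    end = as.integer(start + r$length),
                    name = paste0("r", seq_len(nrow(r))), score = 0L,
                    strand = r$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a transcript catalog as BED12
#'
#' @param catalog a [transcript_catalog()].
#' @param path output file.
#' @export
write_bed12 <- function(catalog, path) {
  rows <- lapply(catalog$transcripts, function(m) {
    s <- m$exons[1, 1]
    e <- m$exons[nrow(m$exons), 2]
    has_cds <- !is.na(m$cds_start)
    data.table(
      chrom = m$chrom, start = as.integer(s), end = as.integer(e),
      name = m$transcript_id, score = 0L, strand = m$strand,
      thickStart = as.integer(if (has_cds) m$cds_start else s),
      thickEnd = as.integer(if (has_cds) m$cds_end else s),
      rgb = "0", blockCount = nrow(m$exons),
      blockSizes = paste0(paste(as.integer(m$exons[, 2] - m$exons[, 1]),
                                collapse = ","), ","),
      blockStarts = paste0(paste(as.integer(m$exons[, 1] - s),
                                 collapse = ","), ",")
    )
  })
  fwrite(rbindlist(rows), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Spliced mature sequence of a transcript
#'
#' @param model a [transcript_model()].
#' @param genome a named `DNAStringSet` (as from
#'   `Biostrings::readDNAStringSet`).
#' @return character string of the mature transcript, 5'->3' (reverse
#'   complement of the genomic plus strand for minus-strand transcripts).
#' @export
mature_sequence <- function(model, genome) {
  chrom_seq <- genome[[model$chrom]]
  pieces <- vapply(seq_len(nrow(model$exons)), function(i) {
    as.character(Biostrings::subseq(chrom_seq, model$exons[i, 1] + 1,
                                    model$exons[i, 2]))
  }, "")
  s <- paste(pieces, collapse = "")
  if (model$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}
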