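#!/usr/bin/env Rscript
# Stage 3: quantify the rG4 signal — TSS metaprofiles, peak-centred
# matrices, per-region RPKM densities (the 5'UTR > 3'UTR > CDS density
# ordering), and the sequence view: PQS scanning of peak-upstream
# sequences plus 6-mer enrichment over shuffled background.
source("analysis/config.R")

catalog <- load_transcripts(file.path(OUT, "sim", "transcripts.bed12"),
                            "bed12",
                            chrom_sizes = file.path(OUT, "sim", "chrom.sizes"))
genome <- Biostrings::readDNAStringSet(file.path(OUT, "sim", "genome.fa"))
names(genome) <- sub(" .*", "", names(genome))
tsses <- t(vapply(catalog$transcripts, tss_tes, c(tss = 0, tes = 0)))
anchors <- data.frame(
  chrom = vapply(catalog$transcripts, `[[`, "", "chrom"),
  pos = tsses[, "tss"],
  strand = vapply(catalog$transcripts, `[[`, "", "strand"))

for (cond in CONDITIONS) {
  bg4 <- deduplicate(read_read_ends(
    file.path(OUT, sprintf("reads_%s_BG4.bed", cond)), "bed6"))
  tr <- coverage(bg4, catalog, bin = PARAMS$bin)
  mp <- metaprofile(tr, anchors, w = PARAMS$meta_w)
  data.table::fwrite(data.table::data.table(offset = mp$offsets,
                                            signal = mp$profile),
                     file.path(OUT, sprintf("metaprofile_TSS_%s.tsv", cond)),
                     sep = "\t")
  dens <- region_density(bg4, catalog)
  data.table::fwrite(dens, file.path(OUT, sprintf("density_%s.tsv", cond)),
                     sep = "\t")
  pooled <- sapply(c("utr5", "cds", "utr3"), function(rg) {
    d <- dens[dens$region == rg]
    sum(d$reads) * 1e9 / (sum(d$length) * bg4$total)
  })
  message(sprintf("%s pooled region RPKM: 5'UTR %.1f | CDS %.1f | 3'UTR %.1f",
                  cond, pooled["utr5"], pooled["cds"], pooled["utr3"]))

  pk <- as.data.frame(read.table(
    file.path(OUT, sprintf("peaks_%s.narrowPeak", cond)), sep = "\t"))
  names(pk)[c(1, 2, 3, 6, 10)] <- c("chrom", "start", "end", "strand", "peak")
  pk$summit <- pk$start + pk$peak
  seqs <- peak_upstream_sequences(pk, genome, ext = PARAMS$ext)
  writeLines(paste0(">", names(seqs), "\n", seqs),
             file.path(OUT, sprintf("peak_sequences_%s.fa", cond)))
  pqs_n <- sum(vapply(seqs, function(s) nrow(scan_pqs(s)), 0L))
  shuffled <- vapply(seqs, function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), "")
  enr <- g_enrichment(seqs, shuffled)
  data.table::fwrite(head(enr, 50),
                     file.path(OUT, sprintf("kmer_enrichment_%s.tsv", cond)),
                     sep = "\t")
  message(sprintf("%s: %d/%d peak sequences contain a canonical PQS; top 6-mer %s (log2 %.2f)",
                  cond, pqs_n, length(seqs), enr$kmer[1],
                  enr$log2_enrichment[1]))
}
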