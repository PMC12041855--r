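#!/usr/bin/env Rscript
# Stage 2: deduplicate read ends, build 10 nt stranded coverage, call
# RT-stop peaks (BG4 vs IgG, Poisson enrichment, FE >= 2, p <= 0.05) and
# annotate summits with genomic features. The feature distribution is the
# pie-chart-style summary of where rG4 peaks live per condition.
source("analysis/config.R")

catalog <- load_transcripts(file.path(OUT, "sim", "transcripts.bed12"),
                            "bed12",
                            chrom_sizes = file.path(OUT, "sim", "chrom.sizes"))
for (cond in CONDITIONS) {
  bg4 <- deduplicate(read_read_ends(
    file.path(OUT, sprintf("reads_%s_BG4.bed", cond)), "bed6",
    library = "BG4", condition = cond))
  igg <- deduplicate(read_read_ends(
    file.path(OUT, sprintf("reads_%s_IgG.bed", cond)), "bed6",
    library = "IgG", condition = cond))
  tr <- coverage(bg4, catalog, bin = PARAMS$bin)
  ct <- coverage(igg, catalog, bin = PARAMS$bin)
  write_bedgraph(tr, file.path(OUT, sprintf("coverage_%s_BG4", cond)))
  pk <- call_peaks(tr, ct, p_cutoff = PARAMS$p_cutoff,
                   fe_cutoff = PARAMS$fe_cutoff, min_gap = PARAMS$min_gap)
  write_narrowpeak(pk, file.path(OUT, sprintf("peaks_%s.narrowPeak", cond)))
  anno <- annotate_peaks(pk, catalog)
  data.table::fwrite(anno,
                     file.path(OUT, sprintf("peaks_%s_annotated.tsv", cond)),
                     sep = "\t")
  message(sprintf("%s: %d peaks after dedup (%d BG4 / %d IgG read ends)",
                  cond, nrow(pk), bg4$total, igg$total))
  print(table(anno$feature))
}
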