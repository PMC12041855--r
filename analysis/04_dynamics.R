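#!/usr/bin/env Rscript
# Stage 4: classify transcripts by rG4 occupancy across maturation
# (GV vs MII + vehicle) and treatment (vehicle vs ligand at MII): Venn
# clusters with a hypergeometric overlap test, per-transcript density
# ratios, and removal-blockade categories for transcripts that carried
# rG4s at GV.
source("analysis/config.R")

catalog <- load_transcripts(file.path(OUT, "sim", "transcripts.bed12"),
                            "bed12",
                            chrom_sizes = file.path(OUT, "sim", "chrom.sizes"))
read_peaks <- function(cond) {
  p <- read.table(file.path(OUT, sprintf("peaks_%s.narrowPeak", cond)),
                  sep = "\t")
  names(p)[c(1, 2, 3, 6, 10)] <- c("chrom", "start", "end", "strand", "peak")
  p$summit <- p$start + p$peak
  p
}
ref <- CONDITIONS[1]; ctl <- CONDITIONS[2]; trt <- CONDITIONS[3]
sets_mat <- rg4_transcript_sets(read_peaks(ref), read_peaks(ctl), catalog)
sets_trt <- rg4_transcript_sets(read_peaks(ctl), read_peaks(trt), catalog)
message("maturation clusters (A = ", ref, ", B = ", ctl, "):")
print(sets_mat$counts)
pval <- overlap_significance(sets_mat$counts[["A"]], sets_mat$counts[["B"]],
                             sets_mat$counts[["shared"]],
                             length(catalog$transcripts))
message(sprintf("overlap significance (hypergeometric upper tail): p = %.3g",
                pval))
data.table::fwrite(sets_mat$table, file.path(OUT, "sets_maturation.tsv"),
                   sep = "\t")
data.table::fwrite(sets_trt$table, file.path(OUT, "sets_treatment.tsv"),
                   sep = "\t")

# rG4 signal density for removal analysis: restricted to reads inside the
# reference-stage (GV) peaks so constant library background cancels out
gv_peaks <- read_peaks(ref)
full_density <- function(cond) {
  bg4 <- deduplicate(read_read_ends(
    file.path(OUT, sprintf("reads_%s_BG4.bed", cond)), "bed6"))
  d <- region_density(bg4, catalog, regions = "full", peaks = gv_peaks)
  setNames(d$rpkm, d$transcript_id)
}
dg <- full_density(ref); dd <- full_density(ctl); db <- full_density(trt)
gv_pos <- names(dg) %in%
  sets_mat$table$transcript_id[sets_mat$table$in_A]
rem <- removal_categories(dg, dd, db, gv_positive = gv_pos,
                          removal_fc = PARAMS$removal_fc,
                          lo = PARAMS$rho_lo, hi = PARAMS$rho_hi,
                          eps = PARAMS$eps)
dyn <- data.table::data.table(
  transcript_id = names(dg), d_ref = dg, d_ctl = dd, d_trt = db,
  log2_trt_vs_ctl = density_ratio(db, dd, eps = PARAMS$eps),
  rho = rem$rho, category = rem$category)
data.table::fwrite(dyn, file.path(OUT, "dynamics.tsv"), sep = "\t")
message("removal-blockade categories (GV-positive transcripts):")
print(table(dyn$category))
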