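#!/usr/bin/env Rscript
# Stage 1: build the synthetic study. One toy chromosome per transcript,
# 50 planted canonical PQS sites (5'UTR-enriched), foldedness high at GV,
# removed at MII under vehicle, re-stabilized under the rG4 ligand. Writes
# the genome, annotation, truth tables, and one read-end BED per
# condition x library.
source("analysis/config.R")

sim <- simulate_transcriptome(CFG)
write_simulation(sim, file.path(OUT, "sim"))
message(sprintf("transcriptome: %d transcripts, %d planted sites (%d skipped)",
                length(sim$catalog$transcripts), nrow(sim$truth$sites),
                sim$truth$n_skipped_sites))
print(table(sim$truth$sites$region))

for (cond in CONDITIONS) {
  for (lib in c("BG4", "IgG")) {
    rs <- simulate_lace_reads(sim, CFG, cond, lib)
    write_bed(rs, file.path(OUT, sprintf("reads_%s_%s.bed", cond, lib)))
    message(sprintf("%s %s: %d read ends", cond, lib, rs$total))
  }
}
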