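#!/usr/bin/env Rscript
# Stage 5: the translatome view. Spike-normalized FPKM for mRNA and RPF
# libraries, translational efficiency TE = RPF/mRNA, fold-change classes
# (maturation and treatment), integration of TE change with the rG4
# density change, and RBP binding-change classes.
source("analysis/config.R")

sim <- simulate_transcriptome(CFG)   # deterministic: same seed as stage 1
ref <- CONDITIONS[1]; ctl <- CONDITIONS[2]; trt <- CONDITIONS[3]
expr <- lapply(setNames(CONDITIONS, CONDITIONS), function(cond)
  simulate_expression(sim, CFG, cond))
mrna <- vapply(expr, `[[`, expr[[1]]$mrna, "mrna")
rpf <- vapply(expr, `[[`, expr[[1]]$rpf, "rpf")
data.table::fwrite(data.table::data.table(feature_id = rownames(mrna), mrna),
                   file.path(OUT, "counts_mrna.tsv"), sep = "\t")
data.table::fwrite(data.table::data.table(feature_id = rownames(rpf), rpf),
                   file.path(OUT, "counts_rpf.tsv"), sep = "\t")

te <- translational_efficiency(fpkm(rpf, expr[[1]]$cds_lengths),
                               fpkm(mrna, expr[[1]]$tx_lengths),
                               eps = PARAMS$te_eps)
cls_mat <- fold_change_classes(te$te[, ref], te$te[, ctl],
                               fc_up = PARAMS$fc_up, fc_down = PARAMS$fc_down)
cls_trt <- fold_change_classes(te$te[, ctl], te$te[, trt],
                               fc_up = PARAMS$fc_up, fc_down = PARAMS$fc_down)
names(cls_mat) <- names(cls_trt) <- rownames(te$te)
message("TE classes, maturation (", ctl, " vs ", ref, "):")
print(table(cls_mat))
message("TE classes, treatment (", trt, " vs ", ctl, "):")
print(table(cls_trt))

dyn <- data.table::fread(file.path(OUT, "dynamics.tsv"))
delta <- setNames(dyn$log2_trt_vs_ctl, dyn$transcript_id)[rownames(te$te)]
integ <- integrate_rg4_te(delta, cls_trt,
                          maturation_te_up = names(cls_mat)[cls_mat == "up"])
message("rG4 x TE quadrants (treatment):")
print(integ$quadrants)
out <- data.table::data.table(transcript_id = rownames(te$te), te$te,
                              low_confidence = te$low_confidence,
                              te_class_maturation = cls_mat,
                              te_class_treatment = cls_trt,
                              delta_rg4 = delta)
data.table::fwrite(out, file.path(OUT, "translatome.tsv"), sep = "\t")

rbp <- classify_rbp_binding(simulate_rbp_intensities(CFG))
data.table::fwrite(rbp, file.path(OUT, "rbp_classes.tsv"), sep = "\t")
message("RBP binding classes:")
print(table(rbp$class))
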