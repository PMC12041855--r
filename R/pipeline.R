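# End-to-end orchestration of the synthetic study: simulate, call peaks,
# quantify, classify dynamics, integrate the translatome, and report.
# Every artifact is a plain-text TSV/JSON/BED file and every byte is a
# deterministic function of the configuration (seed included).

#' Analysis thresholds for the pipeline
#'
#' @param p_cutoff,fe_cutoff,min_gap peak-calling parameters, see
#'   [call_peaks()].
#' @param bin coverage bin size in nt.
#' @param meta_w,peak_w metagene and peak-matrix half-windows in nt.
#' @param ext 5' extension for peak sequence extraction in nt.
#' @param fc_up,fc_down fold-change class thresholds.
#' @param removal_fc,rho_lo,rho_hi,eps removal-category parameters, see
#'   [removal_categories()].
#' @param te_eps TE pseudocount on the FPKM scale.
#' @return list of class `PipelineParams`.
#' @export
pipeline_params <- function(p_cutoff = 0.05, fe_cutoff = 2.0, min_gap = 3L,
                            bin = 10L, meta_w = 1000L, peak_w = 500L,
                            ext = 30L, fc_up = 2, fc_down = 0.5,
                            removal_fc = 2, rho_lo = 0.25, rho_hi = 0.75,
                            eps = 0.01, te_eps = 0.1) {
  p <- as.list(environment())
  stopifnot(p$p_cutoff > 0, p$p_cutoff <= 1, p$fe_cutoff >= 1,
            p$bin >= 1, p$fc_down < 1, p$fc_up > 1,
            p$rho_lo < p$rho_hi, p$eps > 0, p$te_eps > 0)
  structure(p, class = "PipelineParams")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full synthetic-study pipeline
#'
#' Simulates the transcriptome and all libraries under `cfg`, then runs
#' every analysis stage: deduplication, coverage, peak calling against the
#' IgG control per condition, peak annotation, TSS metaprofiles, per-region
#' densities, stage/treatment set classification, removal-blockade
#' categories, spike-normalized expression, TE and fold-change classes,
#' rG4 x TE integration, and RBP binding classes. Writes all tables under
#' `outdir` and returns them invisibly. Two runs with the same `cfg` and
#' `params` produce byte-identical artifacts.
#'
#' The first three configured conditions are used as the maturation
#' reference (GV), the treated-stage control (MII + vehicle) and the
#' treated stage (MII + ligand) respectively.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory.
#' @param params a [pipeline_params()].
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(cfg, outdir, params = pipeline_params()) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            inherits(params, "PipelineParams"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  conds <- names(cfg$foldedness)

  stage_log("simulate", "transcriptome with ", cfg$n_sites, " planted sites")
  sim <- simulate_transcriptome(cfg)
  write_simulation(sim, file.path(outdir, "sim"))

  peak_sets <- list(); densities <- list(); dedup_sets <- list()
  for (cond in conds) {
    bg4 <- simulate_lace_reads(sim, cfg, cond, "BG4")
    igg <- simulate_lace_reads(sim, cfg, cond, "IgG")
    write_bed(bg4, file.path(outdir, sprintf("reads_%s_BG4.bed", cond)))
    write_bed(igg, file.path(outdir, sprintf("reads_%s_IgG.bed", cond)))
    bg4d <- deduplicate(bg4); iggd <- deduplicate(igg)
    stage_log("dedup", cond, " BG4 ", bg4$total, " -> ", bg4d$total,
              "; IgG ", igg$total, " -> ", iggd$total)
    tr <- coverage(bg4d, sim$catalog, bin = params$bin)
    ct <- coverage(iggd, sim$catalog, bin = params$bin)
    write_bedgraph(tr, file.path(outdir, sprintf("coverage_%s_BG4", cond)))
    pk <- call_peaks(tr, ct, p_cutoff = params$p_cutoff,
                     fe_cutoff = params$fe_cutoff, min_gap = params$min_gap)
    anno <- annotate_peaks(pk, sim$catalog)
    write_narrowpeak(pk, file.path(outdir, sprintf("peaks_%s.narrowPeak", cond)))
    fwrite(anno, file.path(outdir, sprintf("peaks_%s_annotated.tsv", cond)),
           sep = "\t")
    stage_log("callpeaks", cond, ": ", nrow(pk), " peaks")
    dens <- region_density(bg4d, sim$catalog)
    fwrite(dens, file.path(outdir, sprintf("density_%s.tsv", cond)), sep = "\t")
    tsses <- t(vapply(sim$catalog$transcripts, tss_tes, c(tss = 0, tes = 0)))
    anchors <- data.frame(
      chrom = vapply(sim$catalog$transcripts, `[[`, "", "chrom"),
      pos = tsses[, "tss"],
      strand = vapply(sim$catalog$transcripts, `[[`, "", "strand"))
    mp <- metaprofile(tr, anchors, w = params$meta_w)
    fwrite(data.table(offset = mp$offsets, signal = mp$profile),
           file.path(outdir, sprintf("metaprofile_TSS_%s.tsv", cond)),
           sep = "\t")
    jsonlite::write_json(
      list(anchor = "TSS", w = params$meta_w, bin = params$bin,
           n_anchors = mp$n_anchors, normalization = mp$normalization),
      file.path(outdir, sprintf("metaprofile_TSS_%s.json", cond)),
      auto_unbox = TRUE, digits = NA)
    peak_sets[[cond]] <- pk; densities[[cond]] <- dens
    dedup_sets[[cond]] <- bg4d
  }

  # ---- dynamics over the first three conditions ----
  dynamics <- NULL
  if (length(conds) >= 3) {
    ref <- conds[1]; ctl <- conds[2]; trt <- conds[3]
    sets_mat <- rg4_transcript_sets(peak_sets[[ref]], peak_sets[[ctl]],
                                    sim$catalog)
    sets_trt <- rg4_transcript_sets(peak_sets[[ctl]], peak_sets[[trt]],
                                    sim$catalog)
    # rG4 signal density for removal analysis: reads inside the
    # reference-stage peak set, so constant library background does not
    # mask the condition contrast
    full_d <- function(cond) {
      d <- region_density(dedup_sets[[cond]], sim$catalog,
                          regions = "full", peaks = peak_sets[[ref]])
      setNames(d$rpkm, d$transcript_id)
    }
    dg <- full_d(ref); dd <- full_d(ctl); db <- full_d(trt)
    gv_pos <- names(dg) %in%
      sets_mat$table[sets_mat$table$in_A == TRUE]$transcript_id
    rem <- removal_categories(dg, dd, db, gv_positive = gv_pos,
                              removal_fc = params$removal_fc,
                              lo = params$rho_lo, hi = params$rho_hi,
                              eps = params$eps)
    rem[, transcript_id := names(dg)]
    ratio <- density_ratio(db, dd, eps = params$eps)
    dyn_tab <- data.table(transcript_id = names(dg),
                          d_ref = dg, d_ctl = dd, d_trt = db,
                          log2_trt_vs_ctl = ratio,
                          rho = rem$rho, category = rem$category)
    fwrite(dyn_tab, file.path(outdir, "dynamics.tsv"), sep = "\t")
    fwrite(sets_mat$table, file.path(outdir, "sets_maturation.tsv"), sep = "\t")
    fwrite(sets_trt$table, file.path(outdir, "sets_treatment.tsv"), sep = "\t")
    dynamics <- list(maturation = sets_mat, treatment = sets_trt,
                     removal = dyn_tab)
    stage_log("dynamics", "maturation clusters: ",
              paste(names(sets_mat$counts), sets_mat$counts,
                    sep = "=", collapse = " "))
  }

  # ---- translatome ----
  translatome <- NULL
  if (length(conds) >= 3) {
    ref <- conds[1]; ctl <- conds[2]; trt <- conds[3]
    expr <- lapply(conds[1:3], function(cond)
      simulate_expression(sim, cfg, cond))
    names(expr) <- conds[1:3]
    mrna_counts <- vapply(expr, `[[`, expr[[1]]$mrna, "mrna")
    rpf_counts <- vapply(expr, `[[`, expr[[1]]$rpf, "rpf")
    fwrite(data.table(feature_id = rownames(mrna_counts), mrna_counts),
           file.path(outdir, "counts_mrna.tsv"), sep = "\t")
    fwrite(data.table(feature_id = rownames(rpf_counts), rpf_counts),
           file.path(outdir, "counts_rpf.tsv"), sep = "\t")
    fp_m <- fpkm(mrna_counts, expr[[1]]$tx_lengths)
    fp_r <- fpkm(rpf_counts, expr[[1]]$cds_lengths)
    te <- translational_efficiency(fp_r, fp_m, eps = params$te_eps)
    te_cls_trt <- fold_change_classes(te$te[, ctl], te$te[, trt],
                                      fc_up = params$fc_up,
                                      fc_down = params$fc_down)
    names(te_cls_trt) <- rownames(te$te)
    te_cls_mat <- fold_change_classes(te$te[, ref], te$te[, ctl],
                                      fc_up = params$fc_up,
                                      fc_down = params$fc_down)
    names(te_cls_mat) <- rownames(te$te)
    # rG4 change on the same in-peak density scale as the dynamics stage
    delta <- density_ratio(db[rownames(te$te)], dd[rownames(te$te)],
                           eps = params$eps)
    names(delta) <- rownames(te$te)
    integ <- integrate_rg4_te(delta, te_cls_trt,
                              maturation_te_up =
                                names(te_cls_mat)[te_cls_mat == "up"])
    te_tab <- data.table(transcript_id = rownames(te$te), te$te,
                         low_confidence = te$low_confidence,
                         te_class_treatment = te_cls_trt,
                         te_class_maturation = te_cls_mat,
                         delta_rg4 = delta)
    fwrite(te_tab, file.path(outdir, "translatome.tsv"), sep = "\t")
    stage_log("translatome", "TE classes (treatment): ",
              paste(names(table(te_cls_trt)), table(te_cls_trt),
                    sep = "=", collapse = " "))
    translatome <- list(te = te, classes_treatment = te_cls_trt,
                        classes_maturation = te_cls_mat,
                        integration = integ)
  }

  # ---- RBP binding classes ----
  rbp <- simulate_rbp_intensities(cfg)
  rbp_cls <- classify_rbp_binding(rbp)
  fwrite(rbp_cls, file.path(outdir, "rbp_classes.tsv"), sep = "\t")
  stage_log("rbp", paste(names(table(rbp_cls$class)), table(rbp_cls$class),
                         sep = "=", collapse = " "))

  # ---- report ----
  report <- list(
    params = unclass(params),
    seed = cfg$seed,
    conditions = conds,
    n_transcripts = cfg$n_transcripts,
    n_planted_sites = nrow(sim$truth$sites),
    peaks_per_condition = lapply(peak_sets, nrow),
    overlap_test = "hypergeometric upper tail (standard overlap enrichment test)"
  )
  if (!is.null(dynamics)) {
    report$maturation_clusters <- as.list(dynamics$maturation$counts)
    report$treatment_clusters <- as.list(dynamics$treatment$counts)
    report$removal_categories <-
      as.list(table(dynamics$removal$category))
  }
  if (!is.null(translatome)) {
    report$te_classes_treatment <-
      as.list(table(translatome$classes_treatment))
    report$quadrants <- as.list(as.vector(translatome$integration$quadrants))
    names(report$quadrants) <- outer(
      rownames(translatome$integration$quadrants),
      colnames(translatome$integration$quadrants),
      function(a, b) paste(a, b, sep = "|"))
  }
  report$rbp_classes <- as.list(table(rbp_cls$class))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, peaks = peak_sets, densities = densities,
                 dynamics = dynamics, translatome = translatome,
                 rbp = rbp_cls, report = report))
}
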