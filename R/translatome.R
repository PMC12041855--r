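# Spike-in-normalized expression, translational efficiency, fold-change
# classes, rG4 x TE integration, and RBP binding-change classes.

#' Spike-in-normalized FPKM
#'
#' `FPKM_t = count_t x 1e9 / (L_t x E_s)`, where `E_s` is the total
#' spike-in-mapped read count of sample `s`. Normalizing to the spike-in
#' total (rather than the library total) preserves absolute scale across
#' samples: a per-sample depth nuisance factor multiplies counts and `E_s`
#' alike and cancels. An alternative median-of-ratios scale over the
#' spike-in rows is available via `method = "median_ratio"`.
#'
#' @param counts named numeric vector (one sample) or matrix (features x
#'   samples) of raw counts, spike-in rows included.
#' @param lengths named numeric vector of feature lengths in nt for the
#'   non-spike-in features.
#' @param ercc_ids spike-in row ids, or a regular expression matched against
#'   rownames when of length 1 (default `"^ERCC-"`).
#' @param method `"total"` (default) or `"median_ratio"`.
#' @return object of class `ExpressionTable`: list with `fpkm` (matrix,
#'   spike-in rows excluded), `ercc_total` per sample, `scale` per sample,
#'   and `method`.
#' @export
fpkm <- function(counts, lengths, ercc_ids = "^ERCC-",
                 method = c("total", "median_ratio")) {
  method <- match.arg(method)
  if (is.null(dim(counts))) counts <- cbind(sample1 = counts)
  ids <- rownames(counts)
  is_ercc <- if (length(ercc_ids) == 1 && !ercc_ids %in% ids)
    grepl(ercc_ids, ids) else ids %in% ercc_ids
  if (!any(is_ercc)) stop("no spike-in rows found")
  ercc_total <- colSums(counts[is_ercc, , drop = FALSE])
  zero <- ercc_total == 0
  if (any(zero))
    stop("sample(s) without spike-in reads: ",
         paste(colnames(counts)[zero], collapse = ", "))
  scale <- if (method == "total") ercc_total else {
    ref <- rowMeans(counts[is_ercc, , drop = FALSE])
    apply(counts[is_ercc, , drop = FALSE], 2, function(cc) {
      r <- cc[ref > 0] / ref[ref > 0]
      stats::median(r) * sum(ref)
    })
  }
  feats <- ids[!is_ercc]
  L <- lengths[feats]
  if (anyNA(L)) stop("missing lengths for: ",
                     paste(head(feats[is.na(L)], 3), collapse = ", "))
  f <- sweep(counts[!is_ercc, , drop = FALSE], 2, scale, "/") * 1e9 / L
  structure(list(fpkm = f, ercc_total = ercc_total, scale = scale,
                 method = method),
            class = "ExpressionTable")
}

#' Translational efficiency from RPF and mRNA expression
#'
#' `TE = (RPF + eps) / (mRNA + eps)` per transcript and sample.
#' Transcripts below the minimum-expression floor (mRNA FPKM >= `min_mrna`
#' in at least one sample) are flagged low-confidence, not removed.
#'
#' @param rpf,mrna [fpkm()] results (or bare matrices) on a shared
#'   transcript index and shared sample columns.
#' @param eps pseudocount on the FPKM scale (default 0.1).
#' @param min_mrna low-confidence floor on mRNA FPKM (default 1).
#' @return object of class `TranslatomeTable`: list with `te` matrix,
#'   `low_confidence` logical vector, and the inputs' FPKM matrices.
#' @export
translational_efficiency <- function(rpf, mrna, eps = 0.1, min_mrna = 1) {
  R <- if (inherits(rpf, "ExpressionTable")) rpf$fpkm else as.matrix(rpf)
  M <- if (inherits(mrna, "ExpressionTable")) mrna$fpkm else as.matrix(mrna)
  common <- intersect(rownames(R), rownames(M))
  if (!length(common)) stop("no shared transcripts between RPF and mRNA")
  R <- R[common, , drop = FALSE]; M <- M[common, , drop = FALSE]
  te <- (R + eps) / (M + eps)
  lowconf <- apply(M, 1, function(x) all(x < min_mrna))
  structure(list(te = te, low_confidence = lowconf, rpf_fpkm = R,
                 mrna_fpkm = M, eps = eps, min_mrna = min_mrna),
            class = "TranslatomeTable")
}

#' Fold-change classes between two value vectors
#'
#' `up` iff `alt/ref > fc_up`, `down` iff `alt/ref < fc_down`, else
#' `unchanged` — strict inequalities, so a ratio of exactly 2 with
#' `fc_up = 2` is `unchanged` ("more than 2-fold").
#'
#' @param values_ref,values_alt positive value vectors on a shared index.
#' @param fc_up,fc_down thresholds with `fc_down < 1 < fc_up`
#'   (defaults 2 and 0.5).
#' @param eps pseudocount; required > 0 if any reference value is 0.
#' @return character vector over `{"up","down","unchanged"}`.
#' @export
fold_change_classes <- function(values_ref, values_alt, fc_up = 2,
                                fc_down = 0.5, eps = 0) {
  if (!(fc_down < 1 && 1 < fc_up)) stop("need fc_down < 1 < fc_up")
  if (length(values_ref) != length(values_alt)) stop("length mismatch")
  if (eps <= 0 && any(values_ref <= 0))
    stop("non-positive reference values require eps > 0")
  fc <- (values_alt + eps) / (values_ref + eps)
  ifelse(fc > fc_up, "up", ifelse(fc < fc_down, "down", "unchanged"))
}

#' Integrate rG4 density change with TE change
#'
#' Labels each transcript by the quadrant of (rG4 change, TE class), where
#' the rG4 change is `up` / `down` / `flat` by sign of the log2 density
#' ratio outside a dead band, and emits the headline sets: TE-down with
#' rG4-up, and (when `maturation_te_up` is supplied) their intersection
#' with the maturation-activated translatome.
#'
#' @param delta_rg4 named numeric vector of per-transcript log2 rG4 density
#'   ratios (treatment vs control), already region-filtered by the caller
#'   if a region-specific view is wanted.
#' @param te_classes named character vector from [fold_change_classes()]
#'   on the same transcripts.
#' @param dead_band half-width of the `flat` band on the log2 scale
#'   (default 0: any positive change is `up`).
#' @param maturation_te_up optional character vector of transcripts whose
#'   TE rose during normal maturation.
#' @return list with `table` (per-transcript labels), `quadrants`
#'   (3 x 3 count matrix), and `sets` (named list of transcript id vectors).
#' @export
integrate_rg4_te <- function(delta_rg4, te_classes, dead_band = 0,
                             maturation_te_up = NULL) {
  common <- intersect(names(delta_rg4), names(te_classes))
  if (!length(common)) stop("no shared transcript index")
  d <- delta_rg4[common]; cl <- te_classes[common]
  rg4 <- ifelse(d > dead_band, "rG4_up",
                ifelse(d < -dead_band, "rG4_down", "rG4_flat"))
  tab <- data.table(transcript_id = common, delta_rg4 = d,
                    rg4_class = rg4, te_class = cl)
  quad <- table(factor(rg4, c("rG4_down", "rG4_flat", "rG4_up")),
                factor(cl, c("down", "unchanged", "up")))
  sets <- list(te_down_rg4_up = common[cl == "down" & rg4 == "rG4_up"])
  if (!is.null(maturation_te_up)) {
    sets$te_down_rg4_up_maturation_activated <-
      intersect(sets$te_down_rg4_up, maturation_te_up)
  }
  list(table = tab, quadrants = quad, sets = sets)
}

#' Percentage of one set contained in another
#'
#' @param n_overlap overlap size; `n_set` size of the reference set.
#' @return `100 x n_overlap / n_set`.
#' @export
overlap_percent <- function(n_overlap, n_set) {
  if (n_overlap > n_set || n_set <= 0) stop("impossible overlap")
  100 * n_overlap / n_set
}

#' Classify RBP binding changes from IP/input intensity tables
#'
#' Proteins with zero or negative input intensity are excluded; proteins
#' bound under mock but with zero IP intensity under treatment are
#' completely blocked; the rest are classed by the IP intensity ratio
#' `FC = IP_treat / IP_mock`: `down` below `fc_down`, `up` above `fc_up`,
#' else `unchanged` (strict inequalities). Proteins unbound in both IP
#' samples are `unchanged`. Retained proteins always fall in exactly one
#' class.
#'
#' @param intensities `data.frame` with columns `input`, `IP_mock`,
#'   `IP_bybx` (non-negative; an id column is carried through if present).
#' @param fc_up,fc_down thresholds (defaults 2 and 0.5).
#' @return `data.table` of class `RbpClassTable` with columns of the input
#'   plus `fc` and `class` in
#'   `{down, up, completely_blocked, unchanged, excluded}`.
#' @export
classify_rbp_binding <- function(intensities, fc_up = 2, fc_down = 0.5) {
  x <- as.data.table(intensities)
  stopifnot(all(c("input", "IP_mock", "IP_bybx") %in% names(x)))
  if (any(x$input < 0 | x$IP_mock < 0 | x$IP_bybx < 0))
    stop("negative intensities")
  fc <- ifelse(x$IP_mock > 0, x$IP_bybx / x$IP_mock,
               ifelse(x$IP_bybx > 0, Inf, NaN))
  cls <- rep("unchanged", nrow(x))
  cls[!is.nan(fc) & fc < fc_down] <- "down"
  cls[!is.nan(fc) & fc > fc_up] <- "up"
  cls[x$IP_mock > 0 & x$IP_bybx == 0] <- "completely_blocked"
  cls[x$input <= 0] <- "excluded"
  x[, fc := fc]
  x[, class := cls]
  structure(x[], class = c("RbpClassTable", class(x)))
}
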