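# Germline-vs-somatic classification without a matched blood sample.
#
# Rationale: a heterozygous germline variant sits near VAF 1/2 in every
# fraction regardless of tumor content, so its tumor/residual VAF ratio is
# close to 1 (log2 ratio 0).  A somatic variant's VAF scales with tumor
# purity, which enrichment raises in the tumor fraction and depletion
# lowers in the residual fraction, so its ratio is well above 1.  A single
# threshold on the log2 ratio therefore separates the two origins; the
# threshold is chosen on a ROC curve built against blood-defined truth.

#' Score mutations shared by all three fractions
#'
#' Computes the tumor/residual VAF ratio and its log2 for mutations in
#' Venn group (c) — detected in the unseparated sample, tumor fraction and
#' residual fraction alike (hence all VAFs >= 3% > 0, and the ratio is
#' defined).  A ratio of 1 (no change) maps to log2 ratio 0.  Rows outside
#' group (c) are skipped with a notice, since their ratio is undefined
#' (the group (b) residual-VAF-0 convention applies to plotting exports,
#' not to ratios).
#'
#' @param matched Matched-variant table from [match_across_fractions()]
#'   (one patient or pooled).
#' @return A data frame of ratio scores: key columns, `patient_id`,
#'   `vaf_tumor`, `vaf_residual`, `ratio`, `log_ratio`, and empty
#'   `truth_label` / `predicted_label` columns.
#' @export
score_shared <- function(matched) {
  skip <- matched$group_label != "c"
  if (any(skip)) {
    message(sum(skip), " variant(s) outside group (c) skipped: ",
            "tumor/residual ratio undefined")
  }
  d <- matched[!skip, , drop = FALSE]
  scores <- d[c("chrom", "pos", "ref", "alt", "patient_id",
                "vaf_tumor", "vaf_residual")]
  scores$ratio <- d$vaf_tumor / d$vaf_residual
  scores$log_ratio <- log2(scores$ratio)
  scores$truth_label <- NA_character_
  scores$predicted_label <- NA_character_
  rownames(scores) <- NULL
  scores
}

#' Label ratio scores with blood-defined truth
#'
#' Variant keys identified in whole-exome sequencing of peripheral blood
#' are defined as germline mutations; all others are defined as somatic.
#'
#' @param scores Ratio-score table from [score_shared()].
#' @param blood_keys Data frame of blood-identified variant keys
#'   (`chrom`, `pos`, `ref`, `alt`); may be empty.
#' @return `scores` with `truth_label` filled in (`"GERMLINE"` /
#'   `"SOMATIC"`).
#' @export
attach_blood_truth <- function(scores, blood_keys) {
  bk <- if (is.null(blood_keys) || nrow(blood_keys) == 0) character() else
    variant_key(blood_keys)
  scores$truth_label <- ifelse(variant_key(scores) %in% bk,
                               "GERMLINE", "SOMATIC")
  scores
}

#' ROC curve of a score against binary truth
#'
#' Builds the full ROC curve over all distinct score cutoffs under the
#' strict decision rule `score > threshold` => positive, and computes the
#' area under the curve by the trapezoid rule, which equals the
#' tie-adjusted Mann-Whitney probability (ties counted 1/2).  The positive
#' class defaults to `"SOMATIC"`: higher log2 tumor/residual ratios are
#' more somatic-like.
#'
#' @param scores Ratio-score table with `truth_label` set (both classes
#'   must be present), or any data frame with a score column and a
#'   `truth_label` column.
#' @param score_col Name of the score column (default `"log_ratio"`).
#' @param positive Label of the positive class.
#' @return An object of class `roc_curve`: `thresholds` (descending, ending
#'   in `-Inf`), `fpr`, `tpr` (both nondecreasing from (0,0) to (1,1)),
#'   `auc`, `n_pos`, `n_neg`, `positive`.
#' @export
roc_curve <- function(scores, score_col = "log_ratio", positive = "SOMATIC") {
  s <- scores[[score_col]]
  y <- scores$truth_label == positive
  if (anyNA(s) || anyNA(y)) stop("scores and truth labels must be complete")
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both classes present (got ", n_pos, " positive, ",
         n_neg, " negative)")
  }
  u <- sort(unique(s), decreasing = TRUE)
  grp <- match(s, u)
  tp <- cumsum(tabulate(grp[y], nbins = length(u)))
  fp <- cumsum(tabulate(grp[!y], nbins = length(u)))
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(u, -Inf), fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg, positive = positive),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f (%d %s vs %d other, %d cutoffs)\n",
              x$auc, x$n_pos, x$positive, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Choose an operating threshold on a ROC curve
#'
#' Selects the cutoff maximizing Youden's J (sensitivity + specificity - 1),
#' breaking ties toward the smallest threshold.  Only finite cutoffs (the
#' observed score values) are candidates.
#'
#' @param curve A [roc_curve()].
#' @return An object of class `threshold_result`: `threshold` (log2-ratio
#'   units under the default scoring), `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
choose_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  if (length(curve$thresholds) < 2) {
    stop("degenerate ROC curve: need at least two points")
  }
  finite <- is.finite(curve$thresholds)
  j <- curve$tpr - curve$fpr
  best <- max(j[finite])
  cand <- which(finite & j >= best - 1e-12)
  pick <- cand[which.min(curve$thresholds[cand])]
  structure(list(threshold = curve$thresholds[pick],
                 sensitivity = curve$tpr[pick],
                 specificity = 1 - curve$fpr[pick],
                 youden_j = j[pick]),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> cutoff %.4g: sensitivity %.3f, specificity %.3f (J = %.3f)\n",
    x$threshold, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' Classify germline vs somatic origin by ratio threshold
#'
#' Predicts `"SOMATIC"` when the log2 tumor/residual VAF ratio is strictly
#' greater than the threshold, `"GERMLINE"` otherwise (germline mutations
#' center at log ratio 0, the no-change point).  When truth labels are
#' present, the confusion matrix is attached as the `"confusion"`
#' attribute.
#'
#' @param scores Ratio-score table from [score_shared()].
#' @param threshold A [choose_threshold()] result or a plain numeric cutoff
#'   in log2-ratio units.
#' @return `scores` with `predicted_label` filled in.
#' @export
classify_origin <- function(scores, threshold) {
  thr <- if (inherits(threshold, "threshold_result")) threshold$threshold
         else as.numeric(threshold)
  scores$predicted_label <- ifelse(scores$log_ratio > thr,
                                   "SOMATIC", "GERMLINE")
  if (!all(is.na(scores$truth_label))) {
    lv <- c("GERMLINE", "SOMATIC")
    attr(scores, "confusion") <- table(
      truth = factor(scores$truth_label, levels = lv),
      predicted = factor(scores$predicted_label, levels = lv))
  }
  scores
}
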