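# Cross-fraction comparison: match detected mutations across the three
# fractions of a patient, assign 3-set Venn regions, and quantify what
# enrichment does to VAF.  Venn regions carry the compact labels used in
# the package's figures and reports:
#   a = tumor-fraction only, b = tumor & unseparated (not residual),
#   c = shared by all three, d = unseparated & residual (not tumor);
# the remaining regions (U-only, R-only, T&R-not-U) are "other".

.venn_regions <- c("T_only", "U_only", "R_only", "TU_not_R", "TR_not_U",
                   "UR_not_T", "TUR")
.venn_labels <- c(T_only = "a", TU_not_R = "b", TUR = "c", UR_not_T = "d",
                  U_only = "other", R_only = "other", TR_not_U = "other")

#' Match detected mutations across a patient's three fractions
#'
#' Joins the unseparated, tumor-fraction and residual call sets of one
#' patient on the variant key and assigns each distinct key its Venn region
#' and group label.  Input fractions are expected to have passed [detect()]
#' already.
#'
#' For plotting exports, group (b) mutations (absent from the residual
#' fraction) are given a residual VAF of 0 in the `vaf_residual_plot`
#' column; the analytic `vaf_residual` column stays `NA` when absent.
#'
#' @param trio A [fraction_trio()] whose fractions are detected call sets.
#' @return A data frame with one row per distinct key: key columns,
#'   `patient_id`, per-fraction `vaf_*` / `depth_*` (NA when absent),
#'   presence flags `in_*`, `venn_region` and `group_label`
#'   (a/b/c/d/other).
#' @export
match_across_fractions <- function(trio) {
  stopifnot(inherits(trio, "fraction_trio"))
  frs <- list(unseparated = trio$unseparated, tumor = trio$tumor,
              residual = trio$residual)
  keysets <- lapply(names(frs), function(nm) {
    validate_calls(frs[[nm]])
    .check_unique_keys(frs[[nm]], paste0(nm, " fraction"))
  })
  names(keysets) <- names(frs)
  all_keys <- unique(do.call(rbind, lapply(frs, function(f)
    f[c("chrom", "pos", "ref", "alt")])))
  all_keys <- all_keys[order(all_keys$chrom, all_keys$pos, all_keys$ref,
                             all_keys$alt), , drop = FALSE]
  rownames(all_keys) <- NULL
  kid <- variant_key(all_keys)
  out <- all_keys
  out$patient_id <- rep_len(trio$patient_id, nrow(out))
  for (nm in names(frs)) {
    idx <- match(kid, keysets[[nm]])
    out[[paste0("vaf_", nm)]] <- frs[[nm]]$vaf[idx]
    out[[paste0("depth_", nm)]] <- frs[[nm]]$depth_total[idx]
    out[[paste0("in_", nm)]] <- !is.na(idx)
  }
  code <- paste0(ifelse(out$in_tumor, "T", ""),
                 ifelse(out$in_unseparated, "U", ""),
                 ifelse(out$in_residual, "R", ""))
  region_of <- c(T = "T_only", U = "U_only", R = "R_only", TU = "TU_not_R",
                 TR = "TR_not_U", UR = "UR_not_T", TUR = "TUR")
  out$venn_region <- unname(region_of[code])
  out$group_label <- unname(.venn_labels[out$venn_region])
  out$vaf_residual_plot <- ifelse(out$group_label == "b", 0, out$vaf_residual)
  out
}

#' Venn-region and group-label counts
#'
#' Tabulates matched variants over the seven regions of the 3-set Venn
#' diagram and over the group labels a/b/c/d/other.  Counts sum to the
#' number of distinct keys.
#'
#' @param matched Output of [match_across_fractions()] (one patient or
#'   pooled).
#' @return A list with named integer vectors `regions` (all 7 regions) and
#'   `labels` (a, b, c, d, other), plus `n_keys`.
#' @export
venn_counts <- function(matched) {
  regions <- vapply(.venn_regions,
                    function(r) sum(matched$venn_region == r), 0L)
  labels <- vapply(c("a", "b", "c", "d", "other"),
                   function(l) sum(matched$group_label == l), 0L)
  stopifnot(sum(regions) == nrow(matched), sum(labels) == nrow(matched))
  list(regions = regions, labels = labels, n_keys = nrow(matched))
}

#' VAF fold change upon enrichment for low-VAF mutations
#'
#' For mutations detected in both the unseparated sample and the tumor
#' fraction with unseparated VAF strictly below `vaf_ceiling` (default 10%),
#' computes the per-variant fold change `vaf_tumor / vaf_unseparated` and
#' summarizes the proportion with increased VAF (fold > 1, a strict
#' increase) and the arithmetic mean fold.  When a truth table from
#' [generate_cohort()] is supplied, summaries are additionally broken out
#' per origin (so the somatic-only enrichment effect can be read off).
#'
#' @param matched Matched-variant table (one patient or pooled; must carry
#'   `patient_id`).
#' @param truth Optional truth table with `patient_id`, key columns and
#'   `origin`.
#' @param vaf_ceiling Strict upper bound on unseparated VAF for selection.
#' @return A list with `per_variant` (selected rows plus `fold` and, when
#'   truth is given, `origin`) and `summary` (one row per group: `group`,
#'   `n`, `n_increased`, `proportion_increased`, `mean_fold`).
#' @export
fold_change_low_vaf <- function(matched, truth = NULL, vaf_ceiling = 0.10) {
  sel <- matched$in_unseparated & matched$in_tumor &
    matched$vaf_unseparated < vaf_ceiling
  d <- matched[sel, , drop = FALSE]
  if (any(d$vaf_unseparated == 0)) {
    stop("internal error: selected variant with unseparated VAF 0 ",
         "(presence after detection implies VAF >= 3%)")
  }
  d$fold <- d$vaf_tumor / d$vaf_unseparated
  if (!is.null(truth)) {
    d$origin <- truth$origin[match(
      paste(d$patient_id, variant_key(d)),
      paste(truth$patient_id, variant_key(truth)))]
  }
  summarize <- function(rows, group) {
    data.frame(group = group, n = nrow(rows),
               n_increased = sum(rows$fold > 1),
               proportion_increased = if (nrow(rows)) mean(rows$fold > 1) else NA_real_,
               mean_fold = if (nrow(rows)) mean(rows$fold) else NA_real_,
               stringsAsFactors = FALSE)
  }
  summary <- summarize(d, "all")
  if (!is.null(truth)) {
    for (org in intersect(.origins, unique(d$origin))) {
      summary <- rbind(summary, summarize(d[!is.na(d$origin) & d$origin == org, ,
                                            drop = FALSE], org))
    }
  }
  rownames(d) <- NULL
  list(per_variant = d, summary = summary)
}

#' Welch's two-sample t-test
#'
#' Two-sided Welch (unequal-variance) t-test with Welch-Satterthwaite
#' degrees of freedom, as used to compare VAF and read depth between
#' mutation groups.  When both groups have zero variance the test statistic
#' is defined by convention: 0 with p = 1 for equal means, +/-Inf with
#' p = 0 otherwise (degrees of freedom then fall back to `n1 + n2 - 2`).
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param alpha Nominal significance level (default 0.01).
#' @param m Number of comparisons for the Bonferroni-adjusted level
#'   reported alongside.
#' @return A `welch_test` list: `statistic`, `df`, `p_value`,
#'   `adjusted_alpha` (= `alpha / m`).
#' @export
welch_t <- function(a, b, alpha = 0.01, m = 1) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values")
  }
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
    stop("groups must be finite and free of missing values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    delta <- mean(a) - mean(b)
    res <- list(statistic = if (delta == 0) 0 else sign(delta) * Inf,
                df = length(a) + length(b) - 2,
                p_value = if (delta == 0) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value)
  }
  res$adjusted_alpha <- bonferroni_alpha(alpha, m)
  structure(res, class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.3g, p = %.4g (significant at %.4g)\n",
              x$statistic, x$df, x$p_value, x$adjusted_alpha))
  invisible(x)
}

#' Bonferroni correction
#'
#' `bonferroni_alpha()` divides the significance level by the number of
#' comparisons (e.g. 0.01 over 3 comparisons gives the 0.0033 level);
#' `bonferroni_p()` multiplies p-values by `m`, capped at 1.
#'
#' @param alpha Significance level in (0, 1].
#' @param p Numeric vector of p-values.
#' @param m Number of comparisons, `>= 1`.
#' @return Adjusted level / adjusted p-values.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  alpha / m
}

#' @rdname bonferroni_alpha
#' @export
bonferroni_p <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, p * m)
}
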