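# Shared fixture builders.  Everything is generated in code; no data files.

# a call that sails through every detection filter unless a field is overridden
clean_call <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                       quality = 60, depth_total = 500L, depth_alt = 50L,
                       vaf = NULL, caller_filter = "PASS",
                       consequence = "missense_variant", ...) {
  variant_call(chrom, pos, ref, alt, depth_total = depth_total,
               depth_alt = depth_alt, vaf = vaf, quality = quality,
               caller_filter = caller_filter, consequence = consequence, ...)
}

# random calls that deliberately straddle every filter boundary
random_boundary_calls <- function(n, seed) {
  set.seed(seed)
  dp <- sample(c(50L, 99L, 100L, 101L, 200L, 1000L, 2000L), n, replace = TRUE)
  ad <- pmin(dp, sample(c(0L, 1L, 3L, 4L, 5L, 6L, 10L, 30L, 100L), n,
                        replace = TRUE))
  af_pick <- function() sample(c(NA, NA, 0.0001, 0.009, 0.01, 0.02, 0.3),
                               n, replace = TRUE)
  variant_call(
    chrom = paste0("chr", sample.int(5, n, replace = TRUE)),
    pos = seq_len(n) * 10L, ref = "A", alt = "T",
    depth_total = dp, depth_alt = ad,
    quality = sample(c(0, 10, 19, 20, 21, 60, 200), n, replace = TRUE),
    caller_filter = sample(c("PASS", "PASS", "q22", "strandbias"), n,
                           replace = TRUE),
    consequence = sample(c(protein_affecting_classes(), "synonymous_variant",
                           "intron_variant"), n, replace = TRUE),
    af_kg_global = af_pick(), af_kg_eas = af_pick(),
    af_exac = af_pick(), af_gnomad = af_pick()
  )
}

# plain-R restatement of the four detection rules, kept independent of detect()
detect_oracle <- function(calls) {
  vf <- ifelse(calls$depth_total > 0, calls$depth_alt / calls$depth_total,
               calls$vaf)
  af <- as.matrix(calls[pop_af_columns()])
  common <- apply(af >= 0.01, 1, any, na.rm = TRUE)
  unname(calls$quality >= 20 & calls$depth_total >= 100 &
           calls$depth_alt >= 5 & vf >= 0.005 &
           calls$caller_filter == "PASS" & !common &
           calls$consequence %in% protein_affecting_classes() & vf >= 0.03)
}

# matched-variant rows built directly, bypassing match_across_fractions()
matched_row <- function(vaf_u, vaf_t, vaf_r = NA, patient_id = "P1",
                        pos = 1L, label = NULL) {
  in_u <- !is.na(vaf_u); in_t <- !is.na(vaf_t); in_r <- !is.na(vaf_r)
  code <- paste0(ifelse(in_t, "T", ""), ifelse(in_u, "U", ""),
                 ifelse(in_r, "R", ""))
  region <- c(T = "T_only", U = "U_only", R = "R_only", TU = "TU_not_R",
              TR = "TR_not_U", UR = "UR_not_T", TUR = "TUR")[code]
  lab <- c(T_only = "a", TU_not_R = "b", TUR = "c", UR_not_T = "d",
           U_only = "other", R_only = "other", TR_not_U = "other")[region]
  data.frame(chrom = "chr1", pos = as.integer(pos), ref = "A", alt = "T",
             patient_id = patient_id,
             vaf_unseparated = vaf_u, depth_unseparated = 500L, in_unseparated = in_u,
             vaf_tumor = vaf_t, depth_tumor = 500L, in_tumor = in_t,
             vaf_residual = vaf_r, depth_residual = 500L, in_residual = in_r,
             venn_region = unname(region), group_label = unname(lab),
             vaf_residual_plot = ifelse(identical(unname(lab), "b"), 0, vaf_r),
             stringsAsFactors = FALSE)
}

# exhaustive pairwise Mann-Whitney AUC (wins + half-ties), the ROC oracle
auc_pairwise <- function(pos_scores, neg_scores) {
  wins <- 0
  for (p in pos_scores) {
    wins <- wins + sum(p > neg_scores) + 0.5 * sum(p == neg_scores)
  }
  wins / (length(pos_scores) * length(neg_scores))
}

# ratio-score table from raw label/score vectors
score_table <- function(score, label) {
  data.frame(chrom = "chr1", pos = seq_along(score), ref = "A", alt = "T",
             patient_id = "P1", vaf_tumor = NA_real_, vaf_residual = NA_real_,
             ratio = 2^score, log_ratio = score, truth_label = label,
             predicted_label = NA_character_, stringsAsFactors = FALSE)
}

# small cohort for fast end-to-end tests
small_params <- function(seed = 11, ...) {
  cohort_params(n_patients = 2, purity_unseparated = c(0.2, 0.5),
                n_somatic = 25, n_germline = 8, seed = seed, ...)
}

detect_trio <- function(trio, ...) {
  fraction_trio(trio$patient_id, detect(trio$unseparated, ...),
                detect(trio$tumor, ...), detect(trio$residual, ...),
                blood_keys = trio$blood_keys)
}
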