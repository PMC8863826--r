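test_that("shared-mutation ratio scores follow the log2 convention", {
  m <- rbind(matched_row(0.45, 0.40, 0.20, pos = 1L),
             matched_row(0.50, 0.50, 0.50, pos = 2L),
             matched_row(0.30, 0.25, 0.50, pos = 3L),
             matched_row(0.05, 0.20, NA, pos = 4L))   # group (b): no ratio
  expect_message(scores <- score_shared(m), "skipped")
  expect_equal(nrow(scores), 3L)
  expect_equal(scores$ratio, c(2, 1, 0.5))
  expect_equal(scores$log_ratio, c(1, 0, -1))  # no change maps to 0
})

test_that("blood-defined truth labels germline iff the key was seen in blood", {
  scores <- score_table(c(0, 2), c(NA, NA))
  blood <- data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "T")
  lab <- attach_blood_truth(scores, blood)
  expect_equal(lab$truth_label, c("GERMLINE", "SOMATIC"))
  none <- attach_blood_truth(scores, blood[0, ])
  expect_true(all(none$truth_label == "SOMATIC"))
})

test_that("trapezoid AUC equals the pairwise Mann-Whitney oracle", {
  # perfect separation and all-ties corner cases
  sep <- score_table(c(2, 3, 0, 0.1),
                     c("SOMATIC", "SOMATIC", "GERMLINE", "GERMLINE"))
  expect_equal(roc_curve(sep)$auc, 1.0)
  ties <- score_table(rep(1.5, 6), rep(c("SOMATIC", "GERMLINE"), 3))
  expect_equal(roc_curve(ties)$auc, 0.5)

  set.seed(2718)
  for (i in 1:100) {
    n_pos <- sample(2:8, 1); n_neg <- sample(2:8, 1)
    s <- c(round(rnorm(n_pos, 1), 1), round(rnorm(n_neg), 1))  # rounding forces ties
    lab <- c(rep("SOMATIC", n_pos), rep("GERMLINE", n_neg))
    curve <- roc_curve(score_table(s, lab))
    expect_equal(curve$auc, auc_pairwise(s[lab == "SOMATIC"],
                                         s[lab == "GERMLINE"]),
                 tolerance = 1e-12)
    # curve shape invariants
    expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
    expect_equal(c(curve$fpr[1], curve$tpr[1]), c(0, 0))
    expect_equal(c(curve$fpr[length(curve$fpr)], max(curve$tpr)), c(1, 1))
    # label flip maps auc to 1 - auc
    flip <- score_table(s, ifelse(lab == "SOMATIC", "GERMLINE", "SOMATIC"))
    expect_equal(roc_curve(flip)$auc, 1 - curve$auc, tolerance = 1e-12)
  }
  expect_error(roc_curve(score_table(1:3, rep("SOMATIC", 3))), "both classes")
})

test_that("in-package AUC agrees with pROC on random instances", {
  library(pROC)
  set.seed(31)
  for (i in 1:10) {
    s <- round(c(rnorm(15, 1.2), rnorm(20)), 1)
    lab <- c(rep("SOMATIC", 15), rep("GERMLINE", 20))
    ours <- roc_curve(score_table(s, lab))$auc
    ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = s,
                                          levels = c("GERMLINE", "SOMATIC"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("threshold choice maximizes Youden J with the smallest-cutoff tie rule", {
  sep <- score_table(c(2, 3, 0, 0.1),
                     c("SOMATIC", "SOMATIC", "GERMLINE", "GERMLINE"))
  thr <- choose_threshold(roc_curve(sep))
  expect_equal(thr$youden_j, 1)
  expect_equal(thr$threshold, 0.1)  # smallest cutoff attaining J = 1 under ">"

  ties <- score_table(rep(1.5, 6), rep(c("SOMATIC", "GERMLINE"), 3))
  thr_t <- choose_threshold(roc_curve(ties))
  expect_equal(thr_t$youden_j, 0)
  expect_equal(thr_t$threshold, 1.5)

  # exhaustive scan oracle on random instances
  set.seed(55)
  for (i in 1:20) {
    s <- round(rnorm(12), 1)
    lab <- sample(rep(c("SOMATIC", "GERMLINE"), 6))
    curve <- roc_curve(score_table(s, lab))
    thr <- choose_threshold(curve)
    scan <- vapply(sort(unique(s)), function(cut) {
      sens <- mean(s[lab == "SOMATIC"] > cut)
      spec <- mean(s[lab == "GERMLINE"] <= cut)
      sens + spec - 1
    }, 0)
    expect_equal(thr$youden_j, max(scan), tolerance = 1e-12)
    expect_equal(thr$threshold,
                 min(sort(unique(s))[scan >= max(scan) - 1e-12]))
    # reported operating point is exact on the training scores
    cls <- classify_origin(score_table(s, lab), thr)
    cm <- attr(cls, "confusion")
    expect_equal(cm["SOMATIC", "SOMATIC"] / sum(cm["SOMATIC", ]),
                 thr$sensitivity)
    expect_equal(cm["GERMLINE", "GERMLINE"] / sum(cm["GERMLINE", ]),
                 thr$specificity)
  }
})

test_that("classification uses the strict greater-than rule", {
  sc <- score_table(c(0, 4, 0.5), c(NA, NA, NA))
  cls <- classify_origin(sc, 0.5)
  expect_equal(cls$predicted_label, c("GERMLINE", "SOMATIC", "GERMLINE"))
})

test_that("on a simulated cohort germline ratios sit near 0 and somatic ratios are positive", {
  cohort <- generate_cohort(small_params(seed = 77))
  trios <- lapply(cohort$trios, detect_trio)
  m <- do.call(rbind, lapply(trios, match_across_fractions))
  scores <- suppressMessages(score_shared(m))
  scores <- attach_blood_truth(scores,
                               do.call(rbind, lapply(trios, `[[`, "blood_keys")))
  germ <- scores$log_ratio[scores$truth_label == "GERMLINE"]
  som <- scores$log_ratio[scores$truth_label == "SOMATIC"]
  # het germline concentrates at log-ratio 0; LOH germline falls below 0,
  # so germline scores stay below every somatic score
  expect_lt(abs(median(germ)), 0.2)
  expect_true(all(germ < 0.5))
  if (length(som) > 0) expect_true(all(som > 1))
})
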