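test_that("matched variants receive the correct Venn region and group label", {
  u <- rbind(clean_call(pos = 1L), clean_call(pos = 3L), clean_call(pos = 4L))
  t <- rbind(clean_call(pos = 2L), clean_call(pos = 3L))
  r <- rbind(clean_call(pos = 3L), clean_call(pos = 4L))
  m <- match_across_fractions(fraction_trio("P1", u, t, r))
  m <- m[order(m$pos), ]
  expect_equal(m$group_label, c("other", "a", "c", "d"))      # U-only, T-only, TUR, UR
  expect_equal(m$venn_region, c("U_only", "T_only", "TUR", "UR_not_T"))
  expect_equal(nrow(m), 4L)
  # group (b): present in tumor and unseparated, absent from residual
  m2 <- match_across_fractions(fraction_trio("P1", u, u, r[0, ]))
  expect_true(all(m2$group_label == "b"))
  expect_true(all(m2$vaf_residual_plot == 0))   # plot convention
  expect_true(all(is.na(m2$vaf_residual)))      # analytic value stays NA
})

test_that("venn counts equal brute-force set algebra on random instances", {
  set.seed(123)
  for (rep in 1:5) {
    keys <- seq_len(50)
    in_u <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    in_t <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    in_r <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    used <- in_u | in_t | in_r
    mk <- function(sel) {
      ks <- keys[sel]
      variant_call("chr1", ks, "A", "T", 500L, 100L)[seq_along(ks), ]
    }
    m <- match_across_fractions(fraction_trio("P1", mk(in_u), mk(in_t), mk(in_r)))
    vc <- venn_counts(m)
    expect_equal(vc$n_keys, sum(used))
    expect_equal(sum(vc$regions), sum(vc$labels))
    # independent set-algebra oracle
    U <- keys[in_u]; T <- keys[in_t]; R <- keys[in_r]
    expect_equal(unname(vc$labels["a"]), length(setdiff(T, union(U, R))))
    expect_equal(unname(vc$labels["b"]), length(setdiff(intersect(T, U), R)))
    expect_equal(unname(vc$labels["c"]), length(intersect(intersect(T, U), R)))
    expect_equal(unname(vc$labels["d"]), length(setdiff(intersect(U, R), T)))
    expect_equal(unname(vc$regions["U_only"]), length(setdiff(U, union(T, R))))
  }
  empty <- match_across_fractions(fraction_trio("P1", clean_call()[0, ],
                                                clean_call()[0, ],
                                                clean_call()[0, ]))
  expect_true(all(venn_counts(empty)$regions == 0L))
})

test_that("low-VAF fold changes follow the strict selection and summary arithmetic", {
  m <- rbind(matched_row(0.05, 0.10, pos = 1L),
             matched_row(0.04, 0.04, pos = 2L),
             matched_row(0.09, 0.27, pos = 3L),
             matched_row(0.12, 0.40, pos = 4L),   # unseparated VAF >= 10%: out
             matched_row(NA, 0.30, pos = 5L))     # absent from unseparated: out
  fc <- fold_change_low_vaf(m)
  expect_equal(fc$per_variant$fold, c(2, 1, 3))
  expect_equal(fc$summary$n, 3L)
  expect_equal(fc$summary$proportion_increased, 2 / 3)   # fold > 1 is strict
  expect_equal(fc$summary$mean_fold, 2)
  expect_equal(fold_change_low_vaf(matched_row(0.05, 0.12))$per_variant$fold,
               2.4)
  # summary invariant to input order
  fc_rev <- fold_change_low_vaf(m[rev(seq_len(nrow(m))), ])
  expect_equal(fc_rev$summary, fc$summary)
  expect_true(all(fc$per_variant$fold > 0))
})

test_that("Welch's t-test matches the closed-form oracle and handles degeneracies", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  w <- welch_t(a, b)
  # independent closed-form computation
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_ref <- (mean(a) - mean(b)) / se
  df_ref <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(w$statistic, t_ref, tolerance = 1e-10)
  expect_equal(w$df, df_ref, tolerance = 1e-10)
  expect_equal(w$p_value, p_ref, tolerance = 1e-10)

  same <- welch_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  const <- welch_t(c(0, 0), c(1, 1))
  expect_lt(const$p_value, 0.01)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
  # antisymmetric statistic, symmetric p
  w_ab <- welch_t(a, b * 2); w_ba <- welch_t(b * 2, a)
  expect_equal(w_ab$statistic, -w_ba$statistic)
  expect_equal(w_ab$p_value, w_ba$p_value)
})

test_that("Bonferroni correction divides alpha and caps adjusted p at 1", {
  expect_equal(bonferroni_alpha(0.01, 3), 0.01 / 3)  # the p < 0.003 level
  expect_equal(bonferroni_p(0.9, m = 5), 1)
  expect_equal(bonferroni_p(c(0.2, 0.01), m = 1), c(0.2, 0.01))
  expect_equal(bonferroni_p(c(0.004, 0.5), m = 2), c(0.008, 1))
  expect_error(bonferroni_alpha(0.01, 0), "m must be")
})

test_that("simulated enrichment separates somatic tumor and residual VAF directionally", {
  cohort <- generate_cohort(small_params(seed = 21))
  truth <- cohort$truth
  vt <- c(); vr <- c()
  for (trio in cohort$trios) {
    som <- variant_key(truth[truth$patient_id == trio$patient_id &
                               truth$origin == "SOMATIC", ])
    vt <- c(vt, trio$tumor$vaf[variant_key(trio$tumor) %in% som])
    vr <- c(vr, trio$residual$vaf[variant_key(trio$residual) %in% som])
  }
  w <- welch_t(vt, vr)
  expect_gt(w$statistic, 0)
  expect_lt(w$p_value, 0.01)
})
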