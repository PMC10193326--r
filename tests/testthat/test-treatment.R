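test_that("zero filtering applies the strict > threshold rule", {
  scores <- rbind(
    mostly_zero = c(rep(0, 199), 0.3),            # 199/200 = 0.995 -> drop
    boundary    = c(rep(0, 198), 0.3, 0.2),       # 198/200 = 0.99  -> keep
    positive    = stats::runif(200, 0.1, 1))
  colnames(scores) <- paste0("s", 1:200)
  zf <- zero_filter(scores)
  expect_identical(zf$dropped, "mostly_zero")
  expect_identical(rownames(zf$retained), c("boundary", "positive"))
  # all-positive matrix passes through untouched
  zf2 <- zero_filter(scores[3, , drop = FALSE])
  expect_length(zf2$dropped, 0)
  expect_identical(nrow(zf$retained) + length(zf$dropped), nrow(scores))
})

test_that("an injected arm shift is recovered with the right coefficient", {
  sim <- make_cohort(n_per_arm = c(placebo = 60, low_dose = 60, high_dose = 60),
                     signatures = "sigX",
                     effects = data.frame(signature = "sigX",
                                          arm = c("low_dose", "high_dose"),
                                          delta = 0.3),
                     baseline_sd = 0.1, seed = 101)
  fit <- fit_cell_type(sim$cohort, "sigX", "combined_vs_placebo")
  expect_lt(abs(fit$beta_treatment - 0.3), 0.05)
  expect_lt(fit$p_treatment, 0.001)
  expect_lt(fit$p_ftest, 0.001)
})

test_that("null cohorts give calibrated type-I error at the 0.1 threshold", {
  hits <- vapply(1:200, function(i) {
    sim <- make_cohort(n_per_arm = c(placebo = 60, low_dose = 60,
                                     high_dose = 60),
                       signatures = "s1", seed = 1000 + i)
    fit_cell_type(sim$cohort, "s1", "combined_vs_placebo")$p_treatment < 0.1
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.10), 0.05)
})

test_that("an age-only signal is not attributed to treatment", {
  sim <- make_cohort(signatures = "sigA", baseline_mean = 2,
                     baseline_sd = 0.05, age_slope = c(sigA = 0.01),
                     seed = 55)
  fit <- fit_cell_type(sim$cohort, "sigA", "combined_vs_placebo")
  expect_gt(fit$p_treatment, 0.1)
  expect_gt(fit$p_simple, 0.1)
  # the age coefficient itself is recovered
  d <- sim$cohort
  cf <- stats::coef(stats::lm(sigA ~ arm + age + gender, data = d))
  expect_lt(abs(unname(cf["age"]) - 0.01), 0.003)
})

test_that("age-confounded effects are attenuated by the covariate model", {
  # older patients concentrated in the treated arms, score rises with age:
  # the treatment-only model sees a spurious shift the covariate model removes
  sim <- make_cohort(signatures = "sigC", baseline_sd = 0.1,
                     age_slope = c(sigC = 0.02),
                     age_arm_bias = c(placebo = -8, low_dose = 8, high_dose = 8),
                     seed = 77)
  fit <- fit_cell_type(sim$cohort, "sigC", "combined_vs_placebo")
  expect_lt(fit$p_simple, fit$p_treatment)
  expect_lt(fit$p_simple, 0.01)
})

test_that("the dual rule flags injected effects and spares null signatures", {
  sigs <- paste0("sig", 1:40)
  injected <- paste0("sig", 1:5)
  sim <- make_cohort(n_per_arm = c(placebo = 60, low_dose = 60, high_dose = 60),
                     signatures = sigs,
                     effects = do.call(rbind, lapply(injected, function(s)
                       data.frame(signature = s, arm = c("low_dose", "high_dose"),
                                  delta = 0.2))),
                     baseline_sd = 0.2, seed = 202)
  res <- analyze_cohort(sim$cohort, contrasts = "combined_vs_placebo")
  flagged <- res$signature_id[res$significant]
  expect_true(all(injected %in% flagged))
  expect_lte(length(setdiff(flagged, injected)), 1)
  # dual-rule exactness on every row
  expect_identical(res$significant,
                   !is.na(res$p_treatment_adj) & !is.na(res$p_ftest_adj) &
                     res$p_treatment_adj < 0.1 & res$p_ftest_adj < 0.1)
})

test_that("permuting arm labels abolishes the flags", {
  sigs <- paste0("sig", 1:20)
  sim <- make_cohort(signatures = sigs,
                     effects = data.frame(signature = "sig1",
                                          arm = c("low_dose", "high_dose"),
                                          delta = 0.5),
                     baseline_sd = 0.2, seed = 303)
  cohort <- sim$cohort
  set.seed(304)
  cohort$arm <- sample(cohort$arm)
  res <- analyze_cohort(cohort, contrasts = "combined_vs_placebo")
  expect_lte(sum(res$significant), 1)
})

test_that("constant scores are flagged and kept out of the adjustment family", {
  sim <- make_cohort(signatures = c("ok1", "ok2"), seed = 404)
  cohort <- sim$cohort
  cohort$flat <- 0.5
  res <- analyze_cohort(cohort, signatures = c("ok1", "ok2", "flat"),
                        contrasts = "high_vs_placebo")
  flat_row <- res[res$signature_id == "flat", ]
  expect_identical(flat_row$flag, "constant score")
  expect_true(is.na(flat_row$p_treatment_adj))
  expect_false(flat_row$significant)
  # adjustment across the two testable signatures only (Bonferroni m = 2)
  res_b <- analyze_cohort(cohort, signatures = c("ok1", "ok2", "flat"),
                          contrasts = "high_vs_placebo",
                          adjust_method = "bonferroni")
  ok <- res_b[res_b$signature_id != "flat", ]
  expect_equal(ok$p_treatment_adj, pmin(1, ok$p_treatment * 2))
})

test_that("per-contrast results cover all three comparisons", {
  sim <- make_cohort(signatures = c("a", "b"), seed = 505)
  res <- analyze_cohort(sim$cohort)
  expect_identical(sort(unique(res$contrast)),
                   sort(c("low_vs_placebo", "high_vs_placebo",
                          "combined_vs_placebo")))
  expect_identical(nrow(res), 6L)
  n_by <- tapply(res$n, res$contrast, unique)
  expect_equal(n_by[["combined_vs_placebo"]], 57 + 62 + 70)
  expect_equal(n_by[["low_vs_placebo"]], 57 + 62)
})
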