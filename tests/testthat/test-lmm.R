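test_that("noise-free balanced data reproduce the planted surface exactly", {
  d <- make_lmm_data(n_participants = 6,
                     change_by_trial = c(moderate = 1, heavy = 0.4,
                                         severe = 0),
                     sd_participant = 0,
                     sd_residual = c(moderate = 0, heavy = 0, severe = 0),
                     sex_effect = 0.25, seed = 1)
  fit <- fit_metabolite_lmm(d, "met1")
  beta <- setNames(fit$fixed_effects$estimate, fit$fixed_effects$term)
  expect_lt(abs(beta[["timepointpost"]] - 1), 1e-6)
  expect_lt(abs(beta[["timepointpost:trialheavy"]] + 0.6), 1e-6)
  expect_lt(abs(beta[["timepointpost:trialsevere"]] + 1), 1e-6)
  expect_lt(abs(beta[["sexmale"]] - 0.25), 1e-6)
  cr <- pairwise_contrasts(fit)
  expect_equal(cr$estimate[cr$contrast == "moderate-severe"], 1,
               tolerance = 1e-6)
  expect_equal(cr$estimate[cr$contrast == "moderate-heavy"], 0.6,
               tolerance = 1e-6)
})

test_that("contrast signs follow the planted moderate > heavy > severe order", {
  d <- make_lmm_data(n_participants = 16,
                     change_by_trial = c(moderate = 1.0, heavy = 0.6,
                                         severe = 0.1),
                     sd_residual = c(moderate = 0.15, heavy = 0.15,
                                     severe = 0.15), seed = 2)
  cr <- pairwise_contrasts(fit_metabolite_lmm(d, "met1"))
  expect_true(all(cr$estimate > 0))
  expect_true(all(cr$p_bh >= cr$p_raw))
})

test_that("null data give near-zero contrasts and well-spread p-values", {
  ests <- ps <- NULL
  for (s in 1:10) {
    d <- make_lmm_data(n_participants = 12, seed = 100 + s)
    cr <- pairwise_contrasts(fit_metabolite_lmm(d, "met1",
                                                heteroscedastic = FALSE))
    ests <- c(ests, cr$estimate)
    ps <- c(ps, cr$p_raw)
  }
  expect_lt(abs(mean(ests)), 0.1)
  expect_gt(mean(ps > 0.05), 0.5)  # mostly non-significant under the null
})

test_that("heteroscedastic and fold-change entry points agree on balanced
           data", {
  cfg <- cohort_config(n_participants = 10,
                       n_features_per_class = c(ffa = 2, glycolytic = 1,
                                                lipoprotein = 0, inert = 1),
                       missing_rate = 0, n_qc = 2, seed = 3)
  ds <- generate_cohort(cfg)$dataset
  long <- make_long_table(ds)
  fc <- compute_log2fc(ds)
  cr_long <- pairwise_contrasts(fit_metabolite_lmm(long, "ffa_001"))
  cr_fc <- pairwise_contrasts(fit_fc_lmm(fc, "ffa_001"))
  expect_equal(cr_long$estimate, cr_fc$estimate, tolerance = 1e-6)
})

test_that("participant relabeling leaves fixed effects unchanged", {
  d <- make_lmm_data(n_participants = 10,
                     change_by_trial = c(moderate = 0.8, heavy = 0.3,
                                         severe = 0), seed = 4)
  d2 <- d
  relabel <- setNames(sprintf("Z%02d", sample(10)),
                      sprintf("P%02d", 1:10))
  d2$participant_id <- relabel[d2$participant_id]
  f1 <- fit_metabolite_lmm(d, "met1")
  f2 <- fit_metabolite_lmm(d2, "met1")
  expect_equal(f1$fixed_effects$estimate, f2$fixed_effects$estimate,
               tolerance = 1e-6)
})

test_that("forcing equal variances reproduces the homoscedastic fit", {
  d <- make_lmm_data(n_participants = 12,
                     change_by_trial = c(moderate = 0.5, heavy = 0.2,
                                         severe = 0), seed = 5)
  hom <- fit_metabolite_lmm(d, "met1", heteroscedastic = FALSE)
  both <- fit_metabolite_lmm(d, "met1", heteroscedastic = TRUE)
  # equal-variance data: the heteroscedastic variance estimates collapse
  # toward a common value and AIC prefers the simpler form (usually);
  # in either case the homoscedastic log-likelihood is reproducible
  expect_equal(hom$model_form, "homoscedastic")
  if (both$model_form == "homoscedastic") {
    expect_equal(both$loglik, hom$loglik, tolerance = 1e-6)
  } else {
    ratio <- max(both$var_residual_by_trial) /
      min(both$var_residual_by_trial)
    expect_lt(ratio, 4)
  }
})

test_that("heteroscedastic data are detected and the variance ratio
           recovered", {
  wins <- 0
  ratios <- numeric(0)
  for (s in 1:25) {
    d <- make_lmm_data(n_participants = 16,
                       sd_residual = c(moderate = 0.2, heavy = 0.2,
                                       severe = 0.6), seed = 200 + s)
    fit <- fit_metabolite_lmm(d, "met1")
    if (fit$model_form == "heteroscedastic") {
      wins <- wins + 1
      ratios <- c(ratios,
                  sqrt(fit$var_residual_by_trial[["severe"]] /
                         fit$var_residual_by_trial[["moderate"]]))
    }
  }
  expect_gte(wins, 23)  # >= 90% of replicates
  expect_lt(abs(median(ratios) - 3), 3 * 0.5)  # within a factor of 1.5
})

test_that("degenerate zero-noise data give a near-zero-width bootstrap CI
           and seeded determinism", {
  d <- make_lmm_data(n_participants = 6,
                     change_by_trial = c(moderate = 1, heavy = 0, severe = 0),
                     sd_participant = 0.5,
                     sd_residual = c(moderate = 0, heavy = 0, severe = 0),
                     seed = 6)
  ci <- bootstrap_ci(d, "met1", "moderate-severe", B = 30, seed = 1)
  expect_lt(ci$ci_high - ci$ci_low, 1e-6)
  expect_equal(ci$ci_low, 1, tolerance = 1e-6)
  d2 <- make_lmm_data(n_participants = 10,
                      change_by_trial = c(moderate = 1, heavy = 0.5,
                                          severe = 0), seed = 7)
  ci_a <- bootstrap_ci(d2, "met1", "moderate-severe", B = 40, seed = 9)
  ci_b <- bootstrap_ci(d2, "met1", "moderate-severe", B = 40, seed = 9)
  expect_identical(ci_a$ci_low, ci_b$ci_low)
  expect_identical(ci_a$ci_high, ci_b$ci_high)
  expect_true(ci_a$ci_low <= 1 && 1 <= ci_a$ci_high)
})

test_that("bootstrap CIs cover a planted effect at roughly nominal rate", {
  # reduced problem: 20 outer replicates, B = 60; at a true 95% rate the
  # 2.5th percentile of Binomial(20, 0.95) is 17, i.e. coverage >= 0.85
  covered <- 0
  for (s in 1:20) {
    d <- make_lmm_data(n_participants = 12,
                       change_by_trial = c(moderate = 1, heavy = 0.5,
                                           severe = 0),
                       sd_residual = c(moderate = 0.25, heavy = 0.25,
                                       severe = 0.25), seed = 300 + s)
    ci <- bootstrap_ci(d, "met1", "moderate-severe", B = 60, seed = s,
                       heteroscedastic = FALSE)
    if (ci$ci_low <= 1 && 1 <= ci$ci_high) covered <- covered + 1
  }
  expect_gte(covered, 17)
})

test_that("contrast table export carries the documented columns", {
  d <- make_lmm_data(n_participants = 8,
                     change_by_trial = c(moderate = 0.8, heavy = 0.2,
                                         severe = 0), seed = 8)
  tab <- lmm_contrast_table(d, bootstrap_B = 20, seed = 1)
  expect_true(all(c("metabolite_id", "contrast", "estimate", "se", "p_raw",
                    "p_bh", "ci_low", "ci_high", "model_form",
                    "converged") %in% names(tab)))
  ok <- tab$converged & is.finite(tab$ci_low)
  expect_true(all(tab$ci_low[ok] <= tab$estimate[ok] + 1e-8))
  expect_true(all(tab$estimate[ok] <= tab$ci_high[ok] + 1e-8))
})

test_that("unconverged fits refuse contrasts", {
  fake <- structure(list(converged = FALSE), class = "LmmFit")
  expect_error(pairwise_contrasts(fake), "converged")
})
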