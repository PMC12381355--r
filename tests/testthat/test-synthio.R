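small_counts <- c(ffa = 6, glycolytic = 4, lipoprotein = 4, inert = 6)

test_that("no-effect, no-noise config gives unit post/pre ratios", {
  cfg <- cohort_config(n_participants = 4, n_features_per_class = small_counts,
                       effect_matrix = default_effect_matrix() * 0,
                       sex_modulation = 0, sd_participant = 0,
                       sd_residual_by_trial = c(moderate = 0, heavy = 0,
                                                severe = 0),
                       missing_rate = 0, n_qc = 2, qc_rsd_target = 0,
                       seed = 1)
  ds <- generate_cohort(cfg)$dataset
  fc <- compute_log2fc(ds)
  expect_equal(max(abs(fc$values)), 0)
})

test_that("noise-free planted effects appear exactly in the log2 ratios", {
  em <- default_effect_matrix() * 0
  em["glycolytic", "severe"] <- 1.5
  cfg <- cohort_config(n_participants = 5, n_features_per_class = small_counts,
                       effect_matrix = em, sex_modulation = 0,
                       sd_participant = 0.4,
                       sd_residual_by_trial = c(moderate = 0, heavy = 0,
                                                severe = 0),
                       missing_rate = 0, n_qc = 2, seed = 2)
  syn <- generate_cohort(cfg)
  fc <- compute_log2fc(syn$dataset)
  gly <- grepl("^glycolytic", colnames(fc$values))
  sev <- fc$meta$trial == "severe"
  expect_equal(unname(fc$values[sev, gly]),
               matrix(1.5, sum(sev), sum(gly)), tolerance = 1e-12)
  expect_equal(max(abs(fc$values[!sev, ])), 0)
  # truth table covers every feature
  expect_setequal(syn$truth$feature_id, colnames(syn$dataset$matrix))
})

test_that("generation is deterministic given the seed and strictly positive", {
  cfg <- cohort_config(n_participants = 6, n_features_per_class = small_counts,
                       missing_rate = 0.1, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$dataset$matrix, b$dataset$matrix)
  expect_identical(a$dataset$sample_meta, b$dataset$sample_meta)
  expect_true(all(a$dataset$matrix > 0, na.rm = TRUE))
  # sample bookkeeping: participants x 3 trials x 2 timepoints + QC rows
  expect_equal(nrow(a$dataset$matrix), 6 * 3 * 2 + cfg$n_qc)
})

test_that("invalid configs name the offending field", {
  expect_error(cohort_config(missing_rate = 1.2), "missing_rate")
  expect_error(cohort_config(sd_participant = -1), "sd_participant")
  expect_error(cohort_config(n_participants = 0), "n_participants")
})

test_that("mcar missingness blanks the forced count and spares QC rows", {
  cfg <- cohort_config(n_participants = 10,
                       n_features_per_class = c(ffa = 10, glycolytic = 0,
                                                lipoprotein = 0, inert = 0),
                       missing_rate = 0, n_qc = 5, seed = 3)
  ds <- generate_cohort(cfg)$dataset
  # 10x10 study block carved out for the exact-count check
  block <- subset_dataset(ds, samples = c(1:10, 61:65), features = 1:10)
  out <- inject_missingness(block, 0.5, "mcar", seed = 4)
  study <- out$matrix[out$sample_meta$sample_type == "study", ]
  expect_equal(sum(is.na(study)), 50)
  expect_false(anyNA(out$matrix[out$sample_meta$sample_type == "qc", ]))
  expect_identical(inject_missingness(block, 0), block)
  expect_error(inject_missingness(block, 1), "rate")
})

test_that("low-intensity missingness prefers low-abundance cells", {
  cfg <- cohort_config(n_participants = 10,
                       n_features_per_class = small_counts,
                       missing_rate = 0, n_qc = 2, seed = 5)
  ds <- generate_cohort(cfg)$dataset
  out <- inject_missingness(ds, 0.1, "low-intensity", seed = 6)
  study_old <- ds$matrix[ds$sample_meta$sample_type == "study", ]
  study_new <- out$matrix[out$sample_meta$sample_type == "study", ]
  blanked <- is.na(study_new)
  expect_lt(mean(study_old[blanked]), mean(study_old[!blanked]))
})

test_that("QC injections land around the pooled mean at the target RSD", {
  cfg <- cohort_config(n_participants = 8, n_features_per_class = small_counts,
                       missing_rate = 0, n_qc = 0, seed = 8)
  ds <- generate_cohort(cfg)$dataset
  # zero-variance target: QC rows equal the pooled mean exactly
  qc0 <- make_qc_injections(ds, 3, rsd_target = 0, seed = 1)
  expect_equal(unname(compute_feature_rsd(qc0)),
               rep(0, ncol(ds$matrix)))
  pooled <- colMeans(ds$matrix)
  qc_rows <- qc0$matrix[qc0$sample_meta$sample_type == "qc", ]
  expect_equal(unname(qc_rows[1, ]), unname(pooled))
  # bookkeeping
  expect_equal(nrow(qc0$matrix), nrow(ds$matrix) + 3)
  expect_error(make_qc_injections(ds, 1, 10), "n_qc")
  # Monte-Carlo at the study's RSD scale: 50 injections at 10% target
  qc50 <- make_qc_injections(ds, 50, rsd_target = 10, seed = 1)
  rsd <- compute_feature_rsd(qc50)
  expect_gte(mean(rsd >= 7 & rsd <= 13), 0.95)
})

test_that("planted class/trial means are recovered under low noise", {
  cfg <- cohort_config(n_participants = 16,
                       n_features_per_class = c(ffa = 20, glycolytic = 10,
                                                lipoprotein = 10, inert = 20),
                       sex_modulation = 0,
                       sd_residual_by_trial = c(moderate = 0.05, heavy = 0.05,
                                                severe = 0.05),
                       missing_rate = 0, n_qc = 2, seed = 9)
  syn <- generate_cohort(cfg)
  fc <- compute_log2fc(syn$dataset)
  cls <- syn$truth$class[match(colnames(fc$values), syn$truth$feature_id)]
  for (tr in c("moderate", "heavy", "severe")) {
    for (cl in unique(cls)) {
      obs <- mean(fc$values[fc$meta$trial == tr, cls == cl])
      expect_lt(abs(obs - cfg$effect_matrix[cl, tr]), 0.05)
    }
  }
})
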