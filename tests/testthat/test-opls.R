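test_that("an indicator column dominates the fit", {
  # a single predictive component mixes in scaled noise columns at weight
  # share ~ p_noise/n, so near-perfect R2Y needs n >> 100 * p_noise
  set.seed(1)
  n <- 1000; p <- 5
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- as.numeric(y == "b")
  colnames(X) <- paste0("f", 1:p)
  m <- fit_opls_da(X, y, n_ortho = 0)
  expect_gt(m$r2y_cum, 0.99)
  expect_equal(unname(which.max(abs(m$w))), 1L)
  expect_equal(which.max(m$vip), c(f1 = 1L))
  # VIP > 3 needs >= 10 features; check the concentration identity instead
  expect_gt(m$vip[1]^2 / p, 0.98)
})

test_that("identical class profiles give a no-signal model", {
  set.seed(2)
  M <- matrix(rnorm(12 * 8), 12, 8)
  X <- rbind(M, M)
  y <- rep(c("a", "b"), each = 12)
  m <- fit_opls_da(X, y, n_ortho = 0)
  expect_lt(abs(m$r2y_cum), 1e-8)
})

test_that("with no orthogonal components the fit equals the PLS1 oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 24; p <- 50
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c("a", "b"), each = n / 2)
    X[y == "b", 1:5] <- X[y == "b", 1:5] + 1
    Xs <- autoscale(X)
    yc <- (as.numeric(factor(y)) - 1)
    yc <- yc - mean(yc)
    oracle <- pls1_oracle(unclass(Xs)[, ], yc)
    m <- fit_opls_da(X, y, n_ortho = 0)
    s <- sign(sum(oracle$w * m$w))  # NIPALS sign indeterminacy
    expect_equal(m$w, s * oracle$w, tolerance = 1e-8)
    expect_equal(m$t, s * oracle$t, tolerance = 1e-8)
    expect_equal(m$p, s * oracle$p, tolerance = 1e-8)
    expect_equal(m$t * m$c, oracle$y_hat, tolerance = 1e-8)
  }
})

test_that("orthogonal scores are uncorrelated with predictive scores and
           R2Y does not decrease with n_ortho", {
  tc <- make_two_class(seed = 3)
  r2y <- vapply(0:3, function(no) {
    m <- fit_opls_da(tc$X, tc$y, n_ortho = no)
    if (no > 0) {
      for (k in seq_len(no)) {
        expect_lt(abs(cor(m$t, m$t_o[, k])), 1e-8)
      }
      expect_equal(unname(sqrt(colSums(m$w_o^2))), rep(1, no),
                   tolerance = 1e-12)
    }
    expect_equal(sqrt(sum(m$w^2)), 1, tolerance = 1e-12)
    expect_true(m$r2x_cum >= 0 && m$r2x_cum <= 1)
    m$r2y_cum
  }, numeric(1))
  expect_true(all(diff(r2y) >= -1e-10))
})

test_that("repeat fits are bit-identical under the sign convention", {
  tc <- make_two_class(seed = 4)
  m1 <- fit_opls_da(tc$X, tc$y, n_ortho = 2)
  m2 <- fit_opls_da(tc$X, tc$y, n_ortho = 2)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$t_o, m2$t_o)
  expect_gt(m1$w[which.max(abs(m1$w))], 0)
})

test_that("class-count preconditions are enforced", {
  X <- matrix(rnorm(30), 10, 3)
  expect_error(fit_opls_da(X, rep(c("a", "b", "c"), c(4, 3, 3))), "2 classes")
  expect_error(fit_opls_da(X, rep(c("a", "b"), c(8, 2))), ">= 3")
})

test_that("VIP satisfies its normalization and uniform-weight identity", {
  # uniform |w| across p features: every VIP = 1
  p <- 16
  model <- structure(list(w = rep(1 / sqrt(p), p),
                          feature_names = paste0("f", 1:p)),
                     class = "OplsModel")
  expect_equal(unname(compute_vip(model)), rep(1, p))
  tc <- make_two_class(seed = 5)
  m <- fit_opls_da(tc$X, tc$y, n_ortho = 1)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
  # an indicator column among >= 10 features concentrates VIP above 3
  set.seed(6)
  n <- 120; p2 <- 12
  y2 <- rep(c("a", "b"), each = n / 2)
  X2 <- matrix(rnorm(n * p2), n, p2)
  X2[, 1] <- as.numeric(y2 == "b")
  m2 <- fit_opls_da(X2, y2, n_ortho = 0)
  expect_equal(unname(which.max(m2$vip)), 1L)
  expect_gt(max(m2$vip), 3)
  expect_error(compute_vip(structure(list(), class = "list")), "fitted")
})

test_that("cross-validation separates signal from permuted labels", {
  set.seed(6)
  n <- 24
  y <- rep(c("a", "b"), each = n / 2)
  # separable design: 20 noisy replicates of the class indicator (the
  # predictive component averages their noise away) plus 10 pure-noise
  # columns that auto-scaling inflates to unit variance
  X <- cbind(matrix(as.numeric(y == "b"), n, 20) +
               matrix(rnorm(n * 20, 0, 0.3), n, 20),
             matrix(rnorm(n * 10), n, 10))
  cv <- cross_validate(X, y, k = 8, n_ortho = 0, seed = 1)
  expect_gt(cv$q2_cum, 0.9)
  # determinism
  cv2 <- cross_validate(X, y, k = 8, n_ortho = 0, seed = 1)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$q2_cum, cv2$q2_cum)
  # permuted labels: negative Q2 in expectation
  q2_null <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    cross_validate(X, sample(y), k = 4, n_ortho = 0, seed = s)$q2_cum
  }, numeric(1))
  expect_lt(mean(q2_null), 0)
  expect_error(cross_validate(X, y, k = 50), "exceeds")
})

test_that("folds are stratified by class", {
  y <- rep(c("a", "b"), each = 12)
  X <- matrix(rnorm(24 * 5), 24, 5)
  cv <- cross_validate(X, y, k = 4, n_ortho = 0, seed = 2)
  tab <- table(cv$folds, y)
  expect_true(all(tab == 3))
})

test_that("permutation p-values respect the add-one floor", {
  tc <- make_two_class(n_per_class = 8, p = 30, n_signal = 15, shift = 3,
                       seed = 7)
  pt <- permutation_test(tc$X, tc$y, n_perm = 25, k = 4, seed = 1)
  expect_equal(pt$p_r2y, 1 / 25)
  expect_equal(pt$p_q2, 1 / 25)
  expect_length(pt$perm_r2y, 25)
  expect_error(permutation_test(tc$X, tc$y, n_perm = 0), "n_perm")
  # null truth: p should not pile near the floor; over 20 seeded null
  # runs at least one exceeds 0.5
  set.seed(8)
  X0 <- matrix(rnorm(16 * 10), 16, 10)
  y0 <- rep(c("a", "b"), each = 8)
  p_null <- vapply(1:20, function(s) {
    permutation_test(X0, y0, n_perm = 10, k = 4, seed = s)$p_q2
  }, numeric(1))
  expect_gte(sum(p_null > 0.5), 1)
})

test_that("projection reproduces training scores and orders class centroids", {
  tc <- make_two_class(seed = 9)
  m <- fit_opls_da(tc$X, tc$y, n_ortho = 1)
  pr <- project(m, tc$X)
  expect_equal(pr$t, m$t, tolerance = 1e-10)
  expect_equal(unname(pr$t_o[, 1]), unname(m$t_o[, 1]), tolerance = 1e-10)
  centroids <- rbind(colMeans(tc$X[tc$y == "a", ]),
                     colMeans(tc$X[tc$y == "b", ]))
  colnames(centroids) <- colnames(tc$X)
  pc <- project(m, centroids)
  expect_lt(min(pc$t) * max(pc$t), 0)  # opposite sides of zero
  expect_error(project(m, tc$X[, 1:10]), "lacks")
})

test_that("an intermediate third class projects between the training classes", {
  em <- default_effect_matrix() * 0
  em["ffa", ] <- c(1.2, 0.6, 0.0)        # heavy sits midway
  em["glycolytic", ] <- c(0.0, 0.75, 1.5)
  cfg <- cohort_config(n_participants = 16,
                       n_features_per_class = c(ffa = 15, glycolytic = 10,
                                                lipoprotein = 0, inert = 15),
                       effect_matrix = em, sex_modulation = 0,
                       sd_residual_by_trial = c(moderate = 0.15,
                                                heavy = 0.15, severe = 0.15),
                       missing_rate = 0, n_qc = 2, seed = 10)
  fc <- compute_log2fc(generate_cohort(cfg)$dataset)
  cmp <- fc$meta$trial %in% c("moderate", "severe")
  m <- fit_opls_da(fc$values[cmp, ], fc$meta$trial[cmp], n_ortho = 1)
  proj <- project(m, fc$values[fc$meta$trial == "heavy", ])
  mean_a <- mean(m$t[fc$meta$trial[cmp] == "moderate"])
  mean_b <- mean(m$t[fc$meta$trial[cmp] == "severe"])
  mid <- mean(proj$t)
  expect_true(mid > min(mean_a, mean_b) && mid < max(mean_a, mean_b))
})

test_that("orthogonal-component auto-selection stops when Q2 stalls", {
  tc <- make_two_class(seed = 11)
  sel <- select_n_ortho(tc$X, tc$y, k = 4, seed = 1, max_ortho = 3)
  expect_true(sel$n_ortho >= 0 && sel$n_ortho <= 3)
  expect_length(sel$q2, sel$n_ortho + 1 + (sel$n_ortho < 3))
})

test_that("models serialize to CSV blocks with a manifest", {
  tc <- make_two_class(seed = 12)
  m <- fit_opls_da(tc$X, tc$y, n_ortho = 1)
  dir <- tempfile()
  write_opls_model(m, dir)
  expect_true(all(file.exists(file.path(dir, c("features.csv", "scores.csv",
                                               "stats.csv",
                                               "manifest.csv")))))
  feat <- read.csv(file.path(dir, "features.csv"))
  expect_equal(feat$w, unname(m$w), tolerance = 1e-12)
})
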