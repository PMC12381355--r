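#' Orthogonal PLS discriminant analysis (two classes)
#'
#' NIPALS PLS1 with orthogonal-signal-correction deflation, written for the
#' two-class discriminant setting (one predictive component; class-uncorrelated
#' systematic variation split into `n_ortho` orthogonal components). The class
#' vector is coded 0/1 and centered. For each orthogonal component the
#' candidate loading's class-predictive part is subtracted
#' (`w_o = p - (w'p) w`, normalized), the orthogonal scores and loadings are
#' extracted, and `X` is deflated by `t_o p_o'` before the final predictive
#' component is taken from the filtered matrix. With `n_ortho = 0` the fit
#' reduces exactly to single-component PLS1.
#'
#' Reported statistics: `r2y_cum = 1 - SS_res(y)/SS_tot(y)`;
#' `r2x_cum` = Frobenius mass of all modelled components over the total;
#' `rmsee = sqrt(SS_res(y) / (n - 1 - n_components))`. The weight sign is
#' fixed by flipping each weight vector so its largest-magnitude element is
#' positive, making repeat fits bit-identical.
#'
#' @param X numeric matrix (samples x features), no missing values.
#' @param y two-class vector (factor/character/numeric with 2 levels),
#'   each class with at least 3 members.
#' @param n_ortho number of orthogonal components (default 1).
#' @param scale when `TRUE` (default) `X` is auto-scaled internally and the
#'   parameters stored; pass `FALSE` for a pre-scaled matrix.
#' @return an `OplsModel` with weights `w`, loadings `p`, scores `t`,
#'   response loading `c`, orthogonal `w_o`/`p_o`/`t_o` (feature x component
#'   matrices), scaling parameters, class labels, fit statistics
#'   (`r2x_cum`, `r2y_cum`, `rmsee`) and VIP scores.
#' @export
fit_opls_da <- function(X, y, n_ortho = 1, scale = TRUE) {
  X <- as.matrix(X)
  cls <- encode_classes(y)
  if (any(table(cls$idx) < 3)) {
    stop("each class needs >= 3 members", call. = FALSE)
  }
  if (nrow(X) < n_ortho + 2) {
    stop("need at least n_ortho + 2 samples", call. = FALSE)
  }
  if (scale) {
    Xs <- autoscale(X)
    center <- attr(Xs, "center"); scl <- attr(Xs, "scale")
    zero_var <- attr(Xs, "zero_variance")
  } else {
    Xs <- X
    center <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
    zero_var <- rep(FALSE, ncol(X))
  }
  yc <- cls$coded - mean(cls$coded)
  p_feat <- ncol(Xs)
  ss_x_tot <- sum(Xs^2)
  ss_y_tot <- sum(yc^2)

  if (sqrt(sum(crossprod(Xs, yc)^2)) < 1e-10) {
    # no covariance between X and the class axis: degenerate no-signal model
    model <- structure(list(
      n_pred = 1L, n_ortho = 0L,
      w = rep(0, p_feat), p = rep(0, p_feat), t = rep(0, nrow(Xs)), c = 0,
      w_o = matrix(0, p_feat, 0), p_o = matrix(0, p_feat, 0),
      t_o = matrix(0, nrow(Xs), 0),
      center = center, scale = scl, zero_variance = zero_var,
      feature_names = colnames(X),
      class_labels = cls$labels, y_coded = cls$coded,
      y_mean = mean(cls$coded),
      r2x_cum = 0, r2y_cum = 0,
      rmsee = sqrt(sum(yc^2) / max(nrow(Xs) - 2, 1)),
      ss_y_tot = ss_y_tot, degenerate = TRUE),
      class = "OplsModel")
    model$vip <- stats::setNames(rep(0, p_feat), colnames(X))
    return(model)
  }
  Xd <- Xs
  w_o <- p_o <- matrix(0, p_feat, 0)
  t_o <- matrix(0, nrow(Xs), 0)
  r2x_parts <- numeric(0)
  for (k in seq_len(n_ortho)) {
    w <- fix_sign(normalize(crossprod(Xd, yc)))
    tt <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, tt)) / sum(tt^2)
    wo <- p - drop(crossprod(w, p)) * w
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-12) break  # no orthogonal variation left
    wo <- fix_sign(wo / nrm)
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    w_o <- cbind(w_o, wo); p_o <- cbind(p_o, po); t_o <- cbind(t_o, to)
    r2x_parts <- c(r2x_parts, sum(to^2) * sum(po^2))
  }
  w <- fix_sign(normalize(crossprod(Xd, yc)))
  tt <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, tt)) / sum(tt^2)
  cc <- drop(crossprod(yc, tt)) / sum(tt^2)
  y_hat <- tt * cc
  ss_res <- sum((yc - y_hat)^2)
  n_comp <- 1 + ncol(w_o)
  model <- structure(list(
    n_pred = 1L, n_ortho = ncol(w_o),
    w = drop(w), p = p, t = tt, c = cc,
    w_o = w_o, p_o = p_o, t_o = t_o,
    center = center, scale = scl, zero_variance = zero_var,
    feature_names = colnames(X),
    class_labels = cls$labels, y_coded = cls$coded, y_mean = mean(cls$coded),
    r2x_cum = (sum(tt^2) * sum(p^2) + sum(r2x_parts)) / ss_x_tot,
    r2y_cum = 1 - ss_res / ss_y_tot,
    rmsee = sqrt(ss_res / max(nrow(Xs) - 1 - n_comp, 1)),
    ss_y_tot = ss_y_tot),
    class = "OplsModel")
  model$vip <- compute_vip(model)
  model
}

encode_classes <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2) {
    stop("y must have exactly 2 classes (one-vs-one only), got ",
         nlevels(f), call. = FALSE)
  }
  list(coded = as.numeric(f) - 1, labels = levels(f), idx = f)
}

normalize <- function(v) {
  v <- drop(v)
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("degenerate weight vector (constant y?)",
                       call. = FALSE)
  v / n
}

# sign convention: largest-|.| element positive
fix_sign <- function(v) {
  v <- drop(v)
  if (v[which.max(abs(v))] < 0) -v else v
}

#' @export
print.OplsModel <- function(x, ...) {
  cat(sprintf(
    "OplsModel (%s vs %s): 1 predictive + %d orthogonal component(s)\n",
    x$class_labels[1], x$class_labels[2], x$n_ortho))
  cat(sprintf("  R2X(cum) %.3f  R2Y(cum) %.3f  RMSEE %.3f\n",
              x$r2x_cum, x$r2y_cum, x$rmsee))
  if (!is.null(x$q2_cum)) cat(sprintf("  Q2(cum) %.3f\n", x$q2_cum))
  invisible(x)
}

#' Variable importance in projection
#'
#' For each feature, `VIP_j = sqrt(p * sum_a SSY_a (w_aj / ||w_a||)^2 /
#' sum_a SSY_a)` over the predictive components. Squared VIPs average to 1
#' (`sum VIP^2 = n_features`). With the single predictive component of a
#' two-class model this reduces to `sqrt(p) * |w_j|`.
#'
#' @param model a fitted `OplsModel`.
#' @return named numeric vector of VIP scores (>= 0).
#' @export
compute_vip <- function(model) {
  if (!inherits(model, "OplsModel") || is.null(model$w)) {
    stop("compute_vip needs a fitted OplsModel", call. = FALSE)
  }
  w <- model$w / sqrt(sum(model$w^2))
  vip <- sqrt(length(w) * w^2)  # single predictive component: SSY weights cancel
  names(vip) <- model$feature_names
  vip
}

#' Project new samples onto a fitted OPLS-DA model
#'
#' New data are scaled with the model's stored training parameters, the
#' stored orthogonal components are removed sequentially
#' (`t_o = X w_o; X <- X - t_o p_o'`), and predictive scores are taken as
#' `t = X_filtered w`. No refit occurs.
#'
#' @param model a fitted `OplsModel`.
#' @param X_new matrix on the raw (unscaled) feature scale, with the
#'   model's feature set.
#' @return list with `t` (predictive scores), `t_o` (orthogonal scores) and
#'   `margin` (predicted class margin `t * c`, positive side = second
#'   class label).
#' @export
project <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (!is.null(model$feature_names)) {
    if (is.null(colnames(X_new))) {
      if (ncol(X_new) != length(model$feature_names)) {
        stop("X_new has ", ncol(X_new), " features; model expects ",
             length(model$feature_names), call. = FALSE)
      }
    } else {
      missing <- setdiff(model$feature_names, colnames(X_new))
      if (length(missing)) {
        stop("X_new lacks model features: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      X_new <- X_new[, model$feature_names, drop = FALSE]
    }
  }
  Xs <- autoscale(X_new, center = model$center, scale = model$scale)
  Xs[, model$zero_variance] <- 0
  t_o <- matrix(0, nrow(Xs), model$n_ortho)
  for (k in seq_len(model$n_ortho)) {
    t_o[, k] <- Xs %*% model$w_o[, k]
    Xs <- Xs - tcrossprod(t_o[, k], model$p_o[, k])
  }
  t_new <- drop(Xs %*% model$w)
  list(t = t_new, t_o = t_o, margin = t_new * model$c)
}

#' Stratified k-fold cross-validation of an OPLS-DA fit
#'
#' Folds are stratified by class and assigned by a seeded shuffle; scaling
#' is recomputed inside each training fold, the held-out samples projected,
#' and `Q2 = 1 - PRESS / SS_tot(y)` with PRESS the summed squared held-out
#' prediction errors.
#'
#' @param X raw (unscaled) matrix.
#' @param y two-class vector.
#' @param k folds (default 8).
#' @param n_ortho orthogonal components.
#' @param seed integer seed for the fold shuffle.
#' @return list with `q2_cum` and the integer `folds` assignment.
#' @export
cross_validate <- function(X, y, k = 8, n_ortho = 1, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k = ", k, " exceeds n = ", n, call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  cls <- encode_classes(y)
  folds <- make_folds(cls$idx, k, seed)
  yc_full <- cls$coded - mean(cls$coded)
  press <- 0
  for (f in seq_len(k)) {
    test <- folds == f
    if (!any(test)) next
    if (length(unique(cls$idx[!test])) < 2) {
      press <- press + sum(yc_full[test]^2)  # degenerate fold: no model
      next
    }
    fit <- fit_opls_da(X[!test, , drop = FALSE], cls$idx[!test],
                       n_ortho = n_ortho, scale = TRUE)
    pr <- project(fit, X[test, , drop = FALSE])
    y_hat <- pr$margin + fit$y_mean           # back to 0/1 scale
    press <- press + sum((cls$coded[test] - y_hat)^2)
  }
  list(q2_cum = 1 - press / sum(yc_full^2), folds = folds)
}

# Stratified fold assignment: within each class, a seeded shuffle dealt
# round-robin so fold sizes differ by at most one per class.
make_folds <- function(class_idx, k, seed) {
  set.seed(as.integer(seed))
  folds <- integer(length(class_idx))
  for (lv in levels(class_idx)) {
    members <- which(class_idx == lv)
    folds[members[sample.int(length(members))]] <-
      rep_len(seq_len(k), length(members))
  }
  folds
}

#' Permutation test of OPLS-DA fit statistics
#'
#' The class labels are shuffled `n_perm` times; for each permutation the
#' full fit plus stratified cross-validation pipeline is re-run and the
#' permuted R2Y and Q2 recorded. P-values use the add-one rule
#' `p = (1 + #\{perm >= observed\}) / n_perm`, so the smallest attainable
#' p at 50 permutations is 1/50 = 0.02.
#'
#' @param X raw (unscaled) matrix.
#' @param y two-class vector.
#' @param n_perm permutations (default 50).
#' @param k CV folds (default 8).
#' @param n_ortho orthogonal components.
#' @param seed integer seed.
#' @return a `PermutationResult`: observed and permuted R2Y/Q2 and p-values.
#' @export
permutation_test <- function(X, y, n_perm = 50, k = 8, n_ortho = 1,
                             seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  X <- as.matrix(X)
  observed <- fit_opls_da(X, y, n_ortho = n_ortho, scale = TRUE)
  cv <- cross_validate(X, y, k = k, n_ortho = n_ortho,
                       seed = derive_seed(seed, "cv_observed"))
  obs_r2y <- observed$r2y_cum
  obs_q2 <- cv$q2_cum
  perm_r2y <- perm_q2 <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(derive_seed(seed, paste0("perm", b)))
    y_perm <- sample(as.character(y))
    fit_b <- fit_opls_da(X, y_perm, n_ortho = n_ortho, scale = TRUE)
    cv_b <- cross_validate(X, y_perm, k = k, n_ortho = n_ortho,
                           seed = derive_seed(seed, paste0("permcv", b)))
    perm_r2y[b] <- fit_b$r2y_cum
    perm_q2[b] <- cv_b$q2_cum
  }
  structure(list(
    observed_r2y = obs_r2y, observed_q2 = obs_q2,
    perm_r2y = perm_r2y, perm_q2 = perm_q2,
    p_r2y = (1 + sum(perm_r2y >= obs_r2y)) / n_perm,
    p_q2 = (1 + sum(perm_q2 >= obs_q2)) / n_perm,
    n_perm = n_perm),
    class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(
    "PermutationResult (%d perms): R2Y %.3f (p = %.3g), Q2 %.3f (p = %.3g)\n",
    x$n_perm, x$observed_r2y, x$p_r2y, x$observed_q2, x$p_q2))
  invisible(x)
}

#' Choose the orthogonal-component count by cross-validation
#'
#' Adds orthogonal components while the cross-validated Q2 improves by more
#' than `min_gain`, up to `max_ortho`.
#'
#' @param X raw matrix; @param y two-class vector
#' @param k CV folds; @param seed integer seed
#' @param max_ortho cap (default 5); @param min_gain required Q2 improvement
#' @return list with chosen `n_ortho` and the per-count `q2` path
#' @export
select_n_ortho <- function(X, y, k = 8, seed = 1L, max_ortho = 5,
                           min_gain = 0.01) {
  q2 <- cross_validate(X, y, k = k, n_ortho = 0, seed = seed)$q2_cum
  best <- 0
  path <- q2
  for (no in seq_len(max_ortho)) {
    q2_no <- cross_validate(X, y, k = k, n_ortho = no, seed = seed)$q2_cum
    path <- c(path, q2_no)
    if (q2_no > q2 + min_gain) {
      best <- no
      q2 <- q2_no
    } else break
  }
  list(n_ortho = best, q2 = path)
}

#' Serialize / restore an OPLS model as CSV blocks
#'
#' Writes a directory of plain-text CSVs (weights/loadings/scores, scaling
#' parameters, fit statistics, class labels) plus a manifest.
#'
#' @param model an `OplsModel`; @param dir output directory
#' @return invisibly the directory (write) / an `OplsModel` (read)
#' @export
write_opls_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feat <- data.frame(feature = model$feature_names %||%
                       paste0("V", seq_along(model$w)),
                     w = model$w, p = model$p,
                     center = model$center, scale = model$scale,
                     vip = model$vip)
  if (model$n_ortho > 0) {
    colnames(model$w_o) <- paste0("w_o", seq_len(model$n_ortho))
    colnames(model$p_o) <- paste0("p_o", seq_len(model$n_ortho))
    feat <- cbind(feat, model$w_o, model$p_o)
  }
  utils::write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  scores <- data.frame(t = model$t)
  if (model$n_ortho > 0) scores <- cbind(scores, t_o = model$t_o)
  utils::write.csv(scores, file.path(dir, "scores.csv"), row.names = FALSE)
  stats_df <- data.frame(
    key = c("n_ortho", "c", "y_mean", "r2x_cum", "r2y_cum", "rmsee",
            "class_neg", "class_pos"),
    value = c(model$n_ortho, model$c, model$y_mean, model$r2x_cum,
              model$r2y_cum, model$rmsee,
              model$class_labels[1], model$class_labels[2]))
  utils::write.csv(stats_df, file.path(dir, "stats.csv"), row.names = FALSE)
  manifest <- data.frame(file = c("features.csv", "scores.csv", "stats.csv"))
  manifest$md5 <- tools::md5sum(file.path(dir, manifest$file))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
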