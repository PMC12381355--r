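#' Long-format observation table for mixed modelling
#'
#' One row per study observation: participant, sex, trial, timepoint,
#' metabolite and value. Values are natural-log abundances (multiplicative
#' error model), so the time x trial interaction surface is on the log
#' scale; divide by `log(2)` to read effects as log2 fold changes, or use
#' `log2_scale = TRUE` to store log2 values directly.
#'
#' @param dataset an imputed `AbundanceDataset`.
#' @param features feature ids to include (default: all).
#' @param log2_scale store log2 rather than natural-log values
#'   (default `TRUE`, so contrasts read as log2 fold-change differences).
#' @return a `LongTable` data.frame.
#' @export
make_long_table <- function(dataset, features = NULL, log2_scale = TRUE) {
  study <- which(is_study(dataset))
  m <- dataset$matrix[study, , drop = FALSE]
  if (anyNA(m)) stop("impute before building the long table", call. = FALSE)
  if (is.null(features)) features <- colnames(m)
  meta <- dataset$sample_meta[study, , drop = FALSE]
  out <- do.call(rbind, lapply(features, function(f) {
    data.frame(participant_id = meta$participant_id, sex = meta$sex,
               trial = meta$trial, timepoint = meta$timepoint,
               metabolite_id = f,
               value = if (log2_scale) log2(m[, f]) else log(m[, f]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("LongTable", "data.frame")
  out
}

lmm_prepare <- function(table, metabolite) {
  d <- table[table$metabolite_id == metabolite, , drop = FALSE]
  if (!nrow(d)) stop("metabolite not in table: ", metabolite, call. = FALSE)
  d$timepoint <- factor(d$timepoint, levels = VALID_TIMEPOINTS)  # ref pre
  d$trial <- factor(d$trial, levels = VALID_TRIALS)              # ref moderate
  d$sex <- factor(d$sex, levels = VALID_SEXES)
  d$sex <- stats::relevel(d$sex, ref = "female")
  d$participant_id <- factor(d$participant_id)
  if (nlevels(d$participant_id) < 2) {
    stop("need >= 2 participants", call. = FALSE)
  }
  d
}

#' Per-metabolite linear mixed model
#'
#' REML fit of `value ~ timepoint * trial + sex` with a participant random
#' intercept. Treatment coding with reference levels pre, moderate, female.
#' When `heteroscedastic = TRUE`, a second fit adds per-trial residual
#' variances (`varIdent` structure); the two forms are compared by AIC and
#' the lower wins — heterogeneous variance is kept only where it improves
#' the model fit. If the mixed fit fails to converge the homoscedastic form
#' is attempted; if all mixed fits fail (e.g., noise-free degenerate data)
#' an ordinary least-squares fallback supplies the fixed effects with
#' `model_form = "ols-degenerate"`.
#'
#' @param table a `LongTable` (see [make_long_table()]).
#' @param metabolite feature id to fit.
#' @param heteroscedastic consider the per-trial residual-variance form.
#' @param sex_by_trial add a sex x trial interaction (off by default).
#' @return an `LmmFit`: fixed effects with SEs, vcov, variance components,
#'   loglik/AIC, `model_form` and `converged`.
#' @export
fit_metabolite_lmm <- function(table, metabolite, heteroscedastic = TRUE,
                               sex_by_trial = FALSE) {
  d <- lmm_prepare(table, metabolite)
  form <- if (sex_by_trial) {
    value ~ timepoint * trial + sex * trial
  } else {
    value ~ timepoint * trial + sex
  }
  fit_hom <- try_lme(form, d, weights = NULL)
  fit_het <- if (heteroscedastic) {
    try_lme(form, d, weights = nlme::varIdent(form = ~ 1 | trial))
  } else NULL

  pick <- NULL
  model_form <- NULL
  if (!is.null(fit_het) && !is.null(fit_hom)) {
    if (stats::AIC(fit_het) < stats::AIC(fit_hom)) {
      pick <- fit_het; model_form <- "heteroscedastic"
    } else {
      pick <- fit_hom; model_form <- "homoscedastic"
    }
  } else if (!is.null(fit_het)) {
    pick <- fit_het; model_form <- "heteroscedastic"
  } else if (!is.null(fit_hom)) {
    pick <- fit_hom; model_form <- "homoscedastic"
  }

  if (is.null(pick)) {
    # degenerate data (e.g., zero residual variance): OLS recovers the
    # fixed-effect surface exactly
    ols <- stats::lm(form, data = d)
    beta <- stats::coef(ols)
    V <- stats::vcov(ols)
    V[is.na(V)] <- 0
    return(structure(list(
      metabolite = metabolite,
      fixed_effects = data.frame(term = names(beta), estimate = unname(beta),
                                 se = sqrt(diag(V))),
      vcov = V, var_participant = 0,
      var_residual_by_trial = stats::setNames(
        rep(summary(ols)$sigma^2, 3), VALID_TRIALS),
      loglik = as.numeric(stats::logLik(ols)), aic = stats::AIC(ols),
      model_form = "ols-degenerate", converged = TRUE, data = d),
      class = "LmmFit"))
  }

  beta <- nlme::fixef(pick)
  V <- stats::vcov(pick)
  sig2 <- pick$sigma^2
  vc <- nlme::VarCorr(pick)
  var_part <- suppressWarnings(as.numeric(vc["(Intercept)", "Variance"]))
  if (!is.finite(var_part)) var_part <- 0
  if (model_form == "heteroscedastic") {
    rel <- stats::coef(pick$modelStruct$varStruct, unconstrained = FALSE,
                       allCoef = TRUE)
    var_res <- sig2 * rel[VALID_TRIALS]^2
    names(var_res) <- VALID_TRIALS
  } else {
    var_res <- stats::setNames(rep(sig2, 3), VALID_TRIALS)
  }
  structure(list(
    metabolite = metabolite,
    fixed_effects = data.frame(term = names(beta), estimate = unname(beta),
                               se = sqrt(diag(as.matrix(V)))),
    vcov = as.matrix(V), var_participant = var_part,
    var_residual_by_trial = var_res,
    loglik = as.numeric(stats::logLik(pick)), aic = stats::AIC(pick),
    model_form = model_form, converged = TRUE, data = d),
    class = "LmmFit")
}

try_lme <- function(form, d, weights) {
  ctrl <- nlme::lmeControl(maxIter = 200, msMaxIter = 200, opt = "optim",
                           returnObject = FALSE)
  out <- tryCatch(
    suppressWarnings(nlme::lme(
      fixed = form, random = ~ 1 | participant_id, data = d,
      weights = weights, method = "REML", control = ctrl)),
    error = function(e) NULL)
  out
}

#' @export
print.LmmFit <- function(x, ...) {
  cat("LmmFit [", x$metabolite, "] ", x$model_form,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(x$fixed_effects, digits = 4)
  invisible(x)
}

contrast_vectors <- function(terms, kind = c("prepost", "fc")) {
  kind <- match.arg(kind)
  L <- matrix(0, 3, length(terms),
              dimnames = list(c("moderate-heavy", "moderate-severe",
                                "heavy-severe"), terms))
  if (kind == "prepost") {
    ih <- "timepointpost:trialheavy"
    is_ <- "timepointpost:trialsevere"
    L["moderate-heavy", ih] <- -1
    L["moderate-severe", is_] <- -1
    L["heavy-severe", ih] <- 1
    L["heavy-severe", is_] <- -1
  } else {
    L["moderate-heavy", "trialheavy"] <- -1
    L["moderate-severe", "trialsevere"] <- -1
    L["heavy-severe", "trialheavy"] <- 1
    L["heavy-severe", "trialsevere"] <- -1
  }
  L
}

#' Pairwise trial contrasts of the pre-to-post change
#'
#' Interaction contrasts on the time x trial surface: differences in the
#' pre-to-post change between trial pairs (moderate-heavy, moderate-severe,
#' heavy-severe; positive = larger change in the first-named trial).
#' Inference is Wald-z on the fixed-effect covariance; BH adjustment is
#' applied within the per-metabolite family of 3 contrasts.
#'
#' @param fit a converged `LmmFit` (or `FcLmmFit`).
#' @return a `ContrastResult` data.frame: `contrast`, `estimate`, `se`,
#'   `z`, `p_raw`, `p_bh`.
#' @export
pairwise_contrasts <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("pairwise_contrasts requires a converged fit", call. = FALSE)
  }
  kind <- if (inherits(fit, "FcLmmFit")) "fc" else "prepost"
  beta <- stats::setNames(fit$fixed_effects$estimate,
                          fit$fixed_effects$term)
  L <- contrast_vectors(names(beta), kind)
  est <- drop(L %*% beta)
  se <- sqrt(diag(L %*% fit$vcov %*% t(L)))
  z <- ifelse(se > 0, est / se, ifelse(abs(est) < 1e-12, 0, Inf))
  p <- 2 * stats::pnorm(-abs(z))
  p[p <= 0] <- .Machine$double.xmin
  out <- data.frame(metabolite_id = fit$metabolite,
                    contrast = rownames(L), estimate = unname(est),
                    se = unname(se), z = unname(z), p_raw = unname(p),
                    p_bh = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ContrastResult", "data.frame")
  out
}

#' Mixed model on the log2 fold-change table
#'
#' Equivalent entry point to [fit_metabolite_lmm()] for balanced data:
#' fits `log2FC ~ trial + sex` with a participant random intercept
#' (optionally trial-heteroscedastic), so trial contrasts are directly the
#' between-trial differences in log2 fold change.
#'
#' @param fc_table a `FoldChangeTable`.
#' @param feature feature id.
#' @param heteroscedastic consider per-trial residual variances by AIC.
#' @return an `FcLmmFit` (same fields as `LmmFit`).
#' @export
fit_fc_lmm <- function(fc_table, feature, heteroscedastic = TRUE) {
  j <- match(feature, colnames(fc_table$values))
  if (is.na(j)) stop("feature not in fold-change table: ", feature,
                     call. = FALSE)
  d <- data.frame(participant_id = factor(fc_table$meta$participant_id),
                  trial = factor(fc_table$meta$trial, levels = VALID_TRIALS),
                  sex = stats::relevel(factor(fc_table$meta$sex,
                                              levels = VALID_SEXES),
                                       ref = "female"),
                  value = fc_table$values[, j])
  fit_hom <- try_lme(value ~ trial + sex, d, weights = NULL)
  fit_het <- if (heteroscedastic) {
    try_lme(value ~ trial + sex, d,
            weights = nlme::varIdent(form = ~ 1 | trial))
  } else NULL
  pick <- fit_hom; model_form <- "homoscedastic"
  if (!is.null(fit_het) &&
      (is.null(fit_hom) || stats::AIC(fit_het) < stats::AIC(fit_hom))) {
    pick <- fit_het; model_form <- "heteroscedastic"
  }
  if (is.null(pick)) {
    ols <- stats::lm(value ~ trial + sex, data = d)
    beta <- stats::coef(ols)
    V <- stats::vcov(ols); V[is.na(V)] <- 0
    return(structure(list(
      metabolite = feature,
      fixed_effects = data.frame(term = names(beta),
                                 estimate = unname(beta),
                                 se = sqrt(diag(V))),
      vcov = V, var_participant = 0,
      var_residual_by_trial = stats::setNames(
        rep(summary(ols)$sigma^2, 3), VALID_TRIALS),
      loglik = as.numeric(stats::logLik(ols)), aic = stats::AIC(ols),
      model_form = "ols-degenerate", converged = TRUE, data = d),
      class = c("FcLmmFit", "LmmFit")))
  }
  beta <- nlme::fixef(pick)
  structure(list(
    metabolite = feature,
    fixed_effects = data.frame(term = names(beta), estimate = unname(beta),
                               se = sqrt(diag(as.matrix(stats::vcov(pick))))),
    vcov = as.matrix(stats::vcov(pick)),
    var_participant = {
      vp <- suppressWarnings(as.numeric(
        nlme::VarCorr(pick)["(Intercept)", "Variance"]))
      if (is.finite(vp)) vp else 0
    },
    var_residual_by_trial = if (model_form == "heteroscedastic") {
      rel <- stats::coef(pick$modelStruct$varStruct, unconstrained = FALSE,
                         allCoef = TRUE)
      stats::setNames(pick$sigma^2 * rel[VALID_TRIALS]^2, VALID_TRIALS)
    } else stats::setNames(rep(pick$sigma^2, 3), VALID_TRIALS),
    loglik = as.numeric(stats::logLik(pick)), aic = stats::AIC(pick),
    model_form = model_form, converged = TRUE, data = d),
    class = c("FcLmmFit", "LmmFit"))
}

#' Cluster-bootstrap confidence interval for a trial contrast
#'
#' Nonparametric case bootstrap: participants are resampled with
#' replacement (keeping each participant's full set of observations), the
#' model refit per replicate with the full-data model form, and the 2.5/97.5
#' percentiles of the contrast estimate returned. Replicates whose refit
#' fails are dropped and counted; more than 50% failures is an error.
#'
#' @param table a `LongTable`.
#' @param metabolite feature id.
#' @param contrast one of `"moderate-heavy"`, `"moderate-severe"`,
#'   `"heavy-severe"`.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param heteroscedastic passed to the refits.
#' @return list with `ci_low`, `ci_high`, `estimates` (replicate values)
#'   and `n_failed`.
#' @export
bootstrap_ci <- function(table, metabolite, contrast, B = 1000, seed = 1L,
                         heteroscedastic = TRUE) {
  full <- fit_metabolite_lmm(table, metabolite,
                             heteroscedastic = heteroscedastic)
  if (!full$converged) stop("full-data fit did not converge", call. = FALSE)
  d <- table[table$metabolite_id == metabolite, , drop = FALSE]
  parts <- unique(d$participant_id)
  set.seed(as.integer(seed))
  est <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    draw <- sample(parts, length(parts), replace = TRUE)
    boot <- do.call(rbind, lapply(seq_along(draw), function(i) {
      di <- d[d$participant_id == draw[i], , drop = FALSE]
      di$participant_id <- paste0("bs", i)  # duplicates become new clusters
      di
    }))
    class(boot) <- c("LongTable", "data.frame")
    fit_b <- tryCatch(
      fit_metabolite_lmm(boot, metabolite,
                         heteroscedastic = full$model_form ==
                           "heteroscedastic"),
      error = function(e) NULL)
    if (is.null(fit_b) || !fit_b$converged) next
    cr <- tryCatch(pairwise_contrasts(fit_b), error = function(e) NULL)
    if (is.null(cr)) next
    est[b] <- cr$estimate[cr$contrast == contrast]
  }
  ok <- !is.na(est)
  if (mean(ok) < 0.5) {
    stop("more than 50% of bootstrap replicates failed to converge",
         call. = FALSE)
  }
  qs <- stats::quantile(est[ok], c(0.025, 0.975), names = FALSE, type = 7)
  list(ci_low = qs[1], ci_high = qs[2], estimates = est[ok],
       n_failed = sum(!ok))
}

#' Contrast results for many metabolites, exported shape
#'
#' Fits each metabolite, computes the three pairwise contrasts, and
#' optionally attaches cluster-bootstrap CIs.
#'
#' @param table a `LongTable`.
#' @param metabolites feature ids (default: all in the table).
#' @param heteroscedastic consider the heteroscedastic form.
#' @param bootstrap_B replicates for CIs; 0 skips the bootstrap.
#' @param seed integer seed for the bootstrap.
#' @return data.frame: metabolite_id, contrast, estimate, se, p_raw, p_bh,
#'   ci_low, ci_high, model_form, converged.
#' @export
lmm_contrast_table <- function(table, metabolites = NULL,
                               heteroscedastic = TRUE, bootstrap_B = 0,
                               seed = 1L) {
  if (is.null(metabolites)) metabolites <- unique(table$metabolite_id)
  out <- lapply(metabolites, function(mm) {
    fit <- tryCatch(fit_metabolite_lmm(table, mm,
                                       heteroscedastic = heteroscedastic),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(metabolite_id = mm, contrast = NA, estimate = NA,
                        se = NA, z = NA, p_raw = NA, p_bh = NA,
                        ci_low = NA, ci_high = NA, model_form = "failed",
                        converged = FALSE))
    }
    cr <- pairwise_contrasts(fit)
    cr$ci_low <- NA_real_; cr$ci_high <- NA_real_
    if (bootstrap_B > 0) {
      for (i in seq_len(nrow(cr))) {
        ci <- tryCatch(
          bootstrap_ci(table, mm, cr$contrast[i], B = bootstrap_B,
                       seed = derive_seed(seed, paste0(mm, cr$contrast[i])),
                       heteroscedastic = heteroscedastic),
          error = function(e) NULL)
        if (!is.null(ci)) {
          cr$ci_low[i] <- ci$ci_low; cr$ci_high[i] <- ci$ci_high
        }
      }
    }
    cr$model_form <- fit$model_form
    cr$converged <- fit$converged
    cr
  })
  do.call(rbind, out)
}
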