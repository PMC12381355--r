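#' Per-feature relative standard deviation over QC injections
#'
#' RSD (coefficient of variation, percent) of each feature across the
#' pooled-QC injections: `100 * sd(QC values) / mean(QC values)` with the
#' sample (n-1) SD. Features with fewer than two non-missing QC values, or
#' a non-positive QC mean, are flagged undefined (`NA`).
#'
#' @param dataset an `AbundanceDataset` containing QC samples.
#' @return named numeric vector of percent RSDs (`NA` = undefined).
#' @export
compute_feature_rsd <- function(dataset) {
  qc <- dataset$matrix[is_qc(dataset), , drop = FALSE]
  if (nrow(qc) == 0) {
    stop("dataset contains no QC samples; RSD undefined", call. = FALSE)
  }
  apply(qc, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m <= 0) return(NA_real_)
    100 * stats::sd(v) / m
  })
}

#' Apply the feature-quality filters
#'
#' Three rules, all strict inequalities so boundary cases are retained:
#' \enumerate{
#'   \item RSD filter: LC-MS features with QC RSD strictly above `rsd_max`
#'     percent (or undefined RSD) are removed.
#'   \item Intensity filter: LC-MS features with intensity below
#'     `intensity_floor` in strictly more than `qc_low_frac` of QC
#'     injections are removed (missing QC values count as below the floor).
#'   \item Missingness filter: features missing in strictly more than
#'     `missing_max` of the study samples are removed (all platforms).
#' }
#' The RSD and intensity rules apply only to the `lcms-lipid` platform
#' stratum; NMR-derived concentrations are exempt. Filters are evaluated on
#' the input dataset and the union of violations removed.
#'
#' @param dataset an `AbundanceDataset`.
#' @param rsd_max percent RSD ceiling (default 30).
#' @param intensity_floor LC-MS intensity floor (default 5000 counts).
#' @param qc_low_frac fraction of QC injections allowed below the floor
#'   (default 0.5).
#' @param missing_max maximum missing fraction across study samples
#'   (default 0.7).
#' @return list with `dataset` (filtered) and `report` (a `FilterReport`:
#'   removal sets per rule, thresholds, counts, and a per-feature table).
#' @export
apply_qc_filters <- function(dataset, rsd_max = 30, intensity_floor = 5000,
                             qc_low_frac = 0.5, missing_max = 0.7) {
  if (ncol(dataset$matrix) == 0 || nrow(dataset$matrix) == 0) {
    stop("empty dataset", call. = FALSE)
  }
  fid <- dataset$feature_meta$feature_id
  lcms <- dataset$feature_meta$platform == "lcms-lipid"
  n_qc <- sum(is_qc(dataset))
  if (any(lcms) && n_qc == 0) {
    stop("LC-MS features present but no QC samples to filter against",
         call. = FALSE)
  }

  rsd <- if (n_qc > 0) compute_feature_rsd(dataset) else
    stats::setNames(rep(NA_real_, length(fid)), fid)
  removed_rsd <- fid[lcms & (is.na(rsd) | rsd > rsd_max)]

  removed_intensity <- character(0)
  low_frac <- rep(NA_real_, length(fid))
  if (n_qc > 0) {
    qc <- dataset$matrix[is_qc(dataset), , drop = FALSE]
    low_frac <- colMeans(is.na(qc) | qc < intensity_floor)
    removed_intensity <- fid[lcms & low_frac > qc_low_frac]
  }

  study <- dataset$matrix[is_study(dataset), , drop = FALSE]
  miss_frac <- colMeans(is.na(study))
  removed_missing <- fid[miss_frac > missing_max]

  removed <- union(union(removed_rsd, removed_intensity), removed_missing)
  keep <- !(fid %in% removed)
  out <- subset_dataset(dataset, features = which(keep))

  table <- data.frame(
    feature_id = c(removed_rsd, removed_intensity, removed_missing),
    reason = rep(c("rsd", "intensity", "missingness"),
                 c(length(removed_rsd), length(removed_intensity),
                   length(removed_missing))),
    statistic = c(rsd[removed_rsd], low_frac[match(removed_intensity, fid)],
                  miss_frac[match(removed_missing, fid)]),
    threshold = rep(c(rsd_max, qc_low_frac, missing_max),
                    c(length(removed_rsd), length(removed_intensity),
                      length(removed_missing))),
    stringsAsFactors = FALSE, row.names = NULL)

  report <- structure(list(
    n_input_features = length(fid),
    removed_rsd = removed_rsd,
    removed_intensity = removed_intensity,
    removed_missing = removed_missing,
    n_retained = sum(keep),
    thresholds = c(rsd_max = rsd_max, intensity_floor = intensity_floor,
                   qc_low_frac = qc_low_frac, missing_max = missing_max),
    table = table,
    status = if (sum(keep) == 0) "warning: all features removed" else "ok"),
    class = "FilterReport")
  if (sum(keep) == 0) {
    warning("all features removed by QC filters", call. = FALSE)
  }
  list(dataset = out, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:", x$n_input_features, "features in,",
      x$n_retained, "retained (",
      length(x$removed_rsd), "RSD,",
      length(x$removed_intensity), "intensity,",
      length(x$removed_missing), "missingness removals )\n")
  invisible(x)
}

#' Write a filter report as CSV
#' @param report a `FilterReport`
#' @param path output CSV path
#' @return invisibly, the report
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(report)
}

#' Iterative random-forest imputation of missing abundances
#'
#' Fills remaining missing study cells with the iterative per-feature
#' random-forest scheme: initialize missing entries with feature means,
#' sweep features in order of increasing missingness, regress each feature
#' with missing values on all other features in its platform stratum
#' (random-forest regression, observed rows as training set), and replace
#' its missing entries with out-of-sample predictions. Sweeps repeat until
#' the normalized change in the imputed values increases (the classic
#' stopping rule for this scheme) or `max_iter` is reached, and the last
#' solution before the increase is returned. Imputation runs per platform
#' stratum on natural-log abundances and is exponentiated back, matching a
#' multiplicative error model. QC rows are excluded from both training and
#' imputation. Observed cells are never altered.
#'
#' @param dataset an `AbundanceDataset` (filters already applied).
#' @param n_trees trees per forest (default 100).
#' @param max_iter maximum sweeps (default 10).
#' @param seed integer seed; imputation is deterministic given it.
#' @return the dataset with no missing study cells.
#' @export
impute_missforest <- function(dataset, n_trees = 100, max_iter = 10,
                              seed = 1L) {
  study_rows <- which(is_study(dataset))
  m <- dataset$matrix[study_rows, , drop = FALSE]
  if (!anyNA(m)) return(dataset)
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    stop("features 100% missing (filters not applied?): ",
         paste(colnames(m)[all_missing], collapse = ", "), call. = FALSE)
  }
  platforms <- dataset$feature_meta$platform
  for (pf in unique(platforms)) {
    cols <- which(platforms == pf)
    block <- m[, cols, drop = FALSE]
    if (anyNA(block)) {
      na_cells <- is.na(block)
      imputed <- impute_block_rf(log(block), n_trees, max_iter,
                                 derive_seed(seed, pf))
      block[na_cells] <- imputed[na_cells]  # observed cells never altered
      m[, cols] <- block
    }
  }
  dataset$matrix[study_rows, ] <- m
  dataset
}

# Core iterative RF sweep on one log-scale block; returns exp()-backtransformed
# matrix. Single-feature blocks fall back to mean imputation (no predictors).
impute_block_rf <- function(logm, n_trees, max_iter, seed) {
  miss <- is.na(logm)
  filled <- logm
  col_means <- colMeans(logm, na.rm = TRUE)
  for (j in seq_len(ncol(logm))) {
    filled[miss[, j], j] <- col_means[j]
  }
  if (ncol(logm) < 2) return(exp(filled))
  target_cols <- which(colSums(miss) > 0)
  target_cols <- target_cols[order(colSums(miss)[target_cols])]
  prev <- filled
  prev_delta <- Inf
  best <- filled
  for (iter in seq_len(max_iter)) {
    for (j in target_cols) {
      obs <- !miss[, j]
      df <- as.data.frame(filled[, -j, drop = FALSE])
      names(df) <- paste0("x", seq_len(ncol(df)))
      train <- df[obs, , drop = FALSE]
      train$.y <- filled[obs, j]
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = train,
        num.trees = n_trees, seed = derive_seed(seed, paste0(iter, "_", j)),
        num.threads = 1)
      filled[miss[, j], j] <-
        stats::predict(fit, df[miss[, j], , drop = FALSE],
                       num.threads = 1)$predictions
    }
    delta <- sum((filled[miss] - prev[miss])^2) / max(sum(filled[miss]^2),
                                                     .Machine$double.eps)
    if (delta > prev_delta) break  # divergence: keep previous sweep
    best <- filled
    prev <- filled
    prev_delta <- delta
    if (delta < 1e-10) break
  }
  exp(best)
}
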