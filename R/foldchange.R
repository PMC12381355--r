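#' Per-participant log2 fold changes
#'
#' Collapses each participant x trial pair of study samples to
#' `log2(post / pre)` per feature — the quantity the multivariate
#' trial-comparison and univariate contrast stages consume. Pairs lacking
#' either timepoint are dropped with a warning naming them.
#'
#' @param dataset an imputed `AbundanceDataset` (no missing study cells).
#' @return a `FoldChangeTable`: list with `values` (matrix, one row per
#'   participant x trial, columns = features) and `meta` (data.frame with
#'   `participant_id`, `trial`, `sex`).
#' @export
compute_log2fc <- function(dataset) {
  study <- which(is_study(dataset))
  m <- dataset$matrix[study, , drop = FALSE]
  meta <- dataset$sample_meta[study, , drop = FALSE]
  if (anyNA(m)) {
    stop("dataset contains missing study cells; impute before fold changes",
         call. = FALSE)
  }
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop("nonpositive abundance for sample ", meta$sample_id[bad[1]],
         ", feature ", colnames(m)[bad[2]], ": cannot take log",
         call. = FALSE)
  }
  key <- interaction(meta$participant_id, meta$trial, drop = TRUE)
  rows <- list()
  info <- list()
  for (k in levels(key)) {
    idx <- which(key == k)
    pre <- idx[meta$timepoint[idx] == "pre"]
    post <- idx[meta$timepoint[idx] == "post"]
    if (length(pre) != 1 || length(post) != 1) {
      warning("dropping ", k, ": needs exactly one pre and one post sample",
              call. = FALSE)
      next
    }
    rows[[k]] <- log2(m[post, ] / m[pre, ])
    info[[k]] <- meta[pre, c("participant_id", "trial", "sex")]
  }
  if (!length(rows)) stop("no complete pre/post pairs found", call. = FALSE)
  values <- do.call(rbind, rows)
  fc_meta <- do.call(rbind, info)
  rownames(values) <- rownames(fc_meta) <- NULL
  ord <- order(fc_meta$participant_id, match(fc_meta$trial, VALID_TRIALS))
  structure(list(values = values[ord, , drop = FALSE],
                 meta = fc_meta[ord, , drop = FALSE]),
            class = "FoldChangeTable")
}

#' @export
print.FoldChangeTable <- function(x, ...) {
  cat("FoldChangeTable:", nrow(x$values), "participant x trial rows,",
      ncol(x$values), "features\n")
  invisible(x)
}

#' Write / read a fold-change table as CSV
#'
#' The two-column key (`participant_id`, `trial`) plus `sex` precede the
#' feature columns.
#' @param fc a `FoldChangeTable`
#' @param path CSV path
#' @return invisibly `fc` (write) / a `FoldChangeTable` (read)
#' @export
write_fc_csv <- function(fc, path) {
  utils::write.csv(data.frame(fc$meta, fc$values, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(fc)
}

#' @rdname write_fc_csv
#' @export
read_fc_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- c("participant_id", "trial", "sex")
  structure(list(values = as.matrix(df[, setdiff(names(df), meta_cols),
                                       drop = FALSE]),
                 meta = df[, meta_cols, drop = FALSE]),
            class = "FoldChangeTable")
}

#' Auto-scale (unit-variance) and mean-center a matrix
#'
#' Each column is centered to mean zero and divided by its population
#' standard deviation (divisor `n`, not `n - 1`). Zero-variance columns are
#' centered, left at zero, and flagged. The centering and scaling vectors
#' are attached as attributes so held-out data can be scaled with training
#' parameters rather than their own.
#'
#' @param x numeric matrix without missing values, >= 2 rows.
#' @param center,scale optional training parameters to apply instead of
#'   computing them from `x` (used when projecting new data).
#' @return the scaled matrix with attributes `center`, `scale` (the raw
#'   population SDs, before zero-variance protection) and `zero_variance`
#'   (logical flag per column).
#' @export
autoscale <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) {
    if (nrow(x) < 2) stop("autoscale needs >= 2 rows", call. = FALSE)
    if (anyNA(x)) stop("autoscale requires a complete matrix", call. = FALSE)
    center <- colMeans(x)
    scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  }
  zero_var <- scale < .Machine$double.eps^0.5
  divisor <- ifelse(zero_var, 1, scale)
  out <- sweep(sweep(x, 2, center), 2, divisor, "/")
  out[, zero_var] <- 0
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  attr(out, "zero_variance") <- zero_var
  out
}
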