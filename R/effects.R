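utils::globalVariables(c("cliffs_delta", "vip", "neg_log10_p"))

#' Cliff's delta effect size
#'
#' Probability-of-superiority effect size
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y)`, in `[-1, 1]`;
#' tied pairs contribute zero. Computed in `O((n+m) log m)` from sorted
#' positions rather than the `O(nm)` pairwise enumeration (the enumeration
#' is retained in the test suite as an oracle).
#'
#' @param x,y non-empty numeric vectors.
#' @return delta in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("cliffs_delta needs non-empty vectors", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("cliffs_delta: NA values", call. = FALSE)
  sy <- sort(y)
  n_le <- findInterval(x, sy)                   # y <= x_i
  n_lt <- findInterval(x, sy, left.open = TRUE) # y <  x_i
  n_gt <- length(y) - n_le
  (sum(n_lt) - sum(n_gt)) / (length(x) * length(y))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with input validation: all
#' p-values must lie in (0, 1].
#'
#' @param p_values numeric vector of raw p-values.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Eruption table: effect size x multivariate importance x significance
#'
#' For the two compared trials, each feature gets: Cliff's delta across the
#' per-participant log2 fold changes of the two groups (orientation
#' `trial_a` vs `trial_b`: positive delta means higher in `trial_a`); the
#' VIP score from the supplied OPLS-DA model; a two-sided per-feature
#' p-value (Welch's t-test by default, Wilcoxon rank-sum optionally) with
#' BH adjustment across features; and the key-feature flag
#' `vip > vip_min & p < alpha`.
#'
#' @param fc_table a `FoldChangeTable` covering both trials.
#' @param model an `OplsModel` fitted on the same comparison.
#' @param comparison character pair `c(trial_a, trial_b)`.
#' @param test per-feature test, `"welch"` or `"wilcoxon"`.
#' @param vip_min VIP threshold for key features (default 3).
#' @param alpha raw-p threshold for key features (default 0.05).
#' @return an `EruptionTable` data.frame: `feature_id`, `cliffs_delta`,
#'   `vip`, `p_value`, `p_adjusted`, `neg_log10_p`, `key_feature`.
#' @export
eruption_table <- function(fc_table, model, comparison = c("moderate",
                                                           "severe"),
                           test = c("welch", "wilcoxon"),
                           vip_min = 3, alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(length(comparison) == 2)
  present <- comparison %in% fc_table$meta$trial
  if (!all(present)) {
    stop("trial absent from fold-change table: ",
         paste(comparison[!present], collapse = ", "), call. = FALSE)
  }
  a <- fc_table$meta$trial == comparison[1]
  b <- fc_table$meta$trial == comparison[2]
  vip <- model$vip
  feats <- colnames(fc_table$values)
  vip <- vip[match(feats, names(vip))]
  delta <- p <- numeric(length(feats))
  for (j in seq_along(feats)) {
    xa <- fc_table$values[a, j]
    xb <- fc_table$values[b, j]
    delta[j] <- cliffs_delta(xa, xb)
    p[j] <- if (test == "welch") {
      if (stats::sd(xa) + stats::sd(xb) < 1e-12) {
        if (abs(mean(xa) - mean(xb)) < 1e-12) 1 else .Machine$double.xmin
      } else {
        stats::t.test(xa, xb)$p.value
      }
    } else {
      stats::wilcox.test(xa, xb, exact = FALSE)$p.value
    }
  }
  p[p <= 0] <- .Machine$double.xmin
  out <- data.frame(
    feature_id = feats,
    cliffs_delta = delta,
    vip = unname(vip),
    p_value = p,
    p_adjusted = bh_adjust(p),
    neg_log10_p = -log10(p),
    key_feature = !is.na(vip) & vip > vip_min & p < alpha,
    stringsAsFactors = FALSE)
  class(out) <- c("EruptionTable", "data.frame")
  out
}

#' Eruption plot (delta vs VIP, colored by -log10 p)
#'
#' Scatter of Cliff's delta against VIP with significance color; key
#' features are labelled. Requires ggplot2.
#'
#' @param table an `EruptionTable`.
#' @return a ggplot object.
#' @export
plot_eruption <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_eruption requires ggplot2", call. = FALSE)
  }
  ggplot2::ggplot(table,
                  ggplot2::aes(x = cliffs_delta, y = vip,
                               color = neg_log10_p)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 3, linetype = 2) +
    ggplot2::scale_color_viridis_c(name = expression(-log[10] * p)) +
    ggplot2::labs(x = "Cliff's delta", y = "VIP") +
    ggplot2::theme_minimal()
}
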