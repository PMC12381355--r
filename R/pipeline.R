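#' Run configuration for the end-to-end analysis
#'
#' Consolidates the analysis parameters: the QC-filter thresholds, the
#' trial comparison fitted by OPLS-DA on log2 fold changes (default
#' moderate vs severe) with the remaining trial projected (default heavy),
#' cross-validation folds, permutation count, key-feature thresholds, and
#' the single seed from which every stage's random stream is derived.
#'
#' @param input either a `CohortConfig` (synthetic run) or a list with
#'   `matrix_path`, `metadata_path` and optional `feature_path`.
#' @param comparison trial pair for the fold-change OPLS-DA model.
#' @param projected trial projected onto that model.
#' @param rsd_max,intensity_floor,qc_low_frac,missing_max QC thresholds.
#' @param vip_min,alpha key-feature thresholds.
#' @param cv_folds,n_perm,n_ortho OPLS-DA settings; `n_ortho = "auto"`
#'   selects the count by cross-validation.
#' @param bootstrap_B contrast-CI replicates (0 disables).
#' @param max_lmm_features cap on per-metabolite mixed-model fits; the
#'   highest-VIP features are taken first.
#' @param fit_pre_post also fit the per-trial pre-vs-post OPLS-DA models
#'   on auto-scaled abundances.
#' @param impute_trees,impute_max_iter imputation settings.
#' @param seed integer master seed.
#' @return a `RunConfig`.
#' @export
run_config <- function(input = cohort_config(),
                       comparison = c("moderate", "severe"),
                       projected = "heavy",
                       rsd_max = 30, intensity_floor = 5000,
                       qc_low_frac = 0.5, missing_max = 0.7,
                       vip_min = 3, alpha = 0.05,
                       cv_folds = 8, n_perm = 50, n_ortho = 1,
                       bootstrap_B = 0, max_lmm_features = 20,
                       fit_pre_post = TRUE,
                       impute_trees = 100, impute_max_iter = 10,
                       seed = 1L) {
  stopifnot(length(comparison) == 2)
  if (comparison[1] == comparison[2]) {
    stop("comparison trials must be distinct", call. = FALSE)
  }
  if (projected %in% comparison) {
    stop("projected trial must not be in the comparison pair", call. = FALSE)
  }
  structure(list(input = input, comparison = comparison,
                 projected = projected,
                 rsd_max = rsd_max, intensity_floor = intensity_floor,
                 qc_low_frac = qc_low_frac, missing_max = missing_max,
                 vip_min = vip_min, alpha = alpha, cv_folds = cv_folds,
                 n_perm = n_perm, n_ortho = n_ortho,
                 bootstrap_B = bootstrap_B,
                 max_lmm_features = max_lmm_features,
                 fit_pre_post = fit_pre_post,
                 impute_trees = impute_trees,
                 impute_max_iter = impute_max_iter,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Execute the full analysis
#'
#' Stage order: load or simulate -> QC filters -> imputation -> log2 fold
#' changes -> OPLS-DA (per-trial pre-vs-post on auto-scaled abundances,
#' then the trial comparison on fold changes with permutation validation
#' and projection of the held-out trial) -> eruption table -> per-metabolite
#' mixed-model contrasts. All randomness derives from `config$seed` via the
#' stage-name seed scheme, so a rerun with an identical config reproduces
#' identical outputs and adding a stage never perturbs the others.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all result tables are
#'   written as CSVs with an md5 manifest.
#' @return a `RunResult` list: `filter_report`, `fc_table`, `prepost`
#'   (per-trial model + permutation), `comparison_model`,
#'   `comparison_permutation`, `projection`, `eruption`, `contrasts`,
#'   `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  stage <- "input"
  result <- tryCatch({
    dataset <- if (inherits(config$input, "CohortConfig")) {
      synth <- generate_cohort(config$input)
      synth$dataset
    } else {
      load_abundance_csv(config$input$matrix_path,
                         config$input$metadata_path,
                         config$input$feature_path)
    }

    stage <- "qcfilter"
    filtered <- apply_qc_filters(dataset, rsd_max = config$rsd_max,
                                 intensity_floor = config$intensity_floor,
                                 qc_low_frac = config$qc_low_frac,
                                 missing_max = config$missing_max)
    stage <- "impute"
    imputed <- impute_missforest(filtered$dataset,
                                 n_trees = config$impute_trees,
                                 max_iter = config$impute_max_iter,
                                 seed = derive_seed(config$seed, "impute"))

    stage <- "foldchange"
    fc <- compute_log2fc(imputed)

    stage <- "opls_prepost"
    prepost <- list()
    if (config$fit_pre_post) {
      for (tr in VALID_TRIALS) {
        rows <- which(is_study(imputed) & imputed$sample_meta$trial == tr)
        X <- imputed$matrix[rows, , drop = FALSE]
        y <- imputed$sample_meta$timepoint[rows]
        no <- resolve_n_ortho(config, X, y,
                              derive_seed(config$seed, paste0("no_", tr)))
        perm <- permutation_test(X, y, n_perm = config$n_perm,
                                 k = config$cv_folds, n_ortho = no,
                                 seed = derive_seed(config$seed,
                                                    paste0("pp_", tr)))
        model <- fit_opls_da(X, y, n_ortho = no)
        cv <- cross_validate(X, y, k = config$cv_folds, n_ortho = no,
                             seed = derive_seed(config$seed,
                                                paste0("ppcv_", tr)))
        model$q2_cum <- cv$q2_cum
        prepost[[tr]] <- list(model = model, permutation = perm)
      }
    }

    stage <- "opls_comparison"
    in_cmp <- fc$meta$trial %in% config$comparison
    Xc <- fc$values[in_cmp, , drop = FALSE]
    yc <- fc$meta$trial[in_cmp]
    no_c <- resolve_n_ortho(config, Xc, yc,
                            derive_seed(config$seed, "no_cmp"))
    comparison_model <- fit_opls_da(Xc, yc, n_ortho = no_c)
    comparison_cv <- cross_validate(Xc, yc, k = config$cv_folds,
                                    n_ortho = no_c,
                                    seed = derive_seed(config$seed,
                                                       "cmp_cv"))
    comparison_model$q2_cum <- comparison_cv$q2_cum
    comparison_perm <- permutation_test(Xc, yc, n_perm = config$n_perm,
                                        k = config$cv_folds, n_ortho = no_c,
                                        seed = derive_seed(config$seed,
                                                           "cmp_perm"))

    stage <- "projection"
    proj_rows <- fc$meta$trial == config$projected
    projection <- if (any(proj_rows)) {
      project(comparison_model, fc$values[proj_rows, , drop = FALSE])
    } else NULL

    stage <- "effects"
    eruption <- eruption_table(fc, comparison_model,
                               comparison = config$comparison,
                               vip_min = config$vip_min,
                               alpha = config$alpha)

    stage <- "lmm"
    long <- make_long_table(imputed)
    lmm_feats <- names(sort(comparison_model$vip, decreasing = TRUE))
    lmm_feats <- utils::head(lmm_feats, config$max_lmm_features)
    contrasts <- lmm_contrast_table(long, lmm_feats,
                                    bootstrap_B = config$bootstrap_B,
                                    seed = derive_seed(config$seed, "boot"))

    list(filter_report = filtered$report, dataset = imputed,
         fc_table = fc, prepost = prepost,
         comparison_model = comparison_model,
         comparison_permutation = comparison_perm,
         projection = projection, eruption = eruption,
         contrasts = contrasts,
         provenance = list(config = config, seed = config$seed,
                           version = as.character(utils::packageVersion(
                             "swimmetab")),
                           timestamp = format(Sys.time(), tz = "UTC")))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(result) <- "RunResult"
  if (!is.null(out_dir)) write_run_result(result, out_dir)
  result
}

resolve_n_ortho <- function(config, X, y, seed) {
  if (identical(config$n_ortho, "auto")) {
    select_n_ortho(X, y, k = config$cv_folds, seed = seed)$n_ortho
  } else {
    config$n_ortho
  }
}

#' @export
print.RunResult <- function(x, ...) {
  cat("RunResult (seed", x$provenance$seed, ")\n")
  print(x$filter_report)
  cat("Trial comparison: ")
  print(x$comparison_model)
  print(x$comparison_permutation)
  cat(sum(x$eruption$key_feature), "key features (VIP/alpha thresholds)\n")
  invisible(x)
}

#' Write a run result as a directory of CSVs with a manifest
#'
#' @param result a `RunResult`; @param out_dir output directory
#' @return invisibly, the manifest data.frame
#' @export
write_run_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_filter_report(result$filter_report,
                      file.path(out_dir, "filter_report.csv"))
  write_fc_csv(result$fc_table, file.path(out_dir, "fold_changes.csv"))
  utils::write.csv(as.data.frame(result$eruption),
                   file.path(out_dir, "eruption.csv"), row.names = FALSE)
  utils::write.csv(result$contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  write_opls_model(result$comparison_model,
                   file.path(out_dir, "comparison_model"))
  if (!is.null(result$projection)) {
    utils::write.csv(
      data.frame(t = result$projection$t, margin = result$projection$margin),
      file.path(out_dir, "projection_scores.csv"), row.names = FALSE)
  }
  stats_df <- data.frame(
    key = c("r2x_cum", "r2y_cum", "q2_cum", "rmsee", "p_r2y", "p_q2",
            "n_key_features", "seed"),
    value = c(result$comparison_model$r2x_cum,
              result$comparison_model$r2y_cum,
              result$comparison_model$q2_cum %||% NA,
              result$comparison_model$rmsee,
              result$comparison_permutation$p_r2y,
              result$comparison_permutation$p_q2,
              sum(result$eruption$key_feature), result$provenance$seed))
  utils::write.csv(stats_df, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  files <- c("filter_report.csv", "fold_changes.csv", "eruption.csv",
             "contrasts.csv", "summary.csv",
             if (!is.null(result$projection)) "projection_scores.csv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(
                           file.path(out_dir, files))))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
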