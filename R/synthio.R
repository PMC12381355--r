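#' Configuration for the synthetic swimming-cohort generator
#'
#' Encodes the statistical design the analysis assumes: a trained cohort of
#' two sexes, paired pre/post plasma samples in the moderate, heavy and
#' severe exercise-intensity domains, feature classes with trial-specific
#' mean log2 fold-change effects, participant random intercepts,
#' trial-heteroscedastic residual noise, a sex-modulated free-fatty-acid
#' response in the severe trial, feature-wise missingness, and repeated
#' pooled-QC injections with a controlled relative standard deviation.
#'
#' Default effects mirror the study phenotype: free fatty acids rise after
#' the moderate-domain trial and are flat-to-down after the severe trial
#' (moderate minus severe difference about +1 log2 unit), while glycolytic
#' metabolites (lactate, pyruvate, alanine analogues) rise most after the
#' severe trial (severe minus moderate about +1.5). Abundances are generated
#' as `exp(Normal)` on the natural-log scale so they are strictly positive
#' and planted log2 effects convert exactly (multiplied by `ln 2`).
#'
#' @param n_participants number of swimmers (default 16).
#' @param sex_ratio fraction of males in `[0, 1]` (default 9/16).
#' @param n_features_per_class named counts for classes
#'   `ffa`, `glycolytic`, `lipoprotein`, `inert`.
#' @param effect_matrix numeric matrix, rows = classes, columns = trials
#'   (`moderate`, `heavy`, `severe`), entries = planted mean log2(post/pre).
#' @param sex_modulation additive shift of the FFA log2 fold change for
#'   males in the severe trial only.
#' @param sd_participant SD of the participant random intercept (log scale).
#' @param sd_residual_by_trial named per-trial residual SDs (log scale);
#'   the severe default is larger, emulating heteroscedasticity.
#' @param baseline_log_mean,baseline_log_sd log-abundance distribution of
#'   feature baselines. The default mean puts typical intensities around
#'   `exp(10) ~ 22000`, comfortably above the LC-MS intensity floor.
#' @param missing_rate fraction of study cells blanked (default 0.05; must
#'   stay below the 0.7 missingness filter so default features survive).
#' @param n_qc number of pooled-QC injections appended (default 10).
#' @param qc_rsd_target per-feature QC coefficient of variation, percent.
#' @param seed integer seed; identical configs generate identical data.
#' @return a `CohortConfig` list.
#' @export
cohort_config <- function(n_participants = 16,
                          sex_ratio = 9 / 16,
                          n_features_per_class = c(ffa = 100, glycolytic = 23,
                                                   lipoprotein = 112,
                                                   inert = 765),
                          effect_matrix = default_effect_matrix(),
                          sex_modulation = 0.5,
                          sd_participant = 0.3,
                          sd_residual_by_trial = c(moderate = 0.3, heavy = 0.3,
                                                   severe = 0.5),
                          baseline_log_mean = 10,
                          baseline_log_sd = 1,
                          missing_rate = 0.05,
                          n_qc = 10,
                          qc_rsd_target = 10,
                          seed = 1L) {
  cfg <- list(n_participants = n_participants, sex_ratio = sex_ratio,
              n_features_per_class = n_features_per_class,
              effect_matrix = effect_matrix,
              sex_modulation = sex_modulation,
              sd_participant = sd_participant,
              sd_residual_by_trial = sd_residual_by_trial,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              missing_rate = missing_rate,
              n_qc = n_qc, qc_rsd_target = qc_rsd_target,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "CohortConfig"
  cfg
}

#' Default planted effect matrix (classes x trials, log2 fold change)
#' @return numeric matrix with rows ffa/glycolytic/lipoprotein/inert and
#'   columns moderate/heavy/severe
#' @export
default_effect_matrix <- function() {
  m <- rbind(ffa        = c(1.0, 0.8, 0.0),
             glycolytic = c(0.3, 0.6, 1.8),
             lipoprotein = c(0.10, 0.10, 0.20),
             inert      = c(0, 0, 0))
  colnames(m) <- VALID_TRIALS
  m
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid CohortConfig field '", field, "': ", msg,
                  call. = FALSE)
  }
  chk(cfg$n_participants >= 1, "n_participants", "must be >= 1")
  chk(cfg$sex_ratio >= 0 && cfg$sex_ratio <= 1, "sex_ratio",
      "must lie in [0, 1]")
  chk(all(cfg$n_features_per_class >= 0) &&
        sum(cfg$n_features_per_class) >= 1,
      "n_features_per_class", "needs at least one feature")
  chk(all(c("ffa", "glycolytic", "lipoprotein", "inert") %in%
            names(cfg$n_features_per_class)),
      "n_features_per_class", "classes ffa/glycolytic/lipoprotein/inert")
  chk(is.matrix(cfg$effect_matrix) &&
        all(VALID_TRIALS %in% colnames(cfg$effect_matrix)),
      "effect_matrix", "needs columns moderate/heavy/severe")
  chk(cfg$sd_participant >= 0, "sd_participant", "must be >= 0")
  chk(all(cfg$sd_residual_by_trial >= 0) &&
        all(VALID_TRIALS %in% names(cfg$sd_residual_by_trial)),
      "sd_residual_by_trial", "per-trial SDs must be >= 0")
  chk(cfg$baseline_log_sd >= 0, "baseline_log_sd", "must be >= 0")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1, "missing_rate",
      "must lie in [0, 1)")
  chk(cfg$n_qc >= 0, "n_qc", "must be >= 0")
  chk(cfg$qc_rsd_target >= 0, "qc_rsd_target", "must be >= 0")
  invisible(cfg)
}

class_platform <- function(cls) {
  switch(cls,
         ffa = "lcms-lipid",
         inert = "lcms-lipid",
         glycolytic = "nmr-small-molecule",
         lipoprotein = "nmr-lipoprotein",
         "lcms-lipid")
}

#' Generate a synthetic cohort dataset
#'
#' Simulates the full study layout: for every participant, one pre and one
#' post sample in each of the three intensity-domain trials, plus `n_qc`
#' pooled-QC injections. Per-cell natural-log abundance is
#' `baseline + participant intercept + (planted log2 effect) * ln 2 * post +
#' trial-specific noise`; the matrix is the exponential of that, so every
#' abundance is strictly positive and the expected log2(post/pre) equals the
#' planted effect exactly.
#'
#' @param config a [cohort_config()].
#' @return a `SyntheticDataset`: list with `dataset` (an `AbundanceDataset`)
#'   and `truth` (data.frame of per-feature class labels and planted
#'   log2 fold-change effects per trial).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(derive_seed(config$seed, "generate_cohort"))
  n_p <- config$n_participants
  counts <- config$n_features_per_class[c("ffa", "glycolytic",
                                          "lipoprotein", "inert")]
  counts <- counts[counts > 0]
  classes <- rep(names(counts), counts)
  n_feat <- length(classes)
  feature_id <- sprintf("%s_%03d", classes,
                        unlist(lapply(counts, seq_len), use.names = FALSE))
  n_male <- round(config$sex_ratio * n_p)
  sex_by_p <- c(rep("male", n_male), rep("female", n_p - n_male))
  participant <- sprintf("P%02d", seq_len(n_p))

  grid <- expand.grid(timepoint = VALID_TIMEPOINTS, trial = VALID_TRIALS,
                      participant_id = participant,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$sex <- sex_by_p[match(grid$participant_id, participant)]
  n_s <- nrow(grid)

  baseline <- stats::rnorm(n_feat, config$baseline_log_mean,
                           config$baseline_log_sd)
  u <- stats::rnorm(n_p, 0, config$sd_participant)

  eff <- matrix(0, n_s, n_feat)
  post <- grid$timepoint == "post"
  for (tr in VALID_TRIALS) {
    planted <- config$effect_matrix[classes, tr]
    rows <- post & grid$trial == tr
    eff[rows, ] <- matrix(planted, sum(rows), n_feat, byrow = TRUE)
    if (tr == "severe" && config$sex_modulation != 0) {
      rows_m <- rows & grid$sex == "male"
      ffa_cols <- classes == "ffa"
      eff[rows_m, ffa_cols] <- eff[rows_m, ffa_cols] + config$sex_modulation
    }
  }
  noise_sd <- config$sd_residual_by_trial[grid$trial]
  loga <- matrix(baseline, n_s, n_feat, byrow = TRUE) +
    u[match(grid$participant_id, participant)] +
    eff * log(2) +
    matrix(stats::rnorm(n_s * n_feat, 0, rep(noise_sd, n_feat)), n_s, n_feat)

  sample_meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_s)),
    participant_id = grid$participant_id,
    sex = grid$sex, trial = grid$trial, timepoint = grid$timepoint,
    sample_type = "study",
    injection_order = seq_len(n_s),
    stringsAsFactors = FALSE)
  feature_meta <- data.frame(
    feature_id = feature_id,
    platform = vapply(classes, class_platform, character(1)),
    class = classes, stringsAsFactors = FALSE)

  ds <- abundance_dataset(exp(loga), sample_meta, feature_meta)
  if (config$n_qc >= 2) {
    ds <- make_qc_injections(ds, config$n_qc, config$qc_rsd_target,
                             seed = derive_seed(config$seed, "qc"))
  }
  if (config$missing_rate > 0) {
    ds <- inject_missingness(ds, config$missing_rate, mechanism = "mcar",
                             seed = derive_seed(config$seed, "missing"))
  }
  truth <- data.frame(feature_id = feature_id, class = classes,
                      config$effect_matrix[classes, VALID_TRIALS],
                      row.names = NULL, check.names = FALSE)
  structure(list(dataset = ds, truth = truth, config = config),
            class = "SyntheticDataset")
}

#' Blank a fraction of study cells
#'
#' Emulates feature-wise missingness. QC rows are never touched. The `mcar`
#' mechanism blanks exactly `round(rate * n_cells)` uniformly chosen study
#' cells; `low-intensity` preferentially blanks the lowest-abundance cells
#' (the censoring pattern typical of intensity-thresholded LC-MS data).
#'
#' @param dataset an `AbundanceDataset`.
#' @param rate fraction of study cells to blank, in `[0, 1)`.
#' @param mechanism `"mcar"` or `"low-intensity"`.
#' @param seed integer seed.
#' @return the dataset with `NA` cells injected.
#' @export
inject_missingness <- function(dataset, rate, mechanism = c("mcar",
                                                            "low-intensity"),
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must lie in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(dataset)
  set.seed(as.integer(seed))
  study <- which(is_study(dataset))
  block <- dataset$matrix[study, , drop = FALSE]
  n_cells <- length(block)
  n_blank <- round(rate * n_cells)
  if (n_blank > 0) {
    if (mechanism == "mcar") {
      idx <- sample.int(n_cells, n_blank)
    } else {
      # sampling weights decay with within-feature intensity rank, so low
      # cells are blanked preferentially but not deterministically
      rk <- apply(block, 2, rank, ties.method = "average")
      w <- as.vector((nrow(block) + 1 - rk)^3)
      idx <- sample.int(n_cells, n_blank, prob = w)
    }
    block[idx] <- NA_real_
  }
  dataset$matrix[study, ] <- block
  dataset
}

#' Append pooled-QC injections
#'
#' Simulates repeated injections of a pooled plasma QC sample: per-feature
#' values are independent draws centered on the pooled study mean with a
#' coefficient of variation of `rsd_target` percent. These rows carry
#' `sample_type = "qc"` and drive the RSD precision filter.
#'
#' @param dataset an `AbundanceDataset` of study samples.
#' @param n_qc number of QC injections (>= 2, otherwise RSD is undefined).
#' @param rsd_target target percent RSD.
#' @param seed integer seed.
#' @return the dataset with `n_qc` QC rows appended.
#' @export
make_qc_injections <- function(dataset, n_qc, rsd_target, seed = 1L) {
  if (n_qc < 2) stop("n_qc must be >= 2 (RSD undefined otherwise)",
                     call. = FALSE)
  set.seed(as.integer(seed))
  study <- dataset$matrix[is_study(dataset), , drop = FALSE]
  pooled <- colMeans(study, na.rm = TRUE)
  n_feat <- length(pooled)
  qc <- matrix(pooled, n_qc, n_feat, byrow = TRUE)
  if (rsd_target > 0) {
    noise <- matrix(stats::rnorm(n_qc * n_feat), n_qc, n_feat)
    qc <- qc * (1 + (rsd_target / 100) * noise)
    qc[qc <= 0] <- .Machine$double.eps  # CV targets << 100%; clipping is rare
  }
  start <- max(dataset$sample_meta$injection_order) + 1L
  qc_meta <- data.frame(
    sample_id = sprintf("QC%03d", seq_len(n_qc)),
    participant_id = NA_character_, sex = NA_character_,
    trial = NA_character_, timepoint = NA_character_,
    sample_type = "qc",
    injection_order = seq(start, length.out = n_qc),
    stringsAsFactors = FALSE)
  abundance_dataset(rbind(dataset$matrix, qc),
                    rbind(dataset$sample_meta, qc_meta),
                    dataset$feature_meta)
}
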