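#' Construct an abundance dataset
#'
#' The container every pipeline stage consumes and produces: a sample x
#' feature abundance matrix plus per-sample metadata and per-feature
#' annotation. Abundances are non-negative where present; `NA` marks a
#' missing cell. Rows of `matrix` and `sample_meta` correspond one-to-one.
#'
#' @param matrix numeric matrix, samples in rows, features in columns.
#'   Column names are feature ids, row names are sample ids.
#' @param sample_meta data.frame with columns `sample_id`, `participant_id`,
#'   `sex` ("male"/"female"), `trial` ("moderate"/"heavy"/"severe"),
#'   `timepoint` ("pre"/"post"), `sample_type` ("study"/"qc") and
#'   `injection_order`.
#' @param feature_meta data.frame with columns `feature_id`, `platform`
#'   (one of "nmr-lipoprotein", "nmr-small-molecule", "lcms-lipid") and
#'   optionally `class`.
#' @return An object of class `AbundanceDataset`.
#' @export
abundance_dataset <- function(matrix, sample_meta, feature_meta) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) != nrow(sample_meta)) {
    stop("matrix has ", nrow(matrix), " rows but sample_meta has ",
         nrow(sample_meta), call. = FALSE)
  }
  if (ncol(matrix) != nrow(feature_meta)) {
    stop("matrix has ", ncol(matrix), " columns but feature_meta has ",
         nrow(feature_meta), " features", call. = FALSE)
  }
  if (anyDuplicated(feature_meta$feature_id)) {
    stop("feature ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(sample_meta$sample_id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (any(matrix < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative where present", call. = FALSE)
  }
  rownames(matrix) <- sample_meta$sample_id
  colnames(matrix) <- feature_meta$feature_id
  structure(
    list(matrix = matrix,
         sample_meta = as.data.frame(sample_meta),
         feature_meta = as.data.frame(feature_meta)),
    class = "AbundanceDataset"
  )
}

#' @export
print.AbundanceDataset <- function(x, ...) {
  n_qc <- sum(x$sample_meta$sample_type == "qc")
  cat("AbundanceDataset:", nrow(x$matrix), "samples (", n_qc, "QC ) x",
      ncol(x$matrix), "features;",
      sum(is.na(x$matrix)), "missing cells\n")
  invisible(x)
}

#' Number of samples and features
#' @param x an `AbundanceDataset`
#' @return integer vector `c(samples, features)`
#' @export
dim.AbundanceDataset <- function(x) dim(x$matrix)

is_study <- function(dataset) dataset$sample_meta$sample_type == "study"
is_qc <- function(dataset) dataset$sample_meta$sample_type == "qc"

#' Subset an abundance dataset by samples and/or features
#' @param dataset an `AbundanceDataset`
#' @param samples logical/integer/character index over samples
#' @param features logical/integer/character index over features
#' @return an `AbundanceDataset`
#' @export
subset_dataset <- function(dataset, samples = NULL, features = NULL) {
  m <- dataset$matrix
  sm <- dataset$sample_meta
  fm <- dataset$feature_meta
  if (!is.null(samples)) {
    m <- m[samples, , drop = FALSE]
    sm <- sm[samples, , drop = FALSE]
    rownames(sm) <- NULL
  }
  if (!is.null(features)) {
    if (is.character(features)) features <- match(features, fm$feature_id)
    m <- m[, features, drop = FALSE]
    fm <- fm[features, , drop = FALSE]
    rownames(fm) <- NULL
  }
  abundance_dataset(m, sm, fm)
}

#' Write an abundance dataset to a matrix CSV and a metadata CSV
#'
#' Matrix CSV: rows are samples, first column `sample_id`, remaining columns
#' features; missing cells are empty fields. Metadata CSV: one row per
#' sample. A feature-annotation CSV is written alongside the metadata when
#' `feature_path` is given.
#'
#' @param dataset an `AbundanceDataset`
#' @param matrix_path,metadata_path output file paths
#' @param feature_path optional path for feature annotation
#' @return invisibly, the dataset
#' @export
write_abundance_csv <- function(dataset, matrix_path, metadata_path,
                                feature_path = NULL) {
  df <- data.frame(sample_id = dataset$sample_meta$sample_id,
                   dataset$matrix, check.names = FALSE)
  utils::write.csv(df, matrix_path, row.names = FALSE, na = "")
  utils::write.csv(dataset$sample_meta, metadata_path, row.names = FALSE)
  if (!is.null(feature_path)) {
    utils::write.csv(dataset$feature_meta, feature_path, row.names = FALSE)
  }
  invisible(dataset)
}

VALID_TRIALS <- c("moderate", "heavy", "severe")
VALID_TIMEPOINTS <- c("pre", "post")
VALID_SEXES <- c("male", "female")
VALID_SAMPLE_TYPES <- c("study", "qc")
VALID_PLATFORMS <- c("nmr-lipoprotein", "nmr-small-molecule", "lcms-lipid")

normalize_label <- function(x) tolower(trimws(as.character(x)))

#' Load an abundance dataset from CSV files
#'
#' Reads the matrix/metadata pair written by [write_abundance_csv()],
#' validating sample-id agreement and factor levels. Trial, timepoint, sex
#' and sample-type labels are normalized (trimmed, lower-cased) with a
#' warning when normalization changed anything; unknown labels are rejected
#' with their row numbers. Empty matrix cells become `NA`.
#'
#' @param matrix_path CSV with `sample_id` first column, features after.
#' @param metadata_path CSV with per-sample metadata.
#' @param feature_path optional feature-annotation CSV (`feature_id`,
#'   `platform`, optional `class`). When absent, all features default to
#'   platform "lcms-lipid".
#' @return an `AbundanceDataset`
#' @export
load_abundance_csv <- function(matrix_path, metadata_path,
                               feature_path = NULL) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(metadata_path)) {
    stop("metadata file not found: ", metadata_path)
  }
  raw <- utils::read.csv(matrix_path, check.names = FALSE,
                         colClasses = NA, na.strings = c("", "NA"))
  if (names(raw)[1] != "sample_id") {
    stop("matrix CSV must have 'sample_id' as its first column")
  }
  meta <- utils::read.csv(metadata_path, check.names = FALSE,
                          na.strings = c("", "NA"))
  required <- c("sample_id", "participant_id", "sex", "trial", "timepoint",
                "sample_type")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"injection_order" %in% names(meta)) {
    meta$injection_order <- seq_len(nrow(meta))
  }

  for (col in c("sex", "trial", "timepoint", "sample_type")) {
    norm <- normalize_label(meta[[col]])
    changed <- which(!is.na(meta[[col]]) & norm != as.character(meta[[col]]))
    if (length(changed)) {
      warning("normalized ", col, " labels in metadata rows: ",
              paste(changed, collapse = ", "), call. = FALSE)
    }
    meta[[col]] <- norm
  }
  check_levels <- function(col, valid) {
    ok <- meta$sample_type == "qc" | meta[[col]] %in% valid
    # qc rows may leave biological factors blank
    ok <- ok | (meta$sample_type == "qc")
    bad <- which(!(meta[[col]] %in% valid) & meta$sample_type != "qc")
    if (length(bad)) {
      stop("invalid ", col, " labels in metadata rows ",
           paste(bad, collapse = ", "), ": ",
           paste(unique(meta[[col]][bad]), collapse = ", "), call. = FALSE)
    }
  }
  check_levels("trial", VALID_TRIALS)
  check_levels("timepoint", VALID_TIMEPOINTS)
  check_levels("sex", VALID_SEXES)
  bad_type <- which(!meta$sample_type %in% VALID_SAMPLE_TYPES)
  if (length(bad_type)) {
    stop("invalid sample_type in metadata rows ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }

  ids_m <- as.character(raw$sample_id)
  ids_meta <- as.character(meta$sample_id)
  orphan <- setdiff(ids_m, ids_meta)
  if (length(orphan)) {
    stop("matrix sample ids absent from metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  orphan2 <- setdiff(ids_meta, ids_m)
  if (length(orphan2)) {
    stop("metadata sample ids absent from matrix: ",
         paste(orphan2, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))
    stop("non-numeric matrix columns: ",
         paste(names(raw)[-1][bad], collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(ids_m, ids_meta), , drop = FALSE]
  rownames(meta) <- NULL

  if (!is.null(feature_path) && file.exists(feature_path)) {
    fmeta <- utils::read.csv(feature_path, check.names = FALSE)
    fmeta <- fmeta[match(colnames(m), fmeta$feature_id), , drop = FALSE]
    if (anyNA(fmeta$feature_id)) {
      stop("feature annotation missing ids present in the matrix")
    }
  } else {
    fmeta <- data.frame(feature_id = colnames(m), platform = "lcms-lipid",
                        stringsAsFactors = FALSE)
  }
  abundance_dataset(m, meta, fmeta)
}

# Stage seeds are derived from the single run seed so that inserting a stage
# never perturbs another stage's random stream. Kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483647)
}
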