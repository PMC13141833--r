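# Reading, validating and writing the package's tabular inputs and outputs:
# sample x feature count matrices, per-sample metadata, run configuration and
# tidy result tables. All files are plain delimited text (tab or comma,
# auto-detected); the decimal separator is always ".".

RACE_LEVELS <- c("European", "African", "Asian")
SEX_LEVELS <- c("male", "female")

METADATA_COLUMNS <- c("sample_id", "cancer_type", "batch", "sex", "age_years",
                      "race", "bmi", "stage", "histology")

#' Construct and validate a count matrix
#'
#' The universal input of the package: a samples x features matrix of
#' nonnegative integer raw read counts, with unique sample ids as row names
#' and unique feature (species) ids as column names.
#'
#' @param counts Numeric matrix, samples in rows, features in columns. All
#'   values must be nonnegative integers.
#' @param sample_ids,feature_ids Optional character vectors overriding the
#'   dimnames of `counts`.
#' @return The validated base matrix (integer storage) with dimnames set.
#' @export
count_matrix <- function(counts, sample_ids = rownames(counts),
                         feature_ids = colnames(counts)) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix", call. = FALSE)
  if (is.null(sample_ids) || is.null(feature_ids))
    stop("count matrix needs sample and feature ids (dimnames)", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids", call. = FALSE)
  if (length(sample_ids) != nrow(counts) || length(feature_ids) != ncol(counts))
    stop("id lists inconsistent with matrix dimensions", call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 |
                 abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "count matrix cell (sample '%s', feature '%s') is not a nonnegative integer: %s",
      sample_ids[bad[1L, 1L]], feature_ids[bad[1L, 2L]],
      format(counts[bad[1L, , drop = FALSE]])), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, feature_ids)
  counts
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a count matrix from delimited text
#'
#' The delimiter (tab or comma) is auto-detected from the header line; the
#' first column holds the ids. Matrices stored features-in-rows are
#' transposed so that the returned matrix always has samples in rows.
#'
#' @param path Path to a TSV/CSV file with a header row and an id column.
#' @param orientation `"samples_rows"` (default) or `"features_rows"`.
#' @return A validated count matrix (see [count_matrix()]).
#' @export
read_count_matrix <- function(path,
                              orientation = c("samples_rows", "features_rows")) {
  orientation <- match.arg(orientation)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA,
                          row.names = NULL)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("count matrix contains non-numeric cells", call. = FALSE)
  rownames(m) <- ids
  if (orientation == "features_rows") m <- t(m)
  count_matrix(m)
}

#' Write a count matrix to tab-delimited text
#'
#' @param m Count matrix (samples x features).
#' @param path Output path.
#' @param id_column Name used for the id column header.
#' @export
write_count_matrix <- function(m, path, id_column = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse sub-staged tumor stage labels to integer levels
#'
#' Sub-stage suffixes are dropped so that, e.g., "3A", "3B" and "3C" all map
#' to stage 3. Empty strings and NA map to missing.
#'
#' @param stage Character or numeric vector of stage labels.
#' @return Integer vector with values in 1..4 or NA.
#' @export
collapse_stage <- function(stage) {
  s <- trimws(toupper(as.character(stage)))
  out <- rep(NA_integer_, length(s))
  nonmissing <- !is.na(s) & s != "" & s != "NA"
  ok <- grepl("^(STAGE\\s*)?([1-4])[A-C]?$", s[nonmissing])
  if (any(!ok))
    stop("unparseable stage label(s): ",
         paste(unique(s[nonmissing][!ok]), collapse = ", "), call. = FALSE)
  out[nonmissing] <- as.integer(sub("^(STAGE\\s*)?([1-4])[A-C]?$", "\\2",
                                    s[nonmissing]))
  out
}

#' Read per-sample metadata
#'
#' Expects the columns sample_id, cancer_type, batch, sex, age_years, race,
#' bmi, stage and histology. Stage
#' labels are collapsed to integer levels 1-4 ("3A" -> 3); race must be one
#' of European, African, Asian; sex one of male, female (case-insensitive).
#' Empty cells in `bmi`, `stage` and `histology` become missing values and
#' are never imputed.
#'
#' @param path Path to a TSV/CSV file.
#' @return A data.frame with one validated row per sample.
#' @export
read_metadata <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character", row.names = NULL)
  missing_cols <- setdiff(METADATA_COLUMNS, colnames(df))
  if (length(missing_cols) > 0L)
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, METADATA_COLUMNS]
  blank_to_na <- function(x) ifelse(trimws(x) == "" | is.na(x), NA, trimws(x))
  df[] <- lapply(df, blank_to_na)
  validate_metadata(data.frame(
    sample_id = df$sample_id,
    cancer_type = df$cancer_type,
    batch = df$batch,
    sex = tolower(df$sex),
    age_years = as.numeric(df$age_years),
    race = df$race,
    bmi = as.numeric(df$bmi),
    stage = collapse_stage(df$stage),
    histology = df$histology,
    stringsAsFactors = FALSE))
}

validate_metadata <- function(meta) {
  stopifnot(is.data.frame(meta))
  missing_cols <- setdiff(METADATA_COLUMNS, colnames(meta))
  if (length(missing_cols) > 0L)
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  bad_race <- setdiff(unique(stats::na.omit(meta$race)), RACE_LEVELS)
  if (length(bad_race) > 0L)
    stop("unknown race label(s): ", paste(bad_race, collapse = ", "),
         "; expected ", paste(RACE_LEVELS, collapse = "/"), call. = FALSE)
  bad_sex <- setdiff(unique(stats::na.omit(meta$sex)), SEX_LEVELS)
  if (length(bad_sex) > 0L)
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  if (any(meta$age_years < 0, na.rm = TRUE))
    stop("negative age", call. = FALSE)
  if (any(meta$bmi <= 0, na.rm = TRUE))
    stop("non-positive BMI", call. = FALSE)
  if (!all(stats::na.omit(meta$stage) %in% 1:4))
    stop("stage outside 1..4 after collapse", call. = FALSE)
  meta
}

#' Write per-sample metadata to tab-delimited text
#' @param meta Metadata data.frame.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  out <- meta[, METADATA_COLUMNS]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Check that every sample of a count matrix has a metadata row
#' @param m Count matrix.
#' @param meta Metadata data.frame.
#' @return Invisibly, the metadata reordered to match the matrix rows.
#' @export
align_metadata <- function(m, meta) {
  idx <- match(rownames(m), meta$sample_id)
  if (anyNA(idx))
    stop("samples without metadata: ",
         paste(utils::head(rownames(m)[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  meta[idx, , drop = FALSE]
}

CONFIG_DEFAULTS <- list(
  alpha = 0.05,
  zero_fraction_threshold = 0.95,
  min_group_size = 20,
  truncation_percentile = 99,
  propensity_clip = c(0.01, 0.99),
  age_cut = 70,
  bmi_cut = 30,
  plsda_components = NULL,
  sensitivity_floor = 25,
  n_resamples = 2000,
  bonferroni_scope = "stratum",
  ratio_mode = "pooled",
  seed = 1L,
  output_dir = "."
)

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration (by file extension) and fills in the
#' documented defaults: alpha 0.05, zero-fraction threshold 0.95, minimum
#' group size 20, weight-truncation percentile 99, propensity clipping at
#' \[0.01, 0.99\], age cut 70 years, BMI cut 30. Unknown keys are rejected.
#'
#' @param path Optional path to a config file; `NULL` gives pure defaults.
#' @param overrides Named list of values taking precedence over the file.
#' @return A named list with every configuration key populated.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  user <- list()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user[names(overrides)] <- overrides
  unknown <- setdiff(names(user), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- CONFIG_DEFAULTS
  cfg[names(user)] <- user
  assert_scalar_number(cfg$alpha, "alpha", 1e-12, 1 - 1e-12)
  assert_scalar_number(cfg$zero_fraction_threshold, "zero_fraction_threshold",
                       0, 1)
  assert_scalar_number(cfg$min_group_size, "min_group_size", 1, Inf)
  if (cfg$truncation_percentile <= 50 || cfg$truncation_percentile > 100)
    stop("`truncation_percentile` must be in (50, 100]", call. = FALSE)
  if (length(cfg$propensity_clip) != 2L || cfg$propensity_clip[1L] <= 0 ||
      cfg$propensity_clip[2L] >= 1 ||
      cfg$propensity_clip[1L] >= cfg$propensity_clip[2L])
    stop("`propensity_clip` must be (lo, hi) inside (0, 1)", call. = FALSE)
  if (!cfg$bonferroni_scope %in% c("stratum", "global"))
    stop("`bonferroni_scope` must be 'stratum' or 'global'", call. = FALSE)
  if (!cfg$ratio_mode %in% c("pooled", "per_sample"))
    stop("`ratio_mode` must be 'pooled' or 'per_sample'", call. = FALSE)
  cfg
}

RESULTS_COLUMNS <- c("species", "cancer", "factor", "combination",
                     "coefficient", "p", "p_bonferroni", "significant")

#' Write a tidy per-combination results table
#' @param records Data.frame of differential-abundance records.
#' @param path Output path.
#' @export
write_results <- function(records, path) {
  missing_cols <- setdiff(RESULTS_COLUMNS, colnames(records))
  if (length(missing_cols) > 0L)
    stop("results table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.table(records[, RESULTS_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tidy per-combination results table
#' @param path Path written by [write_results()].
#' @return Data.frame with typed columns.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  df$significant <- as.logical(df$significant)
  if (any(df$p < 0 | df$p > 1, na.rm = TRUE) ||
      any(df$p_bonferroni < 0 | df$p_bonferroni > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]", call. = FALSE)
  df[, RESULTS_COLUMNS]
}
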