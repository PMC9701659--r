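#' Build a feature matrix (the "community" object)
#'
#' A `feature_matrix` couples a samples-by-features abundance matrix with a
#' sample metadata table and a feature table.  Samples are rows and features
#' (m/z_rt ion species) are columns throughout the package, matching the
#' community-data convention the ecological methods assume.
#'
#' @param abundance Numeric matrix, samples in rows, features in columns.
#'   Row names are sample IDs, column names are feature labels.  All values
#'   must be non-negative; zero means "not detected".
#' @param samples Data frame of sample metadata with columns `sample_id`,
#'   `concentration`, `time`, `replicate` and optionally `mode`.  One row per
#'   abundance-matrix row.
#' @param features Optional data frame with columns `label`, `mz`, `rt`.
#'   When `NULL`, it is parsed from the abundance column names with
#'   [parse_feature_id()].
#' @param dialect Feature-label dialect passed to [parse_feature_id()].
#' @param validate_mz Check that parsed m/z values fall in the acquisition
#'   range (50, 1200)?  Default `FALSE` so synthetic labels are unrestricted.
#'
#' @return An object of class `feature_matrix`.
#' @export
#' @examples
#' ab <- matrix(c(0, 5, 2, 0), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("100.5_1.0", "200.25_2.5")))
#' meta <- tibble::tibble(sample_id = c("s1", "s2"),
#'   concentration = "C27", time = c("T0", "T7"), replicate = 1L)
#' fm <- feature_matrix(ab, meta)
#' fm
feature_matrix <- function(abundance, samples, features = NULL,
                           dialect = "mz_rt", validate_mz = FALSE) {
  abundance <- as.matrix(abundance)
  if (!is.numeric(abundance)) abort("`abundance` must be numeric.")
  if (anyNA(abundance)) abort("`abundance` must not contain NA; impute absences as 0 upstream.")
  if (any(abundance < 0)) abort("`abundance` must be non-negative (ion counts/areas).")
  if (is.null(colnames(abundance))) abort("`abundance` must have feature labels as column names.")
  if (anyDuplicated(colnames(abundance))) abort("Feature labels must be unique.")
  samples <- as_tibble(samples)
  if (!"sample_id" %in% names(samples)) abort("`samples` must have a `sample_id` column.")
  if (is.null(rownames(abundance))) rownames(abundance) <- samples$sample_id
  if (nrow(samples) != nrow(abundance)) {
    abort(sprintf("`samples` has %d rows but `abundance` has %d.", nrow(samples), nrow(abundance)))
  }
  if (!all(rownames(abundance) == samples$sample_id)) {
    idx <- match(rownames(abundance), samples$sample_id)
    if (anyNA(idx)) {
      missing <- setdiff(rownames(abundance), samples$sample_id)
      abort(paste0("Samples absent from metadata: ", paste(head(missing, 5), collapse = ", ")))
    }
    samples <- samples[idx, ]
  }
  if (is.null(features)) {
    features <- parse_feature_id(colnames(abundance), dialect = dialect,
                                 validate_mz = validate_mz)
  } else {
    features <- as_tibble(features)
    if (!all(c("label", "mz", "rt") %in% names(features))) {
      abort("`features` must have columns label, mz, rt.")
    }
    features <- features[match(colnames(abundance), features$label), ]
  }
  structure(
    list(abundance = abundance, samples = samples, features = features),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features\n",
              nrow(x$abundance), ncol(x$abundance)))
  cat(sprintf("  total ion abundance: %.4g; occupancy: %.1f%%\n",
              sum(x$abundance), 100 * mean(x$abundance > 0)))
  if (all(c("concentration", "time") %in% names(x$samples))) {
    cat(sprintf("  conditions: %d concentration x %d time levels\n",
                dplyr::n_distinct(x$samples$concentration),
                dplyr::n_distinct(x$samples$time)))
  }
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$abundance)

#' Tidy a feature matrix into long format
#'
#' @param x A [feature_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, feature) pair and columns
#'   `sample_id`, `label`, `mz`, `rt`, `abundance` plus the sample metadata.
#' @export
tidy.feature_matrix <- function(x, ...) {
  long <- as_tibble(x$abundance, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "label", values_to = "abundance")
  long |>
    left_join(x$samples, by = "sample_id") |>
    left_join(x$features, by = "label")
}

#' One-row summary of a feature matrix
#'
#' @param x A [feature_matrix()].
#' @param ... Unused.
#' @return A tibble with sample/feature counts, total abundance and occupancy.
#' @export
glance.feature_matrix <- function(x, ...) {
  tibble(
    n_samples = nrow(x$abundance),
    n_features = ncol(x$abundance),
    total_abundance = sum(x$abundance),
    occupancy = mean(x$abundance > 0)
  )
}

#' Condition label for each sample
#'
#' Pastes concentration and time (e.g. `"C27_T14"`), the grouping used for
#' pooled richness and for defining comparison groups.
#'
#' @param fm A [feature_matrix()].
#' @return Character vector, one label per sample.
#' @export
condition_labels <- function(fm) {
  paste(fm$samples$concentration, fm$samples$time, sep = "_")
}

#' Subset a feature matrix by sample or feature
#'
#' @param fm A [feature_matrix()].
#' @param samples Logical/integer/character selector on samples (optional).
#' @param features Logical/integer/character selector on features (optional).
#' @return A [feature_matrix()].
#' @export
filter_features <- function(fm, samples = NULL, features = NULL) {
  ab <- fm$abundance
  si <- if (is.null(samples)) seq_len(nrow(ab)) else samples
  fi <- if (is.null(features)) seq_len(ncol(ab)) else features
  ab <- ab[si, fi, drop = FALSE]
  feature_matrix(ab, fm$samples[si, , drop = FALSE],
                 fm$features[match(colnames(ab), fm$features$label), , drop = FALSE])
}
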