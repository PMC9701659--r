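#' Parse m/z_rt feature labels
#'
#' Each detected ion is identified by its mass-to-charge ratio and retention
#' time, written as a single token such as `"377.0844_2.9"`.  The dialect is
#' configurable because exports differ in their separator.
#'
#' @param labels Character vector of feature labels.
#' @param dialect One of `"mz_rt"` (underscore separator, the MarkerLynx-style
#'   default) or `"mz@rt"`.
#' @param validate_mz If `TRUE`, require 50 < m/z < 1200 (the acquisition
#'   mass range).
#' @return A tibble with columns `label`, `mz` (Th), `rt` (minutes).
#' @export
#' @examples
#' parse_feature_id("377.0844_2.9")
parse_feature_id <- function(labels, dialect = c("mz_rt", "mz@rt"),
                             validate_mz = FALSE) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect, "mz_rt" = "_", "mz@rt" = "@")
  num <- "[0-9]+(?:\\.[0-9]+)?"
  pattern <- paste0("^(", num, ")", ifelse(sep == "@", "@", "_"), "(", num, ")$")
  m <- regmatches(labels, regexec(pattern, labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(sprintf("Malformed feature label(s): %s",
                  paste(utils::head(labels[bad], 5), collapse = ", ")))
  }
  mz <- as.numeric(vapply(m, `[[`, "", 2L))
  rt <- as.numeric(vapply(m, `[[`, "", 3L))
  if (validate_mz && any(mz <= 50 | mz >= 1200)) {
    abort(sprintf("m/z outside acquisition range (50, 1200): %s",
                  paste(utils::head(labels[mz <= 50 | mz >= 1200], 5), collapse = ", ")))
  }
  if (any(rt < 0)) abort("Retention time must be non-negative.")
  tibble(label = labels, mz = mz, rt = rt)
}

#' Format m/z and retention time back into a feature label
#'
#' Inverse of [parse_feature_id()] for labels the parser produced itself;
#' original labels round-trip unchanged because the parser preserves them.
#'
#' @param mz,rt Numeric vectors.
#' @param dialect As in [parse_feature_id()].
#' @return Character vector of labels.
#' @export
format_feature_id <- function(mz, rt, dialect = c("mz_rt", "mz@rt")) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect, "mz_rt" = "_", "mz@rt" = "@")
  fmt <- function(v) {
    if (is.character(v)) v
    else vapply(v, format, "", trim = TRUE, scientific = FALSE)
  }
  paste0(fmt(mz), sep, fmt(rt))
}

#' Read a feature abundance table plus metadata
#'
#' Expects a CSV/TSV with one header row of feature labels, a first column of
#' sample IDs and one row per sample, as produced by MarkerLynx-style exports,
#' plus a metadata CSV mapping sample IDs to concentration, time, replicate
#' and ionization mode.  Missing cells are imputed as 0 (absence) with a
#' warning.
#'
#' @param path Path to the feature table (CSV; TSV when the file ends in
#'   `.tsv`/`.txt`; XLSX via the readxl package for supplementary-style
#'   workbooks).
#' @param meta Path to the metadata CSV (columns `sample_id`,
#'   `concentration`, `time`, `replicate`, optionally `mode`), or a data
#'   frame.
#' @param mode Optional ionization-mode filter (`"ESI+"` or `"ESI-"`); rows of
#'   the metadata with a different `mode` are dropped before matching.
#' @param dialect Feature-label dialect for [parse_feature_id()].
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path, meta, mode = NULL, dialect = "mz_rt") {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("XLSX import needs the readxl package.")
    }
    tab <- readxl::read_excel(path)
  } else {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  }
  if (nrow(tab) == 0 || ncol(tab) < 2) abort("Feature table is empty.")
  sample_id <- as.character(tab[[1]])
  ab <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(ab) <- "double"
  if (anyNA(ab)) {
    warn(sprintf("%d missing cell(s) imputed as 0 (not detected).", sum(is.na(ab))))
    ab[is.na(ab)] <- 0
  }
  if (anyDuplicated(colnames(ab))) abort("Duplicate feature labels in table.")
  rownames(ab) <- sample_id
  if (is.character(meta)) meta <- readr::read_csv(meta, show_col_types = FALSE, progress = FALSE)
  meta <- as_tibble(meta)
  if (!is.null(mode) && "mode" %in% names(meta)) {
    meta <- dplyr::filter(meta, .data$mode == !!mode)
  }
  absent <- setdiff(sample_id, meta$sample_id)
  if (length(absent) > 0) {
    abort(paste0("Sample(s) in table absent from metadata: ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  feature_matrix(ab, meta[match(sample_id, meta$sample_id), ], dialect = dialect)
}

#' Write a feature matrix to CSV files
#'
#' @param fm A [feature_matrix()].
#' @param path Output path for the abundance table.
#' @param meta_path Optional output path for the sample metadata.
#' @return `fm`, invisibly.
#' @export
write_feature_table <- function(fm, path, meta_path = NULL) {
  tab <- bind_cols(tibble(sample_id = rownames(fm$abundance)),
                   as_tibble(fm$abundance))
  readr::write_csv(tab, path, progress = FALSE)
  if (!is.null(meta_path)) readr::write_csv(fm$samples, meta_path, progress = FALSE)
  invisible(fm)
}

#' Convert abundances to presence/absence
#'
#' Presence is strict: a feature is present in a sampling unit iff its
#' abundance exceeds `threshold`.  Zero is the instrument's absence code, so
#' the default threshold 0 marks any positive abundance as present.
#'
#' @param fm A [feature_matrix()], or a numeric matrix.
#' @param threshold Non-negative abundance threshold (default 0).
#' @return An `incidence_matrix`: units x features binary matrix with the
#'   unit metadata attached.
#' @export
to_incidence <- function(fm, threshold = 0) {
  if (threshold < 0) abort("`threshold` must be >= 0.")
  ab <- if (inherits(fm, "feature_matrix")) fm$abundance else as.matrix(fm)
  pres <- (ab > threshold) * 1L
  units <- if (inherits(fm, "feature_matrix")) fm$samples else
    tibble(sample_id = rownames(ab) %||% paste0("u", seq_len(nrow(ab))))
  structure(list(presence = pres, units = units), class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> %d units x %d features; %d presences\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence)))
  invisible(x)
}

#' @export
dim.incidence_matrix <- function(x) dim(x$presence)

#' Pool sampling units by metadata keys
#'
#' Replicates (or any group of units) are pooled with logical OR: a feature is
#' present in the pooled unit if it was detected in any member.  Used for
#' per-condition richness (e.g. the pooled `C27_T14` unit).
#'
#' @param im An `incidence_matrix` from [to_incidence()].
#' @param by Character vector of metadata column names to group by
#'   (default `c("concentration", "time")`).
#' @return An `incidence_matrix` with one unit per group, labelled by the
#'   pasted key values.
#' @export
pool_units <- function(im, by = c("concentration", "time")) {
  if (length(by) == 0) abort("`by` must name at least one metadata column.")
  missing_keys <- setdiff(by, names(im$units))
  if (length(missing_keys) > 0) {
    abort(paste0("Grouping key(s) not in unit metadata: ",
                 paste(missing_keys, collapse = ", ")))
  }
  key <- do.call(paste, c(im$units[by], sep = "_"))
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  pooled <- t(vapply(groups, function(i) {
    as.integer(colSums(im$presence[i, , drop = FALSE]) > 0)
  }, integer(ncol(im$presence))))
  colnames(pooled) <- colnames(im$presence)
  rownames(pooled) <- names(groups)
  units <- distinct(bind_cols(tibble(sample_id = key), im$units[by]))
  names(units)[1] <- "sample_id"
  structure(list(presence = pooled, units = units[match(names(groups), units$sample_id), ]),
            class = "incidence_matrix")
}
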