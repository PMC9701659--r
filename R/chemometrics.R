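#' Normalize a feature matrix (transform + per-feature scaling)
#'
#' Applies an elementwise transform followed by a column (feature) scaling:
#'
#' * `autoscale`: `(x - mean) / sd`
#' * `range`: `(x - mean) / (max - min)`
#' * `pareto`: `(x - mean) / sqrt(sd)`
#' * `none`: leave as is
#'
#' The positive-mode convention in the source workflow is no transform with
#' autoscaling; the negative-mode convention is cube root with range
#' scaling.  Features with zero variance (or zero range) cannot be scaled
#' and are dropped with a warning.
#'
#' @param fm A [feature_matrix()].
#' @param transform `"none"` or `"cube_root"`.
#' @param scaling `"autoscale"`, `"range"`, `"pareto"` or `"none"`.
#' @return A [feature_matrix()] whose abundance slot holds the normalized
#'   values (possibly negative); the spec applied is recorded in the
#'   `normalization` attribute.
#' @export
normalize_features <- function(fm,
                               transform = c("none", "cube_root"),
                               scaling = c("autoscale", "range", "pareto", "none")) {
  transform <- match.arg(transform)
  scaling <- match.arg(scaling)
  ab <- fm$abundance
  if (transform == "cube_root") ab <- ab^(1 / 3)
  if (scaling != "none") {
    ctr <- sweep(ab, 2, colMeans(ab))
    denom <- switch(scaling,
      autoscale = apply(ab, 2, sd),
      range = apply(ab, 2, function(x) max(x) - min(x)),
      pareto = sqrt(apply(ab, 2, sd)))
    bad <- denom == 0 | !is.finite(denom)
    if (any(bad)) {
      warn(sprintf("%d zero-variance feature(s) dropped under %s scaling.",
                   sum(bad), scaling))
      ctr <- ctr[, !bad, drop = FALSE]
      denom <- denom[!bad]
    }
    ab <- sweep(ctr, 2, denom, "/")
  }
  out <- list(abundance = ab, samples = fm$samples,
              features = fm$features[match(colnames(ab), fm$features$label), ])
  out <- structure(out, class = "feature_matrix")
  attr(out, "normalization") <- list(transform = transform, scaling = scaling)
  out
}

#' Principal component analysis of a (normalized) feature matrix
#'
#' Centered singular-value decomposition of the samples-by-features matrix.
#' No rescaling happens here beyond the explicit [normalize_features()] step
#' the caller chose.  The number of retained components is either fixed or
#' chosen by an elbow rule: the largest component index c such that the
#' eigenvalue drop from c to c+1 exceeds the mean drop.  Loading signs are
#' fixed so each loading vector's largest-magnitude entry is positive.
#'
#' @param fm A [feature_matrix()] (typically normalized).
#' @param n_components Integer, or `"elbow"` (default).
#' @return A `pca_result`: list with `scores` (samples x kept components),
#'   `loadings` (features x kept components), `var_explained` (percent per
#'   component, all components), `n_components`.
#' @export
run_pca <- function(fm, n_components = "elbow") {
  ab <- if (inherits(fm, "feature_matrix")) fm$abundance else as.matrix(fm)
  if (nrow(ab) < 2) abort("PCA needs more than one sample.")
  if (any(!is.finite(ab))) abort("PCA input must be finite.")
  pc <- prcomp(ab, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  var_explained <- 100 * ev / sum(ev)
  k_max <- length(ev)
  k <- if (identical(n_components, "elbow")) {
    drops <- -diff(ev)
    if (length(drops) == 0) 1L else {
      cand <- which(drops > mean(drops))
      if (length(cand) == 0) 1L else max(cand)
    }
  } else {
    min(as.integer(n_components), k_max)
  }
  # deterministic sign: largest |loading| entry positive
  for (c in seq_len(k_max)) {
    j <- which.max(abs(pc$rotation[, c]))
    if (pc$rotation[j, c] < 0) {
      pc$rotation[, c] <- -pc$rotation[, c]
      pc$x[, c] <- -pc$x[, c]
    }
  }
  samples <- if (inherits(fm, "feature_matrix")) fm$samples else
    tibble(sample_id = rownames(ab) %||% paste0("s", seq_len(nrow(ab))))
  structure(list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    var_explained = var_explained,
    eigenvalues = ev,
    n_components = k,
    samples = samples
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d component(s) kept; PC1 %.1f%%, PC2 %.1f%%\n",
              x$n_components, x$var_explained[1],
              if (length(x$var_explained) > 1) x$var_explained[2] else NA))
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) {
  as_tibble(x$scores, rownames = "sample_id") |>
    left_join(x$samples, by = "sample_id")
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_components = x$n_components,
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_,
         total_var_kept = sum(x$var_explained[seq_len(x$n_components)]))
}

#' PCA score plot
#'
#' @param object A `pca_result`.
#' @param pcs Which two components to plot (default 1:2).
#' @param ... Unused.
#' @return A ggplot of the pairwise score plot colored by concentration
#'   when available.
#' @export
autoplot.pca_result <- function(object, pcs = c(1, 2), ...) {
  df <- tidy(object)
  xn <- paste0("PC", pcs[1]); yn <- paste0("PC", pcs[2])
  aes <- if ("concentration" %in% names(df)) {
    ggplot2::aes(x = .data[[xn]], y = .data[[yn]], color = .data$concentration)
  } else {
    ggplot2::aes(x = .data[[xn]], y = .data[[yn]])
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xn, object$var_explained[pcs[1]]),
      y = sprintf("%s (%.1f%%)", yn, object$var_explained[pcs[2]]))
}

#' Pairwise Pearson correlation matrix
#'
#' Feature-vs-feature or sample-vs-sample Pearson correlations; constant
#' vectors yield `NA` entries with a warning rather than an error.
#'
#' @param fm A [feature_matrix()] or numeric matrix (samples x features).
#' @param axis `"features"` (correlate feature profiles across samples) or
#'   `"samples"`.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(fm, axis = c("features", "samples")) {
  axis <- match.arg(axis)
  ab <- if (inherits(fm, "feature_matrix")) fm$abundance else as.matrix(fm)
  m <- if (axis == "features") ab else t(ab)
  if (nrow(m) < 3) abort("Need at least 3 observations per vector.")
  const <- apply(m, 2, sd) == 0
  if (any(const)) {
    warn(sprintf("%d constant vector(s): correlations set to NA.", sum(const)))
  }
  suppressWarnings(r <- cor(m))
  diag(r) <- 1
  r
}

#' Hierarchical clustering for heatmap rendering
#'
#' Deterministic agglomerative clustering of the rows of a matrix, exporting
#' the leaf order and merge heights a heatmap renderer needs.
#'
#' @param m Numeric matrix (items in rows), all finite.
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r between
#'   rows).
#' @param linkage `"average"` (default), `"complete"` or `"ward"`
#'   (ward.D2).
#' @return A list with the `hclust` object, `order` (leaf order), `labels`,
#'   and `merge_heights`.
#' @export
hierarchical_cluster <- function(m, distance = c("correlation", "euclidean"),
                                 linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- as.matrix(m)
  if (nrow(m) < 2) abort("Need at least 2 items to cluster.")
  if (any(!is.finite(m))) abort("Clustering input must be finite.")
  d <- if (distance == "euclidean") {
    dist(m)
  } else {
    stats::as.dist(1 - suppressWarnings(cor(t(m))))
  }
  if (any(!is.finite(d))) abort("Non-finite distances (constant rows under correlation distance).")
  hc <- hclust(d, method = switch(linkage, average = "average",
                                  complete = "complete", ward = "ward.D2"))
  list(hclust = hc, order = hc$order,
       labels = hc$labels %||% as.character(seq_len(nrow(m))),
       merge_heights = hc$height)
}

#' Keep features whose normalized abundance reaches a threshold
#'
#' The heatmap views only show features whose (normalized) relative
#' abundance reaches `min_value` in at least one sample.
#'
#' @param fm A [feature_matrix()] (normalized or raw).
#' @param min_value Threshold (default 2).
#' @return A [feature_matrix()] restricted to passing features.
#' @export
abundance_filter <- function(fm, min_value = 2) {
  keep <- apply(fm$abundance, 2, function(x) any(x >= min_value))
  if (!any(keep)) warn("No feature reaches the threshold.")
  out <- list(abundance = fm$abundance[, keep, drop = FALSE],
              samples = fm$samples,
              features = fm$features[match(colnames(fm$abundance)[keep],
                                           fm$features$label), ])
  structure(out, class = "feature_matrix")
}
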