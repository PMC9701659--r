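#' Per-feature fold change between two groups
#'
#' Fold change is the ratio of raw group mean abundances with the control in
#' the denominator (`fc = mean(treatment) / mean(control)`).  Scaled data
#' destroy ratio meaning, so fold changes are always computed on raw
#' abundances.  A zero mean in one group is replaced by a pseudo-count
#' (default: half the smallest positive abundance in the table, logged on
#' first use); features with both means zero are excluded.
#'
#' @param fm A [feature_matrix()].
#' @param control,treatment Condition labels (`"<concentration>_<time>"`,
#'   see [condition_labels()]) or logical/integer sample selectors.
#' @param pseudo Pseudo-count for zero means; `NULL` for the default policy.
#' @return A tibble with one row per retained feature: `label`,
#'   `mean_control`, `mean_treatment`, `fc`, `log2fc`.
#' @export
fold_change <- function(fm, control, treatment, pseudo = NULL) {
  sel <- function(which) {
    if (is.character(which) && length(which) <= length(condition_labels(fm))) {
      hit <- condition_labels(fm) %in% which
      if (!any(hit)) abort(sprintf("No samples match group '%s'.",
                                   paste(which, collapse = ",")))
      hit
    } else which
  }
  a <- fm$abundance[sel(control), , drop = FALSE]
  b <- fm$abundance[sel(treatment), , drop = FALSE]
  ma <- unname(colMeans(a))
  mb <- unname(colMeans(b))
  both_zero <- ma == 0 & mb == 0
  if (any(both_zero)) {
    inform(sprintf("%d feature(s) absent from both groups excluded.", sum(both_zero)))
  }
  if (is.null(pseudo)) {
    pos <- fm$abundance[fm$abundance > 0]
    pseudo <- if (length(pos) > 0) min(pos) / 2 else 0.5
  }
  ma2 <- ifelse(ma == 0, pseudo, ma)
  mb2 <- ifelse(mb == 0, pseudo, mb)
  tibble(label = colnames(fm$abundance),
         mean_control = ma, mean_treatment = mb,
         fc = mb2 / ma2, log2fc = log2(mb2 / ma2))[!both_zero, ]
}

#' Volcano screening of one comparison
#'
#' Couples the fold change with a Welch t-test on log-transformed abundances
#' (when each group has >= 2 replicates; otherwise p-values are disabled and
#' the screen is fold-change-only).  A feature passes when
#' `fc >= fc_threshold` or `fc <= 1/fc_threshold`, and `p <= p_threshold`
#' when p-filtering is active.
#'
#' @inheritParams fold_change
#' @param fc_threshold Fold-change cutoff (default 2).
#' @param p_threshold p-value cutoff (default 0.05); set `NA` to disable.
#' @param adjust_p Apply Benjamini-Hochberg correction across features?
#'   Default `FALSE` (the workflow applies none).
#' @return A `differential_set` tibble sorted by decreasing `|log2fc|`, with
#'   columns `label`, `fc`, `log2fc`, `p`, `passes` and the comparison
#'   recorded in attributes `control`/`treatment`.
#' @export
volcano_screen <- function(fm, control, treatment, fc_threshold = 2,
                           p_threshold = 0.05, pseudo = NULL,
                           adjust_p = FALSE) {
  fcs <- fold_change(fm, control, treatment, pseudo = pseudo)
  labs <- condition_labels(fm)
  sel <- function(which) {
    if (is.character(which) && length(which) <= length(labs)) labs %in% which else which
  }
  a <- fm$abundance[sel(control), fcs$label, drop = FALSE]
  b <- fm$abundance[sel(treatment), fcs$label, drop = FALSE]
  use_p <- nrow(a) >= 2 && nrow(b) >= 2 && !is.na(p_threshold)
  if (!use_p && !is.na(p_threshold)) {
    inform("Fewer than 2 replicates per group: p-values disabled, fold-change-only mode.")
  }
  p <- rep(NA_real_, nrow(fcs))
  if (use_p) {
    p <- vapply(seq_len(ncol(a)), function(j) {
      x <- log1p(a[, j]); y <- log1p(b[, j])
      if (sd(x) == 0 && sd(y) == 0) return(if (mean(x) == mean(y)) 1 else 0)
      tryCatch(t.test(y, x)$p.value, error = function(e) NA_real_)
    }, numeric(1))
    if (adjust_p) p <- p.adjust(p, "BH")
  }
  out <- fcs |>
    mutate(p = p,
           passes = (.data$fc >= fc_threshold | .data$fc <= 1 / fc_threshold) &
             (if (use_p) !is.na(p) & p <= p_threshold else TRUE)) |>
    arrange(dplyr::desc(abs(.data$log2fc)))
  structure(out, class = c("differential_set", class(out)),
            control = if (is.character(control)) paste(control, collapse = "+") else "control",
            treatment = if (is.character(treatment)) paste(treatment, collapse = "+") else "treatment",
            fc_threshold = fc_threshold, p_threshold = p_threshold)
}

#' Volcano plot
#'
#' @param object A `differential_set` from [volcano_screen()].
#' @param ... Unused.
#' @return A ggplot of `-log10(p)` (or |log2fc| rank when p is absent)
#'   against `log2fc`, passing features highlighted.
#' @export
autoplot.differential_set <- function(object, ...) {
  df <- as_tibble(object)
  if (all(is.na(df$p))) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                     y = abs(.data$log2fc),
                                     color = .data$passes)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "log2 fold change", y = "|log2 FC|")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                     y = -log10(.data$p),
                                     color = .data$passes)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "log2 fold change", y = "-log10 p")
  }
}

#' Default control-vs-stress comparison scheme
#'
#' Generates the per-time comparisons of the control concentration against
#' each stress concentration at the matching time (e.g. `C27_T14` vs
#' `C16_T14`), the scheme the discriminant-group analysis suggests.
#'
#' @param fm A [feature_matrix()].
#' @param control_concentration The control level (default the first).
#' @param times Times to include (default: all times present).
#' @return A tibble with columns `control`, `treatment`.
#' @export
default_comparisons <- function(fm, control_concentration = NULL, times = NULL) {
  concs <- unique(fm$samples$concentration)
  control_concentration <- control_concentration %||% concs[1]
  times <- times %||% unique(fm$samples$time)
  stress <- setdiff(concs, control_concentration)
  tidyr::expand_grid(time = times, stress = stress) |>
    mutate(control = paste(control_concentration, .data$time, sep = "_"),
           treatment = paste(.data$stress, .data$time, sep = "_")) |>
    select("control", "treatment")
}

#' Cross-comparison frequency of differential features
#'
#' Counts, for every feature that passed at least one screen, the number of
#' comparisons in which it was flagged.
#'
#' @param sets List of `differential_set` objects (see [volcano_screen()]).
#' @return A list with `per_feature` (tibble: `label`, `frequency`,
#'   `comparisons_hit`) and `histogram` (tibble: `frequency`, `n_features`).
#' @export
comparison_frequency <- function(sets) {
  if (length(sets) == 0) abort("Need at least one differential set.")
  hits <- purrr::map_dfr(sets, function(s) {
    cmp <- paste(attr(s, "control"), attr(s, "treatment"), sep = " vs ")
    s |> as_tibble() |> filter(.data$passes) |>
      mutate(comparison = cmp) |> select("label", "comparison")
  })
  per_feature <- hits |>
    group_by(.data$label) |>
    summarise(frequency = dplyr::n(),
              comparisons_hit = list(.data$comparison), .groups = "drop") |>
    arrange(dplyr::desc(.data$frequency))
  histogram <- per_feature |> count(.data$frequency, name = "n_features")
  list(per_feature = per_feature, histogram = histogram)
}

#' Consolidate differential sets into the unique marker list
#'
#' Two bookkeeping modes: `frequency_filter` keeps features flagged in at
#' least `min_frequency` comparisons (the threshold the source workflow sets
#' at 2); `dedup_all` keeps every distinct flagged feature.
#'
#' @inheritParams comparison_frequency
#' @param min_frequency Minimum number of comparisons (default 2).
#' @param mode `"frequency_filter"` (default) or `"dedup_all"`.
#' @return A tibble (`dme_list`) with `label`, `frequency`,
#'   `comparisons_hit`, `direction` (sign summary of the mean log2fc).
#' @export
consolidate_dmes <- function(sets, min_frequency = 2,
                             mode = c("frequency_filter", "dedup_all")) {
  mode <- match.arg(mode)
  freq <- comparison_frequency(sets)$per_feature
  dirs <- purrr::map_dfr(sets, function(s) {
    as_tibble(s) |> filter(.data$passes) |> select("label", "log2fc")
  }) |>
    group_by(.data$label) |>
    summarise(direction = ifelse(mean(.data$log2fc) > 0, "up",
                                 ifelse(mean(.data$log2fc) < 0, "down", "mixed")),
              .groups = "drop")
  out <- left_join(freq, dirs, by = "label")
  if (mode == "frequency_filter") out <- filter(out, .data$frequency >= min_frequency)
  out
}
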