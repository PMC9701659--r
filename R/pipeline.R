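#' Run the four-step workflow end to end
#'
#' Orchestrates (i) chemodiversity (pooled richness, accumulation curve,
#' estimators, per-sample indices, diversity ANOVA, rank-abundance model
#' selection), (ii) chemometrics (normalization + PCA), (iii) differential
#' screening (per-time control-vs-stress volcano screens, frequency
#' consolidation) and (iv) annotation + pathway enrichment, writing tidy CSV
#' tables and a machine-readable `report.json` into `out_dir`.  All
#' randomness flows from the single `seed` through fixed per-step offsets,
#' so a rerun with the same inputs and seed is bit-identical.
#'
#' @param fm A [feature_matrix()].
#' @param out_dir Output directory (created if needed).
#' @param config Optional list overriding defaults: `transform`, `scaling`
#'   (see [normalize_features()]), `n_perm` (accumulation), `fc_threshold`,
#'   `p_threshold`, `min_frequency`, `tol_ppm`, `adducts`, `n_perm_enrich`,
#'   `compound_reference` and `pathway_file` (paths).
#' @param seed Integer global seed (default 1).
#' @return The run report (list), invisibly; `report.json` and the step
#'   tables are written under `out_dir`.
#' @export
run_pipeline <- function(fm, out_dir, config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    transform = "none", scaling = "autoscale",
    n_perm = 100, fc_threshold = 2, p_threshold = 0.05, min_frequency = 2,
    tol_ppm = 5, adducts = c("[M+H]+", "[M+Na]+"), n_perm_enrich = 100,
    compound_reference = NULL, pathway_file = NULL
  ), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package_version = as.character(utils::packageVersion("ecometab")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = cfg[setdiff(names(cfg), c("compound_reference", "pathway_file"))],
    steps = list()
  )
  write_partial <- function() {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  step <- function(name, body) {
    tryCatch(body, error = function(e) {
      report$failed_step <<- name
      write_partial()
      abort(sprintf("Pipeline aborted at step '%s': %s", name, conditionMessage(e)))
    })
  }

  # (i) chemodiversity
  step("diversity", {
    im <- to_incidence(fm)
    pooled <- pool_units(im, by = c("concentration", "time"))
    pooled_rich <- tibble(condition = rownames(pooled$presence),
                          richness = rowSums(pooled$presence))
    sac <- species_accumulation(im, n_perm = cfg$n_perm, seed = seed + 11L)
    est <- richness_estimators(im)
    idx <- diversity_indices(fm)
    div_anova <- anova_oneway(idx, value = H, group = concentration)
    mean_ab <- colMeans(fm$abundance)
    rad <- select_rad(mean_ab[mean_ab > 0], seed = seed + 13L)
    readr::write_csv(pooled_rich, file.path(out_dir, "pooled_richness.csv"), progress = FALSE)
    readr::write_csv(as_tibble(sac), file.path(out_dir, "sac.csv"), progress = FALSE)
    readr::write_csv(idx, file.path(out_dir, "diversity_indices.csv"), progress = FALSE)
    readr::write_csv(tidy(rad), file.path(out_dir, "rad_fits.csv"), progress = FALSE)
    report$steps$diversity <- list(
      n_samples = nrow(fm$abundance), n_features = ncol(fm$abundance),
      total_richness = est$S, chao = est$chao, jack1 = est$jack1, jack2 = est$jack2,
      anova_F = div_anova$F, anova_p = div_anova$p,
      best_rad_model = rad$best)
  })

  # (ii) chemometrics
  step("chemometrics", {
    norm <- normalize_features(fm, transform = cfg$transform, scaling = cfg$scaling)
    pca <- run_pca(norm, n_components = 5)
    readr::write_csv(tidy(pca), file.path(out_dir, "pca_scores.csv"), progress = FALSE)
    readr::write_csv(tibble(component = seq_along(pca$var_explained),
                            var_explained = pca$var_explained),
                     file.path(out_dir, "pca_variance.csv"), progress = FALSE)
    report$steps$chemometrics <- list(
      transform = cfg$transform, scaling = cfg$scaling,
      pc1_var = pca$var_explained[1], pc2_var = pca$var_explained[2])
  })

  # (iii) differential screening
  dmes <- NULL
  step("differential", {
    cmp <- default_comparisons(fm)
    sets <- purrr::map(seq_len(nrow(cmp)), function(i) {
      volcano_screen(fm, cmp$control[i], cmp$treatment[i],
                     fc_threshold = cfg$fc_threshold,
                     p_threshold = cfg$p_threshold)
    })
    per_cmp <- tibble(
      control = cmp$control, treatment = cmp$treatment,
      n_differential = vapply(sets, function(s) sum(s$passes), 1L))
    freq <- comparison_frequency(sets)
    dmes <- consolidate_dmes(sets, min_frequency = cfg$min_frequency)
    dedup <- consolidate_dmes(sets, mode = "dedup_all")
    readr::write_csv(per_cmp, file.path(out_dir, "differential_counts.csv"), progress = FALSE)
    readr::write_csv(freq$histogram, file.path(out_dir, "frequency_histogram.csv"), progress = FALSE)
    readr::write_csv(dmes |> select(-"comparisons_hit"),
                     file.path(out_dir, "dmes.csv"), progress = FALSE)
    report$steps$differential <- list(
      n_comparisons = nrow(cmp),
      total_flags = sum(per_cmp$n_differential),
      n_dme_frequency_filter = nrow(dmes),
      n_dme_dedup_all = nrow(dedup))
  })

  # (iv) annotation + enrichment
  step("annotation", {
    reference <- if (is.null(cfg$compound_reference)) read_compound_reference()
                 else read_compound_reference(cfg$compound_reference)
    pathways <- if (is.null(cfg$pathway_file)) read_pathways_gmt()
                else {
                  if (!file.exists(cfg$pathway_file)) {
                    abort(sprintf("Pathway file '%s' not found.", cfg$pathway_file))
                  }
                  read_pathways_gmt(cfg$pathway_file)
                }
    dme_feats <- fm$features |> filter(.data$label %in% dmes$label)
    ann <- match_features(dme_feats, reference,
                          adduct_names = cfg$adducts, tol_ppm = cfg$tol_ppm)
    report$steps$annotation <- list(
      n_dme = nrow(dme_feats),
      n_annotated = dplyr::n_distinct(ann$annotated$label),
      n_unannotated = length(ann$unannotated))
    if (nrow(ann$annotated) > 0) {
      enr <- pathway_enrichment(
        unique(ann$annotated$kegg_id), pathways,
        universe = unique(reference$kegg_id),
        all_features = fm$features, marker_size = nrow(dme_feats),
        reference = reference, adduct_names = cfg$adducts,
        tol_ppm = cfg$tol_ppm, n_perm = cfg$n_perm_enrich, seed = seed + 17L)
      rep_tabs <- build_report(ann$annotated, enr, pathways)
      readr::write_csv(ann$annotated, file.path(out_dir, "annotations.csv"), progress = FALSE)
      readr::write_csv(as_tibble(enr), file.path(out_dir, "enrichment.csv"), progress = FALSE)
      readr::write_csv(rep_tabs$mapping, file.path(out_dir, "pathway_mapping.csv"), progress = FALSE)
      report$steps$annotation$top_pathway <- enr$pathway_id[1]
      report$steps$annotation$top_pathway_p_exact <- enr$p_exact[1]
    }
  })

  write_partial()
  invisible(report)
}
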