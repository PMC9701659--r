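#' Describe a synthetic nutrient-stress metabolomics experiment
#'
#' The defaults emulate the positive-ionization arm of a 3 nitrate
#' concentrations x 5 sampling times x 3 replicates cell-culture design:
#' a baseline pool of 195 ion species under the control condition, richness
#' declining by 28.2% (intermediate stress) and 37.3% (severe stress) with
#' the decline phased in over the time course (none at T0, half at T7, full
#' from T14 on), lognormal-skewed abundances, a handful of stress-only rare
#' species appearing at late times under stress, Bernoulli per-replicate
#' detection dropout, and a set of spiked marker features with a known
#' multiplicative group effect for screening-recovery tests.
#'
#' @param n_conc,n_time,n_rep Design dimensions (concentrations, times,
#'   replicates).
#' @param S_base Baseline species-pool size (>= 10).
#' @param abundance_model `"lognormal"` or `"zipf"` community abundances.
#' @param meanlog,sdlog Lognormal parameters (abundance scale in counts).
#' @param gamma Zipf exponent (< 0) when `abundance_model = "zipf"`.
#' @param decline Per-concentration richness decline fractions in `[0, 1)`,
#'   first entry the control (0).
#' @param rare_induction Stress-only species added per stressed condition at
#'   the late (full-stress) times.
#' @param dropout Per-replicate, per-feature probability that a truly
#'   present feature goes undetected, in `[0, 1)`.
#' @param rep_cv Lognormal sdlog of the multiplicative replicate noise.
#' @param n_markers Number of spiked marker features.
#' @param marker_fc Multiplicative effect applied to markers in stressed
#'   groups at full-stress times (> 0).
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A `sim_design` list, input to [simulate_experiment()].
#' @export
sim_design <- function(n_conc = 3, n_time = 5, n_rep = 3,
                       S_base = 195,
                       abundance_model = c("lognormal", "zipf"),
                       meanlog = 3, sdlog = 1.2, gamma = -1,
                       decline = c(0, 0.282, 0.373),
                       rare_induction = 5,
                       dropout = 0.10,
                       rep_cv = 0.2,
                       n_markers = 20, marker_fc = 4,
                       seed = 1) {
  abundance_model <- match.arg(abundance_model)
  if (S_base < 10) abort("`S_base` must be >= 10.")
  if (length(decline) != n_conc) abort("`decline` needs one entry per concentration.")
  if (any(decline < 0 | decline >= 1)) abort("`decline` fractions must lie in [0, 1).")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must lie in [0, 1).")
  if (marker_fc <= 0) abort("`marker_fc` must be > 0.")
  structure(list(
    n_conc = n_conc, n_time = n_time, n_rep = n_rep, S_base = S_base,
    abundance_model = abundance_model, meanlog = meanlog, sdlog = sdlog,
    gamma = gamma, decline = decline, rare_induction = rare_induction,
    dropout = dropout, rep_cv = rep_cv, n_markers = n_markers,
    marker_fc = marker_fc, seed = seed
  ), class = "sim_design")
}

# stress phase-in over the time course: 0 at the first time, 0.5 at the
# second, 1 from the third on
stress_phase <- function(t_index) c(0, 0.5, rep(1, 1e3))[t_index]

#' Draw one community abundance vector
#'
#' @param S Number of species (>= 1).
#' @param model One of `"lognormal"`, `"zipf"`, `"brokenstick"`,
#'   `"preemption"` (the last two return the expected-proportion vectors of
#'   [rad_expected()], optionally perturbed).
#' @param N Total abundance for the normalized models (default `100 * S`).
#' @param meanlog,sdlog Lognormal parameters.
#' @param gamma Zipf exponent (< 0).
#' @param alpha Preemption fraction in (0, 1).
#' @param noise Lognormal sdlog of multiplicative perturbation applied to the
#'   deterministic models (0 = none).
#' @param seed Optional seed.
#' @return Length-S positive abundance vector.
#' @export
#' @examples
#' simulate_community(3, "brokenstick", N = 18)  # 11 5 2
simulate_community <- function(S, model = c("lognormal", "zipf", "brokenstick", "preemption"),
                               N = NULL, meanlog = 0, sdlog = 1, gamma = -1,
                               alpha = 0.5, noise = 0, seed = NULL) {
  model <- match.arg(model)
  if (S < 1) abort("`S` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  N <- N %||% (100 * S)
  x <- switch(model,
    lognormal = rlnorm(S, meanlog, sdlog),
    zipf = rad_expected("zipf", list(p1 = 1 / sum(seq_len(S)^gamma),
                                     gamma = gamma), S, N),
    brokenstick = rad_expected("brokenstick", list(), S, N),
    preemption = rad_expected("preemption", list(alpha = alpha), S, N)
  )
  if (noise > 0 && model %in% c("brokenstick", "preemption", "zipf")) {
    x <- x * rlnorm(S, 0, noise)
  }
  x
}

#' Simulate a full stress-course feature matrix with ground truth
#'
#' Builds the per-condition communities (richness decline, stress-induced
#' rare species, spiked markers), then draws replicate observations with
#' multiplicative noise and Bernoulli detection dropout.  Everything is
#' deterministic given `design$seed`.
#'
#' @param design A [sim_design()].
#' @return A list with `fm` (the [feature_matrix()]) and `truth` (a list:
#'   `true_richness` tibble per condition, `markers` tibble of spiked
#'   features with their fold change, `base_abundance`, `design`).
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  d <- design
  set.seed(d$seed)

  conc_levels <- if (d$n_conc == 3) c("C27", "C16", "C4") else paste0("C", seq_len(d$n_conc))
  time_levels <- if (d$n_time == 5) c("T0", "T7", "T14", "T21", "T28") else paste0("T", seq_len(d$n_time) - 1)

  # feature identities: m/z in the acquisition range, rt over the gradient
  n_rare_total <- d$rare_induction * (d$n_conc - 1) *
    sum(stress_phase(seq_len(d$n_time)) == 1)
  S_total <- d$S_base + n_rare_total
  mz <- round(sort(runif(S_total, 51, 1199)), 4)
  rt <- round(runif(S_total, 0.2, 15), 2)
  labels <- format_feature_id(sprintf("%.4f", mz), sprintf("%.2f", rt))
  base_idx <- seq_len(d$S_base)
  rare_pool <- setdiff(seq_len(S_total), base_idx)

  # baseline community abundances (skewed)
  base_ab <- switch(d$abundance_model,
    lognormal = rlnorm(d$S_base, d$meanlog, d$sdlog),
    zipf = simulate_community(d$S_base, "zipf", N = d$S_base * exp(d$meanlog),
                              gamma = d$gamma))
  # rare species live in the low-abundance tail
  rare_ab_level <- quantile(base_ab, 0.15)

  # spiked markers: drawn from the base pool
  marker_idx <- sort(sample(base_idx, min(d$n_markers, d$S_base)))

  conditions <- tidyr::expand_grid(concentration = conc_levels, time = time_levels)
  truth_rows <- list()
  sample_rows <- list()
  ab_rows <- list()
  rare_cursor <- 0

  for (ci in seq_len(d$n_conc)) {
    for (ti in seq_len(d$n_time)) {
      conc <- conc_levels[ci]; tm <- time_levels[ti]
      eff_decline <- d$decline[ci] * stress_phase(ti)
      S_cond <- max(1L, round(d$S_base * (1 - eff_decline)))
      present <- sort(sample(base_idx, S_cond))
      # stress-only rare species at full-stress times
      rare_here <- integer(0)
      if (ci > 1 && stress_phase(ti) == 1 && d$rare_induction > 0) {
        rare_here <- rare_pool[rare_cursor + seq_len(d$rare_induction)]
        rare_cursor <- rare_cursor + d$rare_induction
      }
      cond_idx <- c(present, rare_here)
      if (length(cond_idx) < 1) abort("Design produced an empty condition.")
      cond_mean <- numeric(S_total)
      cond_mean[present] <- base_ab[present]
      cond_mean[rare_here] <- rare_ab_level * rlnorm(length(rare_here), 0, 0.3)
      # marker effect in stress-treatment groups at full-stress times
      # (treatment arm, not richness decline, defines "stressed")
      stressed <- ci > 1 && stress_phase(ti) == 1
      if (stressed) {
        boost <- intersect(marker_idx, which(cond_mean > 0))
        cond_mean[boost] <- cond_mean[boost] * d$marker_fc
      }
      truth_rows[[length(truth_rows) + 1]] <- tibble(
        concentration = conc, time = tm,
        true_richness = length(cond_idx), stressed = stressed)
      for (rep in seq_len(d$n_rep)) {
        noise <- rlnorm(S_total, 0, d$rep_cv)
        detected <- rbinom(S_total, 1, 1 - d$dropout)
        obs <- cond_mean * noise * detected
        obs[cond_mean == 0] <- 0
        sample_rows[[length(sample_rows) + 1]] <- tibble(
          sample_id = paste(conc, tm, rep, sep = "_"),
          concentration = conc, time = tm, replicate = rep, mode = "ESI+")
        ab_rows[[length(ab_rows) + 1]] <- obs
      }
    }
  }

  samples <- bind_rows(sample_rows)
  ab <- do.call(rbind, ab_rows)
  dimnames(ab) <- list(samples$sample_id, labels)
  fm <- feature_matrix(ab, samples,
                       features = tibble(label = labels, mz = mz, rt = rt))
  truth <- list(
    true_richness = bind_rows(truth_rows),
    markers = tibble(label = labels[marker_idx], fold_change = d$marker_fc),
    base_abundance = setNames(base_ab, labels[base_idx]),
    spiked_pathway = character(0),
    design = d
  )
  list(fm = fm, truth = truth)
}

#' Spike a pathway's compounds into a simulated feature matrix
#'
#' For each compound, a feature is created at the exact theoretical adduct
#' m/z (0 ppm) and boosted by `fc` in the stressed groups, so that
#' annotation and pathway enrichment can be tested against known truth.
#'
#' @param fm A [feature_matrix()] from [simulate_experiment()].
#' @param truth The matching truth list (updated and returned).
#' @param compounds Character vector of KEGG compound IDs present in
#'   `reference`.
#' @param reference Compound reference tibble (see
#'   [read_compound_reference()]); defaults to the bundled table.
#' @param adduct Adduct name, e.g. `"[M+Na]+"`.
#' @param fc Fold change applied in stressed samples (> 0; `fc = 1` leaves
#'   abundances unchanged for pre-existing features).
#' @param base_abundance Abundance given to the spiked features in
#'   unstressed samples.
#' @return A list with the updated `fm` and `truth` (gains
#'   `spiked_pathway`, the compound IDs, and `spiked_features`).
#' @export
spike_pathway <- function(fm, truth, compounds,
                          reference = read_compound_reference(),
                          adduct = "[M+Na]+", fc = 8, base_abundance = 50) {
  if (fc <= 0) abort("`fc` must be > 0.")
  missing_cpd <- setdiff(compounds, reference$kegg_id)
  if (length(missing_cpd) > 0) {
    abort(paste0("Compound(s) not in reference: ", paste(missing_cpd, collapse = ", ")))
  }
  ref <- reference[match(compounds, reference$kegg_id), ]
  theo <- unname(vapply(ref$formula,
                        function(f) adduct_mz(monoisotopic_mass(f), adduct),
                        numeric(1)))
  stressed_cond <- truth$true_richness |>
    filter(.data$stressed) |>
    mutate(cond = paste(.data$concentration, .data$time, sep = "_")) |>
    pull(.data$cond)
  sample_cond <- paste(fm$samples$concentration, fm$samples$time, sep = "_")
  in_stress <- sample_cond %in% stressed_cond

  ab <- fm$abundance
  new_labels <- character(0)
  for (i in seq_along(theo)) {
    label <- format_feature_id(sprintf("%.4f", theo[i]), "5.00")
    if (label %in% colnames(ab)) {
      ab[in_stress, label] <- ab[in_stress, label] * fc
    } else {
      col <- rep(base_abundance, nrow(ab))
      col[in_stress] <- base_abundance * fc
      ab <- cbind(ab, setNames(data.frame(col), label) |> as.matrix())
      colnames(ab)[ncol(ab)] <- label
      new_labels <- c(new_labels, label)
    }
  }
  feats <- bind_rows(fm$features,
                     parse_feature_id(new_labels))
  fm2 <- feature_matrix(ab, fm$samples, features = feats)
  truth$spiked_pathway <- compounds
  truth$spiked_features <- tibble(
    kegg_id = compounds,
    label = vapply(theo, function(m) format_feature_id(sprintf("%.4f", m), "5.00"), ""),
    theoretical_mz = theo, adduct = adduct, fold_change = fc)
  list(fm = fm2, truth = truth)
}
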