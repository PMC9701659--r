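#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * log(p_i))` with the abundance vector normalized to
#' proportions; zeros are skipped.  Natural logarithms throughout, so a
#' uniform community of S species has `H = log(S)` nats.
#'
#' @param x Non-negative abundance or proportion vector with at least one
#'   positive entry.
#' @return Shannon index in nats.
#' @export
#' @examples
#' shannon(rep(1, 4))  # log(4)
shannon <- function(x) {
  x <- check_abundance(x)
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Inverse Simpson diversity index
#'
#' `DSi = 1 / sum(p_i^2)`: the effective number of equally common species.
#' A uniform community of S species scores exactly S.
#'
#' @inheritParams shannon
#' @return Inverse Simpson index (effective species count).
#' @export
inverse_simpson <- function(x) {
  x <- check_abundance(x)
  p <- x[x > 0] / sum(x)
  1 / sum(p^2)
}

#' Pielou evenness
#'
#' `J = H / log(S)` where S is the number of species with positive
#' abundance.  Undefined (error) for fewer than two species.
#'
#' @inheritParams shannon
#' @return Evenness in `[0, 1]`.
#' @export
pielou <- function(x) {
  x <- check_abundance(x)
  s <- sum(x > 0)
  if (s < 2) abort("Pielou evenness needs at least 2 species with positive abundance.")
  shannon(x) / log(s)
}

check_abundance <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(x < 0)) abort("Abundances must be non-negative and non-missing.")
  if (all(x == 0)) abort("All-zero abundance vector.")
  x
}

#' Per-sample diversity indices
#'
#' Computes observed richness S, Shannon H (nats), inverse Simpson DSi and
#' Pielou J for every sample of a feature matrix, with optional bootstrap
#' confidence intervals obtained by resampling features within each sample.
#'
#' @param fm A [feature_matrix()], or a samples-by-features matrix.
#' @param ci Add percentile bootstrap confidence intervals?
#' @param B Number of bootstrap resamples (>= 50; default 100).
#' @param level Confidence level (default 0.95).
#' @param seed Seed making the bootstrap reproducible.
#' @return A tibble with one row per sample: `sample_id`, `S`, `H`, `DSi`,
#'   `J`, and `<index>_lo`/`<index>_hi` columns when `ci = TRUE`, joined to
#'   the sample metadata.
#' @export
diversity_indices <- function(fm, ci = FALSE, B = 100, level = 0.95, seed = 1) {
  ab <- if (inherits(fm, "feature_matrix")) fm$abundance else as.matrix(fm)
  meta <- if (inherits(fm, "feature_matrix")) fm$samples else
    tibble(sample_id = rownames(ab) %||% paste0("s", seq_len(nrow(ab))))
  one <- function(x) {
    s <- sum(x > 0)
    tibble(S = s, H = shannon(x), DSi = inverse_simpson(x),
           J = if (s > 1) pielou(x) else NA_real_)
  }
  out <- purrr::map_dfr(seq_len(nrow(ab)), function(i) one(ab[i, ]))
  out <- bind_cols(tibble(sample_id = meta$sample_id), out)
  if (ci) {
    if (B < 50) abort("Use at least 50 bootstrap resamples.")
    set.seed(seed)
    cis <- purrr::map_dfr(seq_len(nrow(ab)), function(i) {
      x <- ab[i, ]
      boots <- replicate(B, {
        xb <- x[sample.int(length(x), replace = TRUE)]
        c(H = shannon(xb), DSi = inverse_simpson(xb),
          J = if (sum(xb > 0) > 1) pielou(xb) else NA_real_)
      })
      qs <- apply(boots, 1, quantile,
                  probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                  na.rm = TRUE)
      tibble(H_lo = qs[1, "H"], H_hi = qs[2, "H"],
             DSi_lo = qs[1, "DSi"], DSi_hi = qs[2, "DSi"],
             J_lo = qs[1, "J"], J_hi = qs[2, "J"])
    })
    out <- bind_cols(out, cis)
  }
  left_join(out, meta, by = "sample_id")
}

#' Incidence-based richness estimators (Chao, jackknife 1 and 2)
#'
#' Nonparametric asymptotic-richness estimators driven by Q1 (species seen
#' in exactly one unit) and Q2 (exactly two units), with n sampling units:
#'
#' * Chao (incidence form): `S + ((n-1)/n) * Q1^2 / (2*Q2)`, replaced by the
#'   bias-corrected `S + ((n-1)/n) * Q1*(Q1-1)/(2*(Q2+1))` when `Q2 = 0`
#' * first-order jackknife: `S + Q1 * (n-1)/n`
#' * second-order jackknife: `S + Q1*(2n-3)/n - Q2*(n-2)^2/(n*(n-1))`
#'
#' @param im An `incidence_matrix` (see [to_incidence()]), or a binary
#'   units-by-species matrix.
#' @return A one-row tibble with `S`, `Q1`, `Q2`, `n`, `chao`, `jack1`,
#'   `jack2`.
#' @export
richness_estimators <- function(im) {
  pres <- if (inherits(im, "incidence_matrix")) im$presence else (as.matrix(im) > 0) * 1L
  n <- nrow(pres)
  if (n < 2) abort("Richness estimators need at least 2 sampling units.")
  freq <- colSums(pres)
  S <- sum(freq > 0)
  Q1 <- sum(freq == 1)
  Q2 <- sum(freq == 2)
  chao <- if (Q2 > 0) {
    S + ((n - 1) / n) * Q1^2 / (2 * Q2)
  } else {
    S + ((n - 1) / n) * Q1 * (Q1 - 1) / 2
  }
  jack1 <- S + Q1 * (n - 1) / n
  jack2 <- S + Q1 * (2 * n - 3) / n - Q2 * (n - 2)^2 / (n * (n - 1))
  tibble(S = S, Q1 = Q1, Q2 = Q2, n = n, chao = chao, jack1 = jack1, jack2 = jack2)
}

#' Species accumulation curve by random unit ordering
#'
#' For each sample count k, the cumulative number of distinct species over k
#' units is averaged over `n_perm` random orderings of the sampling units
#' (the "random" accumulation method).  The 95% band is `mean +/- 1.96 * sd`.
#'
#' @param im An `incidence_matrix` or binary matrix (units x species).
#' @param n_perm Number of random orderings (default 100).
#' @param seed Seed for the permutations.
#' @return A `sac_result`: tibble with columns `k`, `richness`, `sd`, `lo`,
#'   `hi`; the richness-estimator row and Q1/Q2 are attached as attributes
#'   `estimators`, and `n_perm`/`seed` are recorded.
#' @export
species_accumulation <- function(im, n_perm = 100, seed = 1) {
  pres <- if (inherits(im, "incidence_matrix")) im$presence else (as.matrix(im) > 0) * 1L
  n <- nrow(pres)
  if (n < 1 || ncol(pres) < 1) abort("Empty incidence matrix.")
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  set.seed(seed)
  acc <- matrix(0, n_perm, n)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n)
    seen <- rep(FALSE, ncol(pres))
    for (k in seq_len(n)) {
      seen <- seen | (pres[ord[k], ] > 0)
      acc[p, k] <- sum(seen)
    }
  }
  means <- colMeans(acc)
  sds <- apply(acc, 2, sd)
  curve <- tibble(k = seq_len(n), richness = means, sd = sds,
                  lo = means - 1.96 * sds, hi = means + 1.96 * sds)
  out <- structure(curve, class = c("sac_result", class(curve)))
  attr(out, "estimators") <- if (n >= 2) richness_estimators(pres) else NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' @export
glance.sac_result <- function(x, ...) {
  est <- attr(x, "estimators")
  base <- tibble(n_units = nrow(x), S_obs = x$richness[nrow(x)],
                 n_perm = attr(x, "n_perm"))
  if (!is.null(est)) bind_cols(base, est[, c("Q1", "Q2", "chao", "jack1", "jack2")]) else base
}

#' Species accumulation curve plot
#'
#' @param object A `sac_result`.
#' @param ... Unused.
#' @return A ggplot of mean cumulative richness with its 95% band.
#' @export
autoplot.sac_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$richness)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Sampling units", y = "Cumulative richness (m/z_rt pairs)")
}

#' Analytic sample-based rarefaction (Mao's tau)
#'
#' Expected richness in a random subset of k sampling units:
#' `S - sum_j C(n - n_j, k) / C(n, k)` where `n_j` is the number of units in
#' which species j occurs.  This is the `n_perm -> Inf` limit of
#' [species_accumulation()].
#'
#' @param im An `incidence_matrix` or binary matrix.
#' @param k Vector of unit counts, each in `1..n`.
#' @return Numeric vector of expected richness values, one per `k`.
#' @export
rarefaction <- function(im, k) {
  pres <- if (inherits(im, "incidence_matrix")) im$presence else (as.matrix(im) > 0) * 1L
  n <- nrow(pres)
  if (any(k < 1 | k > n)) abort(sprintf("`k` must lie in 1..%d.", n))
  freq <- colSums(pres)
  freq <- freq[freq > 0]
  S <- length(freq)
  vapply(k, function(kk) {
    # lchoose is stable for the large n the pooled designs produce
    absent <- exp(lchoose(n - freq, kk) - lchoose(n, kk))
    S - sum(absent)
  }, numeric(1))
}

#' Percentile bootstrap confidence interval over sampling units
#'
#' Resamples the rows (sampling units) of an incidence or abundance matrix
#' with replacement and returns the percentile interval of a statistic.
#'
#' @param data An `incidence_matrix`, `feature_matrix` or matrix whose rows
#'   are resampled.
#' @param statistic Function mapping the resampled matrix to a single number.
#' @param B Number of resamples (the floor is 50).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for reproducibility.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
#' @examples
#' m <- matrix(rbinom(60, 1, 0.5), nrow = 6)
#' bootstrap_ci(m, function(x) sum(colSums(x) > 0), B = 100, seed = 1)
bootstrap_ci <- function(data, statistic, B = 100, level = 0.95, seed = 1) {
  m <- if (inherits(data, "incidence_matrix")) data$presence
       else if (inherits(data, "feature_matrix")) data$abundance
       else as.matrix(data)
  if (B < 50) abort("The bootstrap floor is 50 resamples.")
  if (nrow(m) < 2) abort("Bootstrap needs at least 2 sampling units.")
  set.seed(seed)
  stats <- replicate(B, statistic(m[sample.int(nrow(m), replace = TRUE), , drop = FALSE]))
  qs <- quantile(stats, probs = c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  c(lo = unname(qs[1]), hi = unname(qs[2]))
}
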