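#' Lilliefors (Kolmogorov-Smirnov) normality test
#'
#' D is the supremum distance between the empirical CDF and the normal CDF
#' with mean and SD estimated from the sample.  Because the parameters are
#' estimated, the plain KS null distribution does not apply; the p-value is
#' obtained by Monte-Carlo simulation of the null (default), or by the
#' analytic Dallal-Wilkinson approximation for speed.
#'
#' @param x Numeric sample, n >= 4, non-constant.
#' @param p_method `"monte_carlo"` (default) or `"approx"` (delegates to
#'   [nortest::lillie.test()]).
#' @param n_sim Monte-Carlo replicates (default 10000).
#' @param seed Seed for the Monte-Carlo null.
#' @return A tibble with `D`, `p`, `n`, `method`.
#' @export
lilliefors <- function(x, p_method = c("monte_carlo", "approx"),
                       n_sim = 10000, seed = 1) {
  p_method <- match.arg(p_method)
  x <- as.numeric(na.omit(x))
  n <- length(x)
  if (n < 4) abort("Lilliefors test needs n >= 4.")
  if (sd(x) == 0) abort("Constant sample: normality test undefined.")
  D <- lillie_stat(x)
  if (p_method == "approx" && n < 5) {
    abort("The analytic approximation needs n >= 5; use p_method = \"monte_carlo\".")
  }
  p <- if (p_method == "approx") {
    nortest::lillie.test(x)$p.value
  } else {
    set.seed(seed)
    null_D <- replicate(n_sim, lillie_stat(rnorm(n)))
    # add-one correction keeps p in (0, 1]
    (sum(null_D >= D) + 1) / (n_sim + 1)
  }
  tibble(D = D, p = p, n = n, method = p_method)
}

# sup |ECDF - fitted normal CDF|, evaluated at the jump points
lillie_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition with the F statistic and its
#' p-value.  Accepts either a data frame with a value and a group column
#' (tidy style) or a list of numeric vectors.
#'
#' @param data Data frame, or list of numeric group vectors.
#' @param value,group Column names (tidy-evaluated) when `data` is a data
#'   frame.
#' @return An `anova_result`: list with `F`, `df_between`, `df_within`, `p`,
#'   sums of squares and a `group_means` tibble.  `tidy()` and `glance()`
#'   methods return tibbles.
#' @export
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8)))$F  # 21
anova_oneway <- function(data, value = NULL, group = NULL) {
  groups <- groups_from_input(data, {{ value }}, {{ group }})
  if (length(groups) < 2) abort("Need at least 2 groups.")
  if (any(lengths(groups) < 2)) abort("Each group needs n >= 2.")
  all_x <- unlist(groups)
  grand <- mean(all_x)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 1) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1
  dfw <- length(all_x) - length(groups)
  if (dfw == 0 || ssw == 0 && ssb == 0) {
    Fval <- if (ssb == 0) 0 else Inf
  } else {
    Fval <- (ssb / dfb) / (ssw / dfw)
  }
  p <- pf(Fval, dfb, dfw, lower.tail = FALSE)
  structure(list(
    F = Fval, df_between = dfb, df_within = dfw, p = p,
    ss_between = ssb, ss_within = ssw,
    group_means = tibble(group = names(groups) %||% paste0("g", seq_along(groups)),
                         n = lengths(groups), mean = vapply(groups, mean, 1)),
    groups = groups
  ), class = "anova_result")
}

groups_from_input <- function(data, value, group) {
  if (is.data.frame(data)) {
    v <- dplyr::pull(data, {{ value }})
    g <- dplyr::pull(data, {{ group }})
    split(v, g)
  } else if (is.list(data)) {
    if (is.null(names(data))) names(data) <- paste0("g", seq_along(data))
    data
  } else {
    abort("`data` must be a data frame or a list of numeric vectors.")
  }
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' @export
glance.anova_result <- function(x, ...) {
  tibble(F = x$F, df_between = x$df_between, df_within = x$df_within, p = x$p)
}

#' @export
tidy.anova_result <- function(x, ...) x$group_means

#' Tukey honest significant difference with compact letter display
#'
#' Pairwise studentized-range adjusted p-values and confidence intervals for
#' all group pairs, plus letter groupings: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @inheritParams anova_oneway
#' @param alpha Familywise error rate (default 0.05).
#' @return A list with `pairs` (tibble: pair, difference, CI, adjusted p)
#'   and `letters` (tibble: group, letters).
#' @export
tukey_hsd <- function(data, value = NULL, group = NULL, alpha = 0.05) {
  groups <- groups_from_input(data, {{ value }}, {{ group }})
  if (length(groups) < 2) abort("Need at least 2 groups.")
  df <- tibble(value = unlist(groups),
               group = factor(rep(names(groups), lengths(groups)),
                              levels = names(groups)))
  tk <- TukeyHSD(aov(value ~ group, data = df), conf.level = 1 - alpha)$group
  pairs <- as_tibble(tk, rownames = "pair") |>
    rename(difference = "diff", lo = "lwr", hi = "upr", p_adj = "p adj")
  # compact letter display by insert-absorb on the non-significant pairs
  letters <- cld_insert_absorb(names(groups), pairs, alpha)
  list(pairs = pairs, letters = letters)
}

cld_insert_absorb <- function(group_names, pairs, alpha) {
  k <- length(group_names)
  same <- matrix(TRUE, k, k, dimnames = list(group_names, group_names))
  for (i in seq_len(nrow(pairs))) {
    gs <- strsplit(pairs$pair[i], "-", fixed = TRUE)[[1]]
    if (pairs$p_adj[i] <= alpha) {
      same[gs[1], gs[2]] <- same[gs[2], gs[1]] <- FALSE
    }
  }
  # start with one letter set containing everything, split on conflicts
  sets <- list(group_names)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!same[i, j]) {
        gi <- group_names[i]; gj <- group_names[j]
        conflicted <- vapply(sets, function(s) all(c(gi, gj) %in% s), TRUE)
        for (ci in which(conflicted)) {
          s <- sets[[ci]]
          sets[[ci]] <- setdiff(s, gj)
          sets[[length(sets) + 1]] <- setdiff(s, gi)
        }
        # absorb duplicated / nested sets
        keep <- rep(TRUE, length(sets))
        for (a in seq_along(sets)) {
          for (b in seq_along(sets)) {
            if (a != b && keep[a] && all(sets[[a]] %in% sets[[b]]) &&
                length(sets[[a]]) < length(sets[[b]])) keep[a] <- FALSE
          }
        }
        sets <- unique(sets[keep])
      }
    }
  }
  lab <- vapply(group_names, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, TRUE))], collapse = "")
  }, "")
  tibble(group = group_names, letters = unname(lab))
}

#' Pearson correlation with coefficient of determination
#'
#' Standard Pearson r with `R2 = 100 * r^2` (percent), the t-based p-value
#' and the least-squares line.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-constant.
#' @return A one-row tibble: `r`, `R2` (percent), `p`, `slope`, `intercept`,
#'   `n`.
#' @export
#' @examples
#' pearson_cor(1:10, 2 * (1:10) + 1)  # r = 1, R2 = 100
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need n >= 3.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero-variance input.")
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  tibble(r = unname(ct$estimate), R2 = 100 * unname(ct$estimate)^2,
         p = ct$p.value,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n = length(x))
}
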