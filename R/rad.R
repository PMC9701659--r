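#' Expected rank-abundance under a parametric model
#'
#' Closed-form expected abundance by rank for the five classical
#' rank-abundance distribution (RAD) models.  With rank `r = 1..S` and total
#' abundance `N`:
#'
#' * broken stick (null, no free parameters): `a_r = (N/S) * sum(1/x, x = r..S)`
#' * geometric/niche preemption (`alpha`): `a_r` proportional to
#'   `alpha * (1 - alpha)^(r-1)`, normalized to sum to `N`
#' * lognormal (`mu`, `sigma`): `a_r = exp(mu + sigma * qnorm((S - r + 0.5)/S))`
#' * Zipf (`p1`, `gamma`, `gamma < 0`): `a_r = N * p1 * r^gamma`
#' * Zipf-Mandelbrot (`c`, `beta`, `gamma`): `a_r = N * c * (r + beta)^gamma`
#'
#' @param model One of `"brokenstick"`, `"preemption"`, `"lognormal"`,
#'   `"zipf"`, `"zipf_mandelbrot"`.
#' @param params Named list/vector of model parameters (see above; empty for
#'   the broken stick).
#' @param S Number of species (ranks).
#' @param N Total community abundance (ignored by the lognormal, whose scale
#'   lives in `mu`).
#' @return Numeric vector of expected abundances for ranks `1..S`.
#' @export
#' @examples
#' rad_expected("brokenstick", list(), S = 3, N = 18)  # 11 5 2
rad_expected <- function(model, params = list(), S, N = NULL) {
  if (S < 1) abort("`S` must be >= 1.")
  params <- as.list(params)
  r <- seq_len(S)
  switch(model,
    brokenstick = {
      if (is.null(N)) abort("Broken stick needs `N`.")
      (N / S) * rev(cumsum(1 / rev(r)))
    },
    preemption = {
      alpha <- params$alpha
      if (is.null(alpha) || alpha <= 0 || alpha >= 1) {
        abort("Preemption needs `alpha` in (0, 1).")
      }
      if (is.null(N)) abort("Preemption needs `N`.")
      raw <- alpha * (1 - alpha)^(r - 1)
      N * raw / sum(raw)
    },
    lognormal = {
      if (is.null(params$mu) || is.null(params$sigma)) {
        abort("Lognormal needs `mu` and `sigma`.")
      }
      exp(params$mu + params$sigma * qnorm((S - r + 0.5) / S))
    },
    zipf = {
      if (is.null(params$p1) || is.null(params$gamma)) abort("Zipf needs `p1` and `gamma`.")
      if (params$gamma >= 0) abort("Zipf `gamma` must be < 0.")
      if (is.null(N)) abort("Zipf needs `N`.")
      N * params$p1 * r^params$gamma
    },
    zipf_mandelbrot = {
      if (is.null(params$c) || is.null(params$beta) || is.null(params$gamma)) {
        abort("Zipf-Mandelbrot needs `c`, `beta` and `gamma`.")
      }
      if (is.null(N)) abort("Zipf-Mandelbrot needs `N`.")
      N * params$c * (r + params$beta)^params$gamma
    },
    abort(sprintf("Unknown RAD model '%s'.", model))
  )
}

rad_models_available <- c("brokenstick", "preemption", "lognormal",
                          "zipf", "zipf_mandelbrot")

rad_n_params <- c(brokenstick = 0L, preemption = 1L, lognormal = 2L,
                  zipf = 2L, zipf_mandelbrot = 3L)

# Poisson log-likelihood of counts y under mean mu (gamma terms included so
# AIC values are comparable across models)
poisson_loglik <- function(y, mu) {
  mu <- pmax(mu, .Machine$double.eps)
  sum(y * log(mu) - mu - lgamma(y + 1))
}

# Poisson (saturated-model) deviance
poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, .Machine$double.eps)
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' Fit one rank-abundance model by Poisson maximum likelihood
#'
#' Abundances are sorted in decreasing order and treated as counts; model
#' parameters maximize the Poisson likelihood of the observed counts given
#' the [rad_expected()] curve.  The broken stick has no free parameters.  The
#' optimizer is Nelder-Mead with multiple deterministic restarts because the
#' Zipf-Mandelbrot likelihood is multimodal.
#'
#' @param x Positive abundance vector (any order; sorted internally).
#' @param model One of the five RAD model names.
#' @param n_restarts Number of jittered restarts for multi-parameter models.
#' @param seed Seed for the restart jitter (default 1; the fit is
#'   deterministic under a fixed seed).
#' @return A `rad_fit` object: list with `model`, `params`, `expected`,
#'   `deviance`, `aic`, `loglik`, `resid_sd` and `converged`.
#' @export
fit_rad <- function(x, model, n_restarts = 5, seed = 1) {
  if (any(x <= 0)) abort("All abundances must be > 0.")
  y <- sort(as.numeric(x), decreasing = TRUE)
  S <- length(y)
  N <- sum(y)
  k <- rad_n_params[[model]]

  make_fit <- function(params, converged) {
    expected <- tryCatch(rad_expected(model, params, S, N), error = function(e) NULL)
    if (is.null(expected) || any(!is.finite(expected))) {
      return(structure(list(model = model, params = params, expected = NULL,
                            deviance = NA_real_, aic = NA_real_,
                            loglik = NA_real_, resid_sd = NA_real_,
                            converged = FALSE),
                       class = "rad_fit"))
    }
    ll <- poisson_loglik(y, expected)
    structure(list(
      model = model, params = params, expected = expected,
      deviance = poisson_deviance(y, expected),
      aic = -2 * ll + 2 * k,
      loglik = ll,
      resid_sd = sd(y - expected),
      converged = converged
    ), class = "rad_fit")
  }

  if (model == "brokenstick") return(make_fit(list(), TRUE))
  if (S == 1 && model != "preemption") {
    # a single rank cannot identify >=2-parameter shape models
    return(make_fit(switch(model,
      lognormal = list(mu = log(y), sigma = 1),
      zipf = list(p1 = 1, gamma = -1),
      zipf_mandelbrot = list(c = 1, beta = 0, gamma = -1)), FALSE))
  }

  # parameter transforms keeping the optimizer unconstrained
  pack <- switch(model,
    preemption = list(
      init = function() stats::qlogis(min(max(y[1] / N, 1e-3), 1 - 1e-3)),
      to = function(th) list(alpha = stats::plogis(th[1]))),
    lognormal = list(
      init = function() c(mean(log(y)), log(max(sd(log(y)), 1e-2))),
      to = function(th) list(mu = th[1], sigma = exp(th[2]))),
    zipf = list(
      init = function() c(stats::qlogis(min(max(y[1] / N, 1e-4), 1 - 1e-4)), log(1)),
      to = function(th) list(p1 = stats::plogis(th[1]), gamma = -exp(th[2]))),
    zipf_mandelbrot = list(
      init = function() c(log(max(y[1] / N, 1e-4)), log(0.5), log(1)),
      to = function(th) list(c = exp(th[1]), beta = exp(th[2]) - 0.5,
                             gamma = -exp(th[3])))
  )

  objective <- function(th) {
    p <- pack$to(th)
    mu <- tryCatch(rad_expected(model, p, S, N), error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu)) || any(mu <= 0)) return(1e12)
    -poisson_loglik(y, mu)
  }

  init0 <- pack$init()
  starts <- list(init0)
  if (n_restarts > 1) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(seed)
    for (i in seq_len(n_restarts - 1)) {
      starts[[i + 1]] <- init0 + rnorm(length(init0), sd = 0.5)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }

  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      optim(st, objective, method = if (length(st) == 1) "Brent" else "Nelder-Mead",
            lower = if (length(st) == 1) -20 else -Inf,
            upper = if (length(st) == 1) 20 else Inf,
            control = list(maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best) || best$value >= 1e12) {
    return(make_fit(pack$to(init0), FALSE))
  }
  make_fit(pack$to(best$par), best$convergence == 0)
}

#' @export
print.rad_fit <- function(x, ...) {
  cat(sprintf("<rad_fit> %s: AIC %.2f, deviance %.3f%s\n", x$model,
              x$aic, x$deviance, if (x$converged) "" else " (not converged)"))
  if (length(x$params) > 0) {
    cat("  params:", paste(names(x$params),
                           signif(unlist(x$params), 4), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
glance.rad_fit <- function(x, ...) {
  tibble(model = x$model,
         n_params = rad_n_params[[x$model]],
         deviance = x$deviance, aic = x$aic, loglik = x$loglik,
         resid_sd = x$resid_sd, converged = x$converged)
}

#' @export
tidy.rad_fit <- function(x, ...) {
  if (length(x$params) == 0) return(tibble(term = character(), estimate = numeric()))
  tibble(term = names(x$params), estimate = unlist(x$params, use.names = FALSE))
}

#' Fit all five RAD models and rank them by AIC
#'
#' All five models are attempted; the result table is sorted by ascending
#' AIC with ties broken in favor of fewer free parameters.  Failed fits stay
#' in the table flagged as not converged.
#'
#' @inheritParams fit_rad
#' @return A `rad_select` object: list with `fits` (named list of `rad_fit`),
#'   `best` (the winning model name) and `table` (the ranked tibble).
#' @export
#' @examples
#' x <- rad_expected("brokenstick", list(), S = 20, N = 2000)
#' select_rad(round(x))$best
select_rad <- function(x, n_restarts = 5, seed = 1) {
  fits <- lapply(rad_models_available, function(m) fit_rad(x, m, n_restarts, seed))
  names(fits) <- rad_models_available
  tab <- purrr::map_dfr(fits, glance)
  ok <- !is.na(tab$aic)
  if (!any(ok)) abort("All RAD fits failed.")
  tab <- tab[order(!ok, tab$aic, tab$n_params), ]
  structure(list(fits = fits, best = tab$model[1], table = tab,
                 observed = sort(as.numeric(x), decreasing = TRUE)),
            class = "rad_select")
}

#' @export
print.rad_select <- function(x, ...) {
  cat(sprintf("<rad_select> best model: %s\n", x$best))
  print(x$table)
  invisible(x)
}

#' @export
tidy.rad_select <- function(x, ...) x$table

#' Rank-abundance plot with fitted model curves
#'
#' @param object A `rad_select` object.
#' @param ... Unused.
#' @return A ggplot: observed abundances by rank (log scale) with the
#'   expected curve of each converged model.
#' @export
autoplot.rad_select <- function(object, ...) {
  y <- object$observed
  obs <- tibble(rank = seq_along(y), abundance = y)
  curves <- purrr::map_dfr(object$fits, function(f) {
    if (is.null(f$expected)) return(NULL)
    tibble(model = f$model, rank = seq_along(f$expected), expected = f$expected)
  })
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$abundance)) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$expected, color = .data$model)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Rank", y = "Abundance",
                  title = paste("Rank-abundance fits; best:", object$best))
}
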