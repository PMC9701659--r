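test_that("diversity indices evaluate their closed forms", {
  expect_equal(shannon(rep(0.25, 4)), log(4))
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_equal(shannon(c(4, 4, 2)),
               -sum(c(0.4, 0.4, 0.2) * log(c(0.4, 0.4, 0.2))))
  expect_equal(round(shannon(c(4, 4, 2)), 4), 1.0549)

  expect_equal(inverse_simpson(rep(1, 10)), 10)
  expect_equal(inverse_simpson(c(1, 0)), 1)
  expect_equal(inverse_simpson(c(0.5, 0.3, 0.2)), 1 / 0.38)

  expect_equal(pielou(rep(3, 7)), 1)
  p <- c(0.97, 0.01, 0.01, 0.01)
  expect_equal(pielou(p), -sum(p * log(p)) / log(4))
  expect_equal(round(pielou(p), 5), 0.12097)
  expect_error(pielou(c(1, 0)), "at least 2 species")
  expect_error(shannon(c(0, 0)), "All-zero")
})

test_that("indices are permutation-invariant and agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(21)
  for (i in 1:5) {
    x <- rlnorm(30, 2, 1)
    perm <- sample(x)
    expect_equal(shannon(x), shannon(perm))
    expect_equal(inverse_simpson(x), inverse_simpson(perm))
    expect_equal(pielou(x), pielou(perm))
    expect_equal(shannon(x), vegan::diversity(x, "shannon"))
    expect_equal(inverse_simpson(x), vegan::diversity(x, "invsimpson"))
  }
})

test_that("H <= ln S, DSi <= S and J in [0,1] on random communities", {
  set.seed(33)
  for (i in 1:20) {
    x <- rlnorm(sample(5:50, 1), 1, 1.5)
    s <- length(x)
    expect_lte(shannon(x), log(s) + 1e-12)
    expect_lte(inverse_simpson(x), s + 1e-9)
    j <- pielou(x)
    expect_gte(j, 0)
    expect_lte(j, 1)
    expect_equal(j, shannon(x) / log(s))
  }
})

test_that("richness estimators follow the incidence formulas", {
  # fixture with S=10, Q1=4, Q2=2 across n=5 units:
  # f1-f3 in all units, f4 in three, f5/f6 in two (Q2), f7-f10 unique (Q1)
  pres <- matrix(0L, 5, 10, dimnames = list(NULL, paste0("f", 1:10)))
  pres[, 1:3] <- 1L
  pres[1:3, 4] <- 1L
  pres[1:2, 5] <- 1L
  pres[3:4, 6] <- 1L
  pres[cbind(c(1, 2, 3, 4), 7:10)] <- 1L
  est <- richness_estimators(pres)
  expect_equal(est$S, 10)
  expect_equal(est$Q1, 4)
  expect_equal(est$Q2, 2)
  expect_equal(est$jack1, 13.2)                   # 10 + 4*4/5
  expect_equal(est$chao, 10 + (4 / 5) * 16 / 4)   # 13.2
  expect_equal(est$jack2, 10 + 4 * 7 / 5 - 2 * 9 / 20)

  # no uniques or duplicates: nothing left undetected, all estimators = S
  full <- matrix(1L, 4, 6, dimnames = list(NULL, paste0("f", 1:6)))
  est2 <- richness_estimators(full)
  expect_equal(est2$chao, 6)
  expect_equal(est2$jack1, 6)
  expect_equal(est2$jack2, 6)

  expect_error(richness_estimators(matrix(1, 1, 3)), "at least 2")
})

test_that("estimators never fall below observed richness and match vegan", {
  skip_if_not_installed("vegan")
  set.seed(17)
  for (i in 1:10) {
    pres <- matrix(rbinom(8 * 25, 1, runif(1, 0.15, 0.6)), 8, 25,
                   dimnames = list(NULL, paste0("f", 1:25)))
    pres <- pres[, colSums(pres) > 0, drop = FALSE]
    if (ncol(pres) < 2) next
    est <- richness_estimators(pres)
    expect_gte(est$chao, est$S)
    expect_gte(est$jack1, est$S)
    vp <- vegan::specpool(as.data.frame(pres))
    expect_equal(est$chao, vp$chao, tolerance = 1e-10)
    expect_equal(est$jack1, vp$jack1, tolerance = 1e-10)
    expect_equal(est$jack2, vp$jack2, tolerance = 1e-10)
  }
})

test_that("accumulation curves are monotone and end at observed richness", {
  im <- toy_incidence()
  sac <- species_accumulation(im, n_perm = 50, seed = 4)
  expect_true(all(diff(sac$richness) >= 0))
  expect_equal(sac$richness[nrow(sac)], 5)  # terminal value = S, SD 0
  expect_equal(sac$sd[nrow(sac)], 0)

  # identical units: flat curve at S with zero SD
  same <- matrix(1L, 4, 7, dimnames = list(NULL, paste0("f", 1:7)))
  sac2 <- species_accumulation(same, n_perm = 20, seed = 1)
  expect_equal(sac2$richness, rep(7, 4))
  expect_equal(sac2$sd, rep(0, 4))

  # k = 1 mean equals the average per-unit richness
  expect_equal(sac$richness[1], mean(rowSums(im$presence)))

  # disjoint species sets of size s: curve is exactly k*s
  disj <- matrix(0L, 3, 9, dimnames = list(NULL, paste0("f", 1:9)))
  disj[1, 1:3] <- 1L; disj[2, 4:6] <- 1L; disj[3, 7:9] <- 1L
  sac3 <- species_accumulation(disj, n_perm = 30, seed = 2)
  expect_equal(sac3$richness, c(3, 6, 9))
  expect_equal(sac3$sd, c(0, 0, 0))
})

test_that("accumulation agrees with vegan's random method in expectation", {
  skip_if_not_installed("vegan")
  set.seed(42)
  pres <- matrix(rbinom(6 * 30, 1, 0.3), 6, 30,
                 dimnames = list(NULL, paste0("f", 1:30)))
  sac <- species_accumulation(pres, n_perm = 500, seed = 9)
  vg <- vegan::specaccum(pres, method = "random", permutations = 500)
  se <- sac$sd / sqrt(500) + vg$sd / sqrt(500) + 1e-9
  expect_true(all(abs(sac$richness - vg$richness) <= 4 * se + 0.05))
})

test_that("analytic rarefaction equals exhaustive subset enumeration", {
  set.seed(5)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    pres <- matrix(rbinom(n * 12, 1, 0.4), n, 12,
                   dimnames = list(NULL, paste0("f", 1:12)))
    for (k in 1:n) {
      expect_equal(rarefaction(pres, k), rarefaction_bruteforce(pres, k),
                   tolerance = 1e-12)
    }
  }
  im <- toy_incidence()
  expect_equal(rarefaction(im, 3), 5)                        # k = n gives S
  expect_equal(rarefaction(im, 1), mean(rowSums(im$presence)))
  expect_error(rarefaction(im, 4), "must lie in")
})

test_that("random accumulation converges to analytic rarefaction", {
  set.seed(99)
  pres <- matrix(rbinom(5 * 20, 1, 0.35), 5, 20,
                 dimnames = list(NULL, paste0("f", 1:20)))
  sac <- species_accumulation(pres, n_perm = 1000, seed = 12)
  exact <- rarefaction(pres, sac$k)
  se <- pmax(sac$sd / sqrt(1000), 1e-9)
  expect_true(all(abs(sac$richness - exact) <= 3 * se + 0.02))
})

test_that("bootstrap intervals behave on degenerate and regular input", {
  const <- matrix(1L, 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  ci <- bootstrap_ci(const, function(m) sum(colSums(m) > 0), B = 60, seed = 1)
  expect_equal(unname(ci["lo"]), unname(ci["hi"]))  # constant data, zero width

  expect_error(bootstrap_ci(const, function(m) 1, B = 10), "floor is 50")
  expect_error(bootstrap_ci(const[1, , drop = FALSE], function(m) 1, B = 60),
               "at least 2")

  # interval contains the point estimate for the mean per-unit richness
  set.seed(2)
  pres <- matrix(rbinom(80, 1, 0.5), 8, 10, dimnames = list(NULL, paste0("f", 1:10)))
  stat <- function(m) mean(rowSums(m))
  ci2 <- bootstrap_ci(pres, stat, B = 200, seed = 3)
  expect_lte(ci2["lo"], stat(pres))
  expect_gte(ci2["hi"], stat(pres))
})

test_that("bootstrap Shannon intervals cover the replicate-mean truth", {
  # units are noisy observations of a fixed lognormal community; the CI on
  # H(column means) should cover the noise-free value in most runs
  set.seed(1234)
  base <- rlnorm(40, 1, 1)
  truth <- shannon(base)
  hits <- 0
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    set.seed(10000 + s)
    units <- t(replicate(8, base * rlnorm(40, 0, 0.35)))
    colnames(units) <- paste0("f", 1:40)
    ci <- bootstrap_ci(units, function(m) shannon(colMeans(m)), B = 100,
                       seed = s)
    if (truth >= ci["lo"] && truth <= ci["hi"]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("per-sample index table carries metadata and optional CIs", {
  fm <- toy_feature_matrix()
  idx <- diversity_indices(fm)
  expect_equal(nrow(idx), 4)
  expect_true(all(c("S", "H", "DSi", "J", "concentration") %in% names(idx)))
  expect_equal(idx$S, unname(rowSums(fm$abundance > 0)))

  idx_ci <- diversity_indices(fm, ci = TRUE, B = 60, seed = 2)
  expect_true(all(idx_ci$H_lo <= idx_ci$H_hi))
  expect_error(diversity_indices(fm, ci = TRUE, B = 10), "at least 50")
})
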