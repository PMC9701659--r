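test_that("molecular formulas parse into exact element counts", {
  expect_equal(parse_formula("C16H18O9"), c(C = 16L, H = 18L, O = 9L))
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parse_formula("C8H16N2O3S2"),
               c(C = 8L, H = 16L, N = 2L, O = 3L, S = 2L))
  # subscript markup from table transcriptions is tolerated
  expect_equal(parse_formula("C_16_H_18_O_9_"), c(C = 16L, H = 18L, O = 9L))
  expect_equal(parse_formula("NaCl"), c(Cl = 1L, Na = 1L))
  expect_error(parse_formula("C16H18O9X"), "Unknown element")
  expect_error(parse_formula("c16"), "parse")
  expect_equal(length(parse_formula("")), 0)
})

test_that("monoisotopic masses match independent hand sums", {
  # oracle: sums written out from the isotope table, independent of the
  # packaged constants vector
  expect_equal(monoisotopic_mass("C16H18O9"),
               16 * 12 + 18 * 1.0078250321 + 9 * 15.9949146221,
               tolerance = 1e-4)
  expect_equal(round(monoisotopic_mass("C16H18O9"), 4), 354.0951)
  expect_equal(monoisotopic_mass("C9H11NO2"),
               9 * 12 + 11 * 1.0078250321 + 14.0030740052 + 2 * 15.9949146221,
               tolerance = 1e-4)
  expect_equal(round(monoisotopic_mass("C9H11NO2"), 4), 165.079)
  expect_equal(monoisotopic_mass(""), 0)
  expect_equal(monoisotopic_mass(c(H = 2L, O = 1L)), 18.0105646, tolerance = 1e-6)
})

test_that("adduct m/z arithmetic uses electron-corrected shifts", {
  expect_equal(adduct_mz(354.09508, "[M+Na]+"), 354.09508 + 22.989218)
  expect_equal(round(adduct_mz(monoisotopic_mass("C16H18O9"), "[M+Na]+"), 4),
               377.0843)
  expect_equal(round(adduct_mz(monoisotopic_mass("C9H11NO2"), "[M+H]+"), 4),
               166.0863)
  # negative-mode shifts
  M <- monoisotopic_mass("C16H18O9")
  expect_equal(adduct_mz(M, "[M-H]-"), M - 1.007276)
  expect_equal(adduct_mz(M, "[M+Cl]-"), M + 34.969402)
  expect_equal(adduct_mz(M, "[M+FA-H]-") - adduct_mz(M, "[M-H]-"),
               46.005477, tolerance = 1e-4)  # formic acid neutral mass
  expect_error(adduct_mz(100, "[M+X]+"), "Unknown adduct")
  expect_error(adduct_mz(-1, "[M+H]+"), "> 0")
})

test_that("ppm errors are signed and symmetric around zero", {
  expect_equal(ppm_error(377.0844, 377.0843), 1e6 * 0.0001 / 377.0843)
  expect_equal(ppm_error(100, 100), 0)
  expect_equal(ppm_error(99.9999, 100), -1)
  expect_error(ppm_error(100, 0), "> 0")
})

test_that("printed annotation anchors are arithmetically consistent within 5 ppm", {
  anchors <- tibble::tibble(
    formula = c("C9H11NO2", "C16H18O9", "C28H48O6"),
    adduct = c("[M+H]+", "[M+Na]+", "[M+Na]+"),
    observed = c(166.0865, 377.0844, 503.3366))
  for (i in 1:3) {
    theo <- adduct_mz(monoisotopic_mass(anchors$formula[i]), anchors$adduct[i])
    expect_lte(abs(ppm_error(anchors$observed[i], theo)), 5)
  }
})

test_that("every reference compound matches itself at its own adduct m/z", {
  ref <- read_compound_reference()
  expect_gt(nrow(ref), 40)
  for (add in c("[M+H]+", "[M+Na]+", "[M-H]-", "[M+Cl]-")) {
    mzs <- adduct_mz(ref$monoisotopic_mass, add)
    feats <- tibble::tibble(label = paste0("x", seq_along(mzs)), mz = mzs)
    hits <- match_features(feats, ref, adduct_names = add, tol_ppm = 5)$annotated
    self <- hits |> dplyr::group_by(label) |>
      dplyr::slice_min(abs(ppm), n = 1, with_ties = FALSE) |> dplyr::ungroup()
    expect_equal(nrow(self), nrow(ref))
    expect_true(all(abs(self$ppm) < 1e-9))
  }
})

test_that("feature matching respects the ppm tolerance boundary", {
  ref <- read_compound_reference()
  cga <- ref[ref$kegg_id == "C00852", ]
  theo <- adduct_mz(cga$monoisotopic_mass, "[M+Na]+")
  feats <- tibble::tibble(
    label = c("hit", "edge_in", "edge_out", "far"),
    mz = c(theo, theo * (1 + 4.9e-6), theo * (1 + 5.5e-6), 300))
  res <- match_features(feats, ref, adduct_names = "[M+Na]+", tol_ppm = 5)
  expect_setequal(res$annotated$label[res$annotated$kegg_id == "C00852"],
                  c("hit", "edge_in"))
  expect_true(all(c("edge_out", "far") %in% res$unannotated))
  # zero tolerance keeps only the exact mass
  res0 <- match_features(feats, ref, adduct_names = "[M+Na]+", tol_ppm = 0)
  expect_equal(res0$annotated$label, "hit")
  expect_error(match_features(feats, ref, adduct_names = character(0)),
               "at least one adduct")
})

test_that("hypergeometric enrichment reproduces the enumerated tail", {
  # N=20, m=5, n_sig=8, k=4: tail = [C(5,4)C(15,4) + C(5,5)C(15,3)] / C(20,8)
  universe <- sprintf("C%05d", 1:20)
  pathways <- tibble::tibble(
    pathway_id = "pw1", pathway_name = "toy",
    members = list(universe[1:5]))
  sig <- c(universe[1:4], universe[6:9])  # 4 of the 8 fall in the pathway
  res <- pathway_enrichment(sig, pathways, universe)
  enumerated <- (choose(5, 4) * choose(15, 4) + choose(5, 5) * choose(15, 3)) /
    choose(20, 8)
  expect_equal(res$p_exact, enumerated)
  expect_equal(res$p_exact, 7280 / 125970)
  expect_equal(res$k, 4)

  # k = 0 boundary: upper tail is 1
  sig0 <- universe[6:9]
  res0 <- pathway_enrichment(sig0, pathways, universe)
  expect_equal(res0$p_exact, 1)

  # empty pathways are skipped with a warning
  pw2 <- tibble::tibble(pathway_id = c("a", "b"), pathway_name = c("a", "b"),
                        members = list(universe[1:3], character(0)))
  expect_warning(res2 <- pathway_enrichment(sig, pw2, universe), "skipped")
  expect_equal(nrow(res2), 1)
})

test_that("permutation p converges to the exact tail under uniform annotatability", {
  # features map 1:1 onto compounds, so random feature lists re-annotate to
  # uniform compound draws and the permutation null is hypergeometric
  ref <- read_compound_reference()
  ref <- ref[!duplicated(round(ref$monoisotopic_mass, 3)), ][1:20, ]
  feats <- tibble::tibble(label = paste0("f", 1:20),
                          mz = adduct_mz(ref$monoisotopic_mass, "[M+H]+"))
  pathways <- tibble::tibble(pathway_id = "pw", pathway_name = "pw",
                             members = list(ref$kegg_id[1:5]))
  sig_feats <- feats[c(1:4, 6:9), ]
  ann <- match_features(sig_feats, ref, adduct_names = "[M+H]+")$annotated
  res <- pathway_enrichment(unique(ann$kegg_id), pathways,
                            universe = ref$kegg_id,
                            all_features = feats, marker_size = 8,
                            reference = ref, adduct_names = "[M+H]+",
                            n_perm = 2000, seed = 5)
  se <- sqrt(res$p_exact * (1 - res$p_exact) / 2000)
  expect_lt(abs(res$p_perm - res$p_exact), 4 * se + 0.01)
})

test_that("report tables map pathways to markers in long format", {
  ann <- tibble::tibble(
    label = c("f1", "f2", "f3"),
    kegg_id = c("C00852", "C02947", "C08814"),
    adduct = "[M+H]+", ppm = c(0.5, -1, 2))
  pathways <- read_pathways_gmt()
  enr <- pathway_enrichment(ann$kegg_id, pathways,
                            universe = read_compound_reference()$kegg_id)
  rep <- build_report(ann, enr, pathways)
  # C00852 and C02947 each sit in three bundled pathways, C08814 in one
  expect_equal(nrow(rep$mapping), 7)
  expect_equal(sum(rep$summary$n_hits),
               nrow(dplyr::distinct(rep$mapping, pathway_id, label)))
  # a marker in two pathways appears under both
  expect_gte(sum(rep$mapping$kegg_id == "C00852"), 2)
})
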