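# monoisotopic atomic masses (Da), IUPAC/CODATA values
MONOISOTOPIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163,
  Na = 22.9897692809,
  Cl = 34.96885268
)

#' Parse a molecular formula into element counts
#'
#' Hill-notation-like formulas over C, H, N, O, S, P, Na, Cl (e.g.
#' `"C16H18O9"`).  Unknown element symbols are rejected.
#'
#' @param s Formula string.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C16H18O9")
parse_formula <- function(s) {
  if (length(s) != 1 || !is.character(s)) abort("`s` must be a single string.")
  s <- gsub("[_ ]", "", s)  # tolerate subscript markup like C_16_H_18_O_9_
  if (s == "") return(setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(nchar(tokens)) != nchar(s)) {
    abort(sprintf("Cannot parse formula '%s'.", s))
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elements, names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown element(s) in '%s': %s.", s, paste(unknown, collapse = ", ")))
  }
  out <- tapply(counts, elements, sum)
  setNames(as.integer(out), names(out))
}

#' Monoisotopic mass of a formula
#'
#' @param x Formula string, or named element-count vector from
#'   [parse_formula()].
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C16H18O9")  # 354.0951
monoisotopic_mass <- function(x) {
  counts <- if (is.character(x)) parse_formula(x) else x
  if (length(counts) == 0) return(0)
  sum(MONOISOTOPIC_MASS[names(counts)] * counts)
}

#' Supported adducts and their mass shifts
#'
#' Electron-corrected shifts (Da) for singly charged adducts: the proton
#' mass is 1.007276, the sodium cation adds 22.989218, chloride adds
#' 34.969402, formate adds 44.998201, and water loss subtracts 18.010565.
#'
#' @return A tibble with `adduct`, `mass_shift`, `charge`.
#' @export
adducts <- function() {
  tibble(
    adduct = c("[M+H]+", "[M+Na]+", "[M+H-H2O]+",
               "[M-H]-", "[M+Cl]-", "[M+FA-H]-", "[M-H2O-H]-"),
    mass_shift = c(1.007276, 22.989218, 1.007276 - 18.010565,
                   -1.007276, 34.969402, 44.998201, -1.007276 - 18.010565),
    charge = c(1L, 1L, 1L, -1L, -1L, -1L, -1L)
  )
}

#' Theoretical adduct m/z
#'
#' For the singly charged adducts supported here, the theoretical m/z is
#' the neutral monoisotopic mass plus the adduct's fixed shift.
#'
#' @param M Neutral monoisotopic mass (Da), > 0.
#' @param adduct Adduct name from [adducts()].
#' @return Theoretical m/z.
#' @export
#' @examples
#' adduct_mz(354.09508, "[M+Na]+")  # 377.0843
adduct_mz <- function(M, adduct) {
  if (any(M <= 0)) abort("`M` must be > 0.")
  tab <- adducts()
  i <- match(adduct, tab$adduct)
  if (anyNA(i)) abort(sprintf("Unknown adduct '%s'.", paste(adduct[is.na(i)], collapse = ", ")))
  M + tab$mass_shift[i]
}

#' Signed ppm mass error
#'
#' @param observed,theoretical m/z values; `theoretical > 0`.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) abort("`theoretical` must be > 0.")
  (observed - theoretical) / theoretical * 1e6
}

#' Read a compound reference table
#'
#' TSV with columns `name`, `formula`, `kegg_id`.  The bundled default is
#' transcribed from the printed annotation tables of the source study
#' (phenylpropanoid, brassinosteroid, flavonoid and glucosinolate pathway
#' compounds); monoisotopic masses are recomputed from the formulas.
#'
#' @param path Path to the TSV; default the bundled table.
#' @return A tibble: `name`, `formula`, `kegg_id`, `monoisotopic_mass`.
#' @export
read_compound_reference <- function(path = system.file("extdata", "compounds.tsv",
                                                       package = "ecometab")) {
  ref <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("name", "formula", "kegg_id") %in% names(ref))) {
    abort("Compound reference needs columns name, formula, kegg_id.")
  }
  ref$monoisotopic_mass <- vapply(ref$formula, monoisotopic_mass, numeric(1))
  ref
}

#' Read pathway membership sets (GMT)
#'
#' Standard GMT: one pathway per line, tab-separated
#' `id<TAB>name<TAB>member1<TAB>member2...`.
#'
#' @param path Path to the GMT file; default the bundled pathway sets.
#' @return A tibble: `pathway_id`, `pathway_name`, `members` (list column of
#'   KEGG compound IDs).
#' @export
read_pathways_gmt <- function(path = system.file("extdata", "pathways.gmt",
                                                 package = "ecometab")) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    pathway_id = vapply(parts, `[[`, "", 1L),
    pathway_name = vapply(parts, `[[`, "", 2L),
    members = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Match differential features against a compound reference
#'
#' Every (feature, compound, adduct) combination whose absolute ppm error is
#' within tolerance becomes a candidate annotation; candidates are sorted by
#' |ppm| within feature.  Identification is mass-only (level 3); retention
#' time is carried through but not used for matching.
#'
#' @param features A tibble with columns `label` and `mz` (e.g. a
#'   consolidated marker list joined to the feature table), or a character
#'   vector of m/z_rt labels.
#' @param reference Compound reference from [read_compound_reference()].
#' @param adduct_names Adduct names to try (subset of [adducts()]).
#' @param tol_ppm Tolerance in ppm (default 5).
#' @return A list with `annotated` (tibble: `label`, `mz`, `name`,
#'   `formula`, `kegg_id`, `adduct`, `theoretical_mz`, `ppm`, `level`) and
#'   `unannotated` (labels with no candidate).
#' @export
match_features <- function(features, reference = read_compound_reference(),
                           adduct_names = c("[M+H]+", "[M+Na]+"),
                           tol_ppm = 5) {
  if (length(adduct_names) == 0) abort("Need at least one adduct.")
  if (nrow(reference) == 0) abort("Empty compound reference.")
  if (is.character(features)) features <- parse_feature_id(features)
  if (!all(c("label", "mz") %in% names(features))) {
    abort("`features` needs columns label and mz.")
  }
  theo <- tidyr::expand_grid(
    reference |> select("name", "formula", "kegg_id", "monoisotopic_mass"),
    adduct = adduct_names
  ) |>
    mutate(theoretical_mz = adduct_mz(.data$monoisotopic_mass, .data$adduct))
  cand <- tidyr::expand_grid(
    features |> select("label", "mz") |> distinct(),
    theo
  ) |>
    mutate(ppm = ppm_error(.data$mz, .data$theoretical_mz)) |>
    filter(abs(.data$ppm) <= tol_ppm) |>
    mutate(level = 3L) |>
    arrange(.data$label, abs(.data$ppm)) |>
    select("label", "mz", "name", "formula", "kegg_id", "adduct",
           "theoretical_mz", "ppm", "level")
  list(annotated = cand,
       unannotated = setdiff(features$label, cand$label))
}

#' Pathway over-representation of annotated markers
#'
#' For each pathway with k annotated-marker hits out of m member compounds,
#' with `n_sig` distinct significant compounds and a universe of N
#' annotatable compounds, the exact p-value is the hypergeometric upper tail
#' `P(X >= k)`.  The permutation p-value rebuilds the null the way an m/z
#' based workflow must: `n_perm` random feature lists of the same size as
#' the marker list are drawn from all detected features, re-annotated with
#' [match_features()], and scored; `p_perm` is the (add-one) fraction
#' achieving >= k hits in the pathway.
#'
#' @param tme_ids Character vector of significant KEGG compound IDs (the
#'   annotated markers).
#' @param pathways Pathway sets from [read_pathways_gmt()].
#' @param universe Character vector: all KEGG IDs considered annotatable
#'   (must contain every pathway member counted).
#' @param all_features Optional tibble (`label`, `mz`) of all detected
#'   features; when supplied with `marker_size`, permutation p-values are
#'   computed.
#' @param marker_size Size of the random m/z lists (default: number of
#'   distinct marker labels that produced `tme_ids`; required for
#'   permutation).
#' @param reference,adduct_names,tol_ppm Passed to [match_features()] for
#'   re-annotation.
#' @param n_perm Number of permutations (default 200).
#' @param seed Seed for the permutations.
#' @return An `enrichment_result` tibble: `pathway_id`, `pathway_name`, `k`,
#'   `m`, `n_sig`, `N`, `p_exact`, and `p_perm`/`n_perm` when permutation
#'   was run, sorted by `p_exact`.
#' @export
pathway_enrichment <- function(tme_ids, pathways, universe,
                               all_features = NULL, marker_size = NULL,
                               reference = read_compound_reference(),
                               adduct_names = c("[M+H]+", "[M+Na]+"),
                               tol_ppm = 5, n_perm = 200, seed = 1) {
  tme_ids <- unique(tme_ids)
  if (length(tme_ids) < 1) abort("Need at least one significant compound.")
  universe <- unique(universe)
  n_sig <- sum(tme_ids %in% universe)
  N <- length(universe)
  empty <- lengths(pathways$members) == 0
  if (any(empty)) {
    warn(sprintf("%d empty pathway(s) skipped.", sum(empty)))
    pathways <- pathways[!empty, ]
  }
  res <- pathways |>
    mutate(
      m = vapply(.data$members, function(mm) sum(mm %in% universe), 1L),
      k = vapply(.data$members, function(mm) sum(tme_ids %in% mm), 1L),
      n_sig = n_sig, N = N,
      p_exact = phyper(.data$k - 1, .data$m, N - .data$m, n_sig,
                       lower.tail = FALSE)
    ) |>
    select("pathway_id", "pathway_name", "k", "m", "n_sig", "N", "p_exact")

  if (!is.null(all_features)) {
    size <- marker_size %||% length(tme_ids)
    set.seed(seed)
    labels <- unique(all_features$label)
    perm_hits <- matrix(0L, n_perm, nrow(res))
    for (p in seq_len(n_perm)) {
      draw <- sample(labels, min(size, length(labels)))
      ann <- match_features(all_features[all_features$label %in% draw, ],
                            reference, adduct_names, tol_ppm)$annotated
      ids <- unique(ann$kegg_id)
      perm_hits[p, ] <- vapply(pathways$members,
                               function(mm) sum(ids %in% mm), 1L)
    }
    res$p_perm <- vapply(seq_len(nrow(res)), function(i) {
      (sum(perm_hits[, i] >= res$k[i]) + 1) / (n_perm + 1)
    }, numeric(1))
    res$n_perm <- n_perm
  }
  out <- arrange(res, .data$p_exact)
  structure(out, class = c("enrichment_result", class(out)), seed = seed)
}

#' Long-format pathway-by-marker report
#'
#' One row per (pathway, annotated marker) pair — the layout a chord/Circos
#' rendering consumes — plus per-pathway summary counts.
#'
#' @param annotated The `annotated` tibble from [match_features()].
#' @param enrichment An `enrichment_result` (see [pathway_enrichment()]).
#' @param pathways Pathway sets from [read_pathways_gmt()].
#' @return A list with `mapping` (tibble: `pathway_id`, `pathway_name`,
#'   `label`, `kegg_id`, `adduct`, `ppm`) and `summary` (per-pathway hit
#'   counts joined to the enrichment).
#' @export
build_report <- function(annotated, enrichment, pathways) {
  membership <- pathways |>
    select("pathway_id", "pathway_name", "members") |>
    tidyr::unnest_longer("members", values_to = "kegg_id")
  mapping <- membership |>
    dplyr::inner_join(annotated |> select("label", "kegg_id", "adduct", "ppm"),
                      by = "kegg_id",
                      relationship = "many-to-many") |>
    select("pathway_id", "pathway_name", "label", "kegg_id", "adduct", "ppm")
  summary <- mapping |>
    group_by(.data$pathway_id, .data$pathway_name) |>
    summarise(n_hits = dplyr::n_distinct(.data$label), .groups = "drop") |>
    left_join(as_tibble(enrichment), by = c("pathway_id", "pathway_name"))
  list(mapping = mapping, summary = summary)
}
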