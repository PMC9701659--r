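# small fixtures built in code, shared across test files

toy_feature_matrix <- function() {
  ab <- rbind(
    c(10, 0, 3, 100),
    c(8, 2, 0, 120),
    c(0, 5, 4, 90),
    c(12, 0, 6, 110)
  )
  colnames(ab) <- c("100.1000_1.0", "200.2000_2.0", "300.3000_3.0", "400.4000_4.0")
  rownames(ab) <- paste0("s", 1:4)
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    concentration = c("C27", "C27", "C4", "C4"),
    time = c("T0", "T0", "T0", "T0"),
    replicate = c(1L, 2L, 1L, 2L)
  )
  feature_matrix(ab, meta)
}

# deterministic binary incidence matrix with known Q1/Q2 structure
toy_incidence <- function() {
  pres <- rbind(
    c(1, 1, 0, 1, 0),
    c(1, 0, 1, 1, 0),
    c(1, 1, 0, 0, 1)
  )
  colnames(pres) <- paste0("sp", 1:5)
  rownames(pres) <- paste0("u", 1:3)
  to_incidence(pres, threshold = 0)
}

# exhaustive sample-based rarefaction by subset enumeration (oracle, n <= 8)
rarefaction_bruteforce <- function(pres, k) {
  n <- nrow(pres)
  subsets <- utils::combn(n, k, simplify = FALSE)
  mean(vapply(subsets, function(s) {
    sum(colSums(pres[s, , drop = FALSE]) > 0)
  }, numeric(1)))
}
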