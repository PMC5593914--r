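# Independent brute-force oracles and small fixtures shared across tests.
# These deliberately avoid the package's vectorized code paths.

# Bit-by-bit LBP code: explicit threshold-and-weight evaluation over the
# documented clockwise-from-top-left neighbour order.
oracle_lbp_code <- function(w) {
  vc <- w[2, 2]
  nb <- c(w[1, 1], w[1, 2], w[1, 3], w[2, 3],
          w[3, 3], w[3, 2], w[3, 1], w[2, 1])
  sum(ifelse(nb - vc >= 0, 1, 0) * 2^(0:7))
}

# Window-by-window LBP histogram: loops over every interior cell.
oracle_lbp_histogram <- function(m) {
  counts <- rep(0, 256)
  for (i in 2:(nrow(m) - 1)) {
    for (j in 2:(ncol(m) - 1)) {
      code <- oracle_lbp_code(m[(i - 1):(i + 1), (j - 1):(j + 1)])
      counts[code + 1] <- counts[code + 1] + 1
    }
  }
  counts
}

# Pairwise-counting AUC: concordant positive-negative pairs, ties half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Hand-written 3-residue ASCII PSSM with known scores, including the
# trailing percentage/information columns the parser must discard.
fixture_pssm_lines <- function() {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", c(aa, aa)), collapse = " ")),
    "    1 M    -1  -2  -3  -4   5   0  -2  -3  -2   1   2  -1   8   0  -3  -1  -1  -2  -1   1   0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0  0.30  0.09",
    "    2 K    -1   2   0  -1  -4   1   1  -2  -1  -3  -3   5  -2  -4  -1   0  -1  -3  -2  -3   0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0  0.41  0.12",
    "    3 V     0  -3  -3  -4  -1  -3  -3  -4  -4   3   1  -3   1  -1  -3  -2   0  -3  -1   4   0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0  0.52  0.15",
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1355     0.3179"
  )
}

# The hand-transcribed score matrix of the fixture above.
fixture_pssm_scores <- function() {
  matrix(c(
    -1, -2, -3, -4,  5,  0, -2, -3, -2,  1,  2, -1,  8,  0, -3, -1, -1, -2, -1,  1,
    -1,  2,  0, -1, -4,  1,  1, -2, -1, -3, -3,  5, -2, -4, -1,  0, -1, -3, -2, -3,
     0, -3, -3, -4, -1, -3, -3, -4, -4,  3,  1, -3,  1, -1, -3, -2,  0, -3, -1,  4
  ), nrow = 3, byrow = TRUE)
}

random_pssm_matrix <- function(nr, nc = 20) {
  matrix(sample(-10:12, nr * nc, replace = TRUE), nrow = nr)
}

# Tiny two-class network with hand-chosen descriptors, for assembly tests.
fixture_feature_tables <- function() {
  prot <- dplyr::bind_cols(
    tibble::tibble(protein_id = c("T1", "T2")),
    tibble::as_tibble(matrix(c(rep(0.25, 256), rep(0.5, 256)),
                             nrow = 2, byrow = TRUE,
                             dimnames = list(NULL, sprintf("lbp_%03d", 0:255))))
  )
  drug <- dplyr::bind_cols(
    tibble::tibble(drug_id = c("D1", "D2")),
    tibble::as_tibble(matrix(c(rep(1L, 615), rep(0L, 615)),
                             nrow = 2, byrow = TRUE,
                             dimnames = list(NULL, sprintf("fp_%03d", 1:615))))
  )
  list(prot = prot, drug = drug)
}
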