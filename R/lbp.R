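#' Local binary pattern code of a 3 x 3 window
#'
#' Thresholds the eight neighbours of the centre cell against the centre
#' value and packs the signs into an 8-bit code:
#' \deqn{LBP = \sum_{i=0}^{7} s(v_i - v_c)\,2^i, \quad
#'       s(x) = 1 \text{ if } x \ge 0 \text{ else } 0.}
#' Neighbours are enumerated clockwise starting at the top-left corner, so
#' bit i carries weight 2^i for neighbour positions (in row, col offsets
#' from the centre): (-1,-1), (-1,0), (-1,+1), (0,+1), (+1,+1), (+1,0),
#' (+1,-1), (0,-1). Any fixed ordering gives the same descriptor up to a
#' permutation of histogram bins; this one is frozen so descriptors are
#' comparable across runs. Note `s(0) = 1`: a flat window codes to 255.
#'
#' @param window A 3 x 3 numeric matrix; the centre is `window[2, 2]`.
#' @return Integer in `[0, 255]`.
#' @examples
#' lbp_code(matrix(5, 3, 3))   # flat -> 255
#' @export
lbp_code <- function(window) {
  window <- as.matrix(window)
  stopifnot(identical(dim(window), c(3L, 3L)))
  vc <- window[2L, 2L]
  off <- lbp_neighbor_offsets()
  bits <- vapply(seq_len(8L), function(i) {
    as.integer(window[2L + off[i, 1L], 2L + off[i, 2L]] >= vc)
  }, integer(1))
  sum(bits * 2L^(0:7))
}

# clockwise from top-left; row i holds (drow, dcol) for bit i-1
lbp_neighbor_offsets <- function() {
  matrix(
    c(-1L, -1L,
      -1L,  0L,
      -1L,  1L,
       0L,  1L,
       1L,  1L,
       1L,  0L,
       1L, -1L,
       0L, -1L),
    ncol = 2L, byrow = TRUE
  )
}

#' LBP histogram descriptor of a PSSM
#'
#' Treats the L x 20 PSSM as an image, computes the [lbp_code()] at every
#' interior cell (those with a complete 3 x 3 neighbourhood: rows 2..L-1,
#' columns 2..19), and tallies the codes into 256 bins. Border cells
#' produce no code, so raw counts always sum to `(L - 2) * 18`. By default
#' the histogram is normalized to frequencies so protein length does not
#' dominate descriptor magnitude.
#'
#' LBP codes depend only on the sign of score differences, so the
#' descriptor is invariant to adding any constant to the whole matrix.
#'
#' @param x A [pssm()] object (or a plain numeric matrix with >= 3 rows
#'   and >= 3 columns).
#' @param normalize If `TRUE` (default) bins sum to 1; if `FALSE` bins are
#'   raw interior-cell counts.
#' @return An object of class `lbp_histogram`: list with `protein_id`,
#'   `bins` (length 256, names `lbp_000`...`lbp_255`) and `normalized`.
#' @export
lbp_histogram <- function(x, normalize = TRUE) {
  if (inherits(x, "pssm")) {
    m <- x$scores
    id <- x$protein_id
  } else {
    m <- as.matrix(x)
    id <- "matrix"
  }
  codes <- lbp_code_matrix(m)
  bins <- tabulate(codes + 1L, nbins = 256L)
  if (normalize) bins <- bins / sum(bins)
  names(bins) <- sprintf("lbp_%03d", 0:255)
  structure(
    list(protein_id = id, bins = bins, normalized = normalize),
    class = "lbp_histogram"
  )
}

#' @export
print.lbp_histogram <- function(x, ...) {
  cat(sprintf(
    "<lbp_histogram> %s: 256 bins (%s), top bin %s\n",
    x$protein_id,
    if (x$normalized) "frequencies" else "counts",
    names(x$bins)[which.max(x$bins)]
  ))
  invisible(x)
}

# vectorized LBP over all interior cells; returns integer matrix of codes
lbp_code_matrix <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  if (nr < 3L || nc < 3L) {
    abort(sprintf(
      "LBP descriptor undefined: matrix is %d x %d but a complete 3 x 3 neighbourhood needs at least 3 rows and 3 columns",
      nr, nc
    ))
  }
  ri <- 2:(nr - 1L)
  ci <- 2:(nc - 1L)
  centre <- m[ri, ci, drop = FALSE]
  off <- lbp_neighbor_offsets()
  codes <- matrix(0L, nrow = length(ri), ncol = length(ci))
  for (i in seq_len(8L)) {
    nb <- m[ri + off[i, 1L], ci + off[i, 2L], drop = FALSE]
    codes <- codes + (nb >= centre) * 2L^(i - 1L)
  }
  codes
}

#' Dimension of the LBP protein descriptor
#'
#' The 8-neighbour LBP operator produces 2^8 = 256 distinct codes, so every
#' protein descriptor has exactly 256 components regardless of sequence
#' length.
#'
#' @return `256L`
#' @export
lbp_dim <- function() 256L
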