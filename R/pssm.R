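#' Position-specific scoring matrices
#'
#' A PSSM is the L x 20 integer log-odds profile PSI-BLAST emits for a
#' protein of length L (typically from 3 search iterations at an E-value
#' cutoff of 0.001). Rows are sequence positions, columns the 20 standard
#' amino acids in PSI-BLAST's fixed order. The package treats the matrix as
#' a single-channel image on which the local binary pattern operator runs.
#'
#' @param protein_id Identifier string.
#' @param scores Integer matrix with 20 columns.
#' @return An object of class `pssm`: a list with `protein_id`, `scores`
#'   and `residue_order`.
#' @examples
#' p <- pssm("P1", matrix(0L, nrow = 4, ncol = 20))
#' dim(p$scores)
#' @export
pssm <- function(protein_id, scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 1L || ncol(scores) != 20L) {
    abort(sprintf(
      "PSSM for '%s' must be an L x 20 matrix with L >= 1, got %d x %d",
      protein_id, nrow(scores), ncol(scores)
    ))
  }
  if (any(scores != round(scores))) {
    abort(sprintf("PSSM for '%s' contains non-integer scores", protein_id))
  }
  storage.mode(scores) <- "integer"
  dimnames(scores) <- list(NULL, pssm_residue_order())
  structure(
    list(
      protein_id = as.character(protein_id),
      scores = scores,
      residue_order = pssm_residue_order()
    ),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %s: %d x 20 log-odds matrix\n", x$protein_id, nrow(x$scores)))
  invisible(x)
}

# PSI-BLAST column order for the first 20 score columns.
pssm_residue_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, then one row per
#' sequence position holding the position index, the query residue, 20
#' log-odds scores, and trailing weighted-percentage / information columns.
#' Only the first 20 score columns are kept; everything after them is
#' discarded.
#'
#' @param path Path to an ASCII PSSM file, or a character vector of lines
#'   via `lines`.
#' @param protein_id Identifier for the parsed protein; defaults to the
#'   file name without extension.
#' @param lines Optional character vector of file lines (overrides `path`).
#' @return A [pssm()] object.
#' @export
parse_pssm <- function(path = NULL, protein_id = NULL, lines = NULL) {
  if (is.null(lines)) {
    if (is.null(path)) abort("provide either `path` or `lines`")
    lines <- readLines(path, warn = FALSE)
    if (is.null(protein_id)) {
      protein_id <- sub("\\.[^.]*$", "", basename(path))
    }
  }
  protein_id <- protein_id %||% "protein"

  is_row <- grepl("^\\s*\\d+\\s+[A-Za-z*]\\s", lines)
  rows <- which(is_row)
  if (length(rows) == 0L) {
    abort(sprintf("no PSSM score rows found for '%s'", protein_id))
  }
  # score rows are contiguous; footer statistics never match the row regex
  scores <- matrix(0L, nrow = length(rows), ncol = 20L)
  for (i in seq_along(rows)) {
    ln <- rows[i]
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) < 22L) {
      abort(sprintf(
        "malformed PSSM row at line %d of '%s': expected >= 22 fields, got %d",
        ln, protein_id, length(toks)
      ))
    }
    vals <- suppressWarnings(as.integer(toks[3:22]))
    if (anyNA(vals)) {
      abort(sprintf(
        "malformed PSSM row at line %d of '%s': non-integer score field",
        ln, protein_id
      ))
    }
    scores[i, ] <- vals
  }
  pssm(protein_id, scores)
}

#' Write a PSSM in PSI-BLAST ASCII format
#'
#' Emits the `-out_ascii_pssm` dialect that [parse_pssm()] reads: the two
#' header lines, one row per position with 20 log-odds scores followed by
#' 20 weighted-percentage columns and two trailing statistics, and the
#' footer. Round-trips through [parse_pssm()].
#'
#' @param x A [pssm()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  aa <- x$residue_order
  header <- c(
    "",
    paste(
      "Last position-specific scoring matrix computed, weighted observed",
      "percentages rounded down, information per position, and relative",
      "weight of gapless real matches to pseudocounts"
    ),
    paste0("           ", paste(sprintf("%3s", c(aa, aa)), collapse = " "))
  )
  # residue letter per row: pick the highest-scoring residue as a plausible query
  best <- aa[max.col(x$scores, ties.method = "first")]
  body <- vapply(seq_len(nrow(x$scores)), function(i) {
    paste0(
      sprintf("%5d %s ", i, best[i]),
      paste(sprintf("%3d", x$scores[i, ]), collapse = " "),
      "  ",
      paste(sprintf("%3d", rep(0L, 20L)), collapse = " "),
      sprintf("  %5.2f %9.2f", 0, 0)
    )
  }, character(1))
  footer <- c(
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1355     0.3179",
    "Standard Gapped      0.0410     0.2670",
    ""
  )
  writeLines(c(header, body, footer), path)
  invisible(path)
}

#' Batch-featurize a directory of PSSM files
#'
#' Parses every PSSM file in `pssm_dir` and computes the 256-bin LBP
#' histogram descriptor for each (see [lbp_histogram()]). Unreadable or
#' malformed files are skipped with a message and reported in the
#' `failed` attribute.
#'
#' @param pssm_dir Directory containing ASCII PSSM files.
#' @param pattern Filename pattern, default all `.pssm`/`.txt`/`.mat` files.
#' @param normalize Normalize histograms to frequencies (default `TRUE`).
#' @return A tibble with `protein_id` and 256 descriptor columns
#'   `lbp_000` ... `lbp_255`, one row per successfully parsed file, with a
#'   character attribute `failed` listing files that could not be processed.
#' @export
featurize_proteins <- function(pssm_dir, pattern = "\\.(pssm|txt|mat)$",
                               normalize = TRUE) {
  files <- list.files(pssm_dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L) {
    abort(sprintf("no PSSM files matching '%s' in %s", pattern, pssm_dir))
  }
  failed <- character()
  rows <- list()
  for (f in files) {
    res <- tryCatch(
      lbp_histogram(parse_pssm(f), normalize = normalize),
      error = function(e) {
        message(sprintf("skipping %s: %s", basename(f), conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) failed <- c(failed, f) else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) {
    abort(sprintf("all %d PSSM files in %s failed to featurize", length(files), pssm_dir))
  }
  out <- dplyr::bind_rows(lapply(rows, lbp_as_row))
  attr(out, "failed") <- failed
  out
}

lbp_as_row <- function(h) {
  v <- as.list(h$bins)
  names(v) <- sprintf("lbp_%03d", 0:255)
  tibble::as_tibble(c(list(protein_id = h$protein_id), v))
}
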