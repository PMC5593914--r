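#' Dimension of the drug substructure fingerprint
#'
#' Drug molecules are described by presence/absence bits over a fixed
#' catalogue of 615 common substructures (functional groups and
#' fragments), so every fingerprint has exactly 615 components.
#'
#' @return `615L`
#' @export
fingerprint_dim <- function() 615L

#' Parse one drug fingerprint record
#'
#' A record is `drug_id` plus either a 615-character 0/1 string or a hex
#' string decoding to at least 615 bits (hex is truncated to the first
#' 615 bits, most-significant bit first within each nibble).
#'
#' @param record A single string `"drug_id<TAB>bits"`, or the bits alone
#'   when `drug_id` is given separately.
#' @param drug_id Optional identifier; if missing, the record is split on
#'   whitespace/tab into id and bits.
#' @return An object of class `fingerprint`: list with `drug_id` and
#'   integer `bits` of length 615.
#' @examples
#' fp <- parse_fingerprint(paste0("D1\t", strrep("0", 615)))
#' sum(fp$bits)
#' @export
parse_fingerprint <- function(record, drug_id = NULL) {
  stopifnot(is.character(record), length(record) == 1L)
  if (is.null(drug_id)) {
    toks <- strsplit(trimws(record), "\\s+")[[1]]
    if (length(toks) != 2L) {
      abort("fingerprint record must be 'drug_id<whitespace>bitstring'")
    }
    drug_id <- toks[1L]
    bits_str <- toks[2L]
  } else {
    bits_str <- trimws(record)
  }

  if (grepl("^[01]+$", bits_str)) {
    if (nchar(bits_str) != fingerprint_dim()) {
      abort(sprintf(
        "fingerprint for '%s' has %d bits, expected %d",
        drug_id, nchar(bits_str), fingerprint_dim()
      ))
    }
    bits <- as.integer(strsplit(bits_str, "")[[1]])
  } else if (grepl("^(0[xX])?[0-9a-fA-F]+$", bits_str)) {
    bits_str <- sub("^0[xX]", "", bits_str)
    if (nchar(bits_str) * 4L < fingerprint_dim()) {
      abort(sprintf(
        "hex fingerprint for '%s' decodes to %d bits, need >= %d",
        drug_id, nchar(bits_str) * 4L, fingerprint_dim()
      ))
    }
    nib <- strtoi(strsplit(bits_str, "")[[1]], base = 16L)
    bits <- as.integer(t(outer(nib, c(8L, 4L, 2L, 1L), function(v, w) bitwAnd(v, w) > 0L)))
    bits <- bits[seq_len(fingerprint_dim())]
  } else {
    abort(sprintf("fingerprint for '%s' is neither a 0/1 string nor hex", drug_id))
  }
  structure(list(drug_id = as.character(drug_id), bits = bits),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %s: %d/615 bits set\n", x$drug_id, sum(x$bits)))
  invisible(x)
}

format_fingerprint <- function(x) {
  paste0(x$drug_id, "\t", paste(x$bits, collapse = ""))
}

#' Read a drug fingerprint table
#'
#' Canonical on-disk format: TSV with columns `drug_id` and a 615-character
#' 0/1 string (hex accepted). A header line `drug_id\tbits` is optional.
#'
#' @param path TSV file path.
#' @return Tibble with `drug_id` and bit columns `fp_001` ... `fp_615`.
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("no fingerprint records in %s", path))
  if (grepl("^drug_id\\b", lines[1L])) lines <- lines[-1L]
  fps <- lapply(lines, parse_fingerprint)
  fingerprints_as_tibble(fps)
}

#' Write a drug fingerprint table
#'
#' @param x Tibble with `drug_id` and `fp_*` bit columns (as produced by
#'   [read_fingerprints()] or [simulate_dti()]), or a list of
#'   [parse_fingerprint()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(x, path) {
  if (is.data.frame(x)) {
    bit_cols <- grep("^fp_", names(x), value = TRUE)
    stopifnot(length(bit_cols) == fingerprint_dim())
    lines <- vapply(seq_len(nrow(x)), function(i) {
      paste0(x$drug_id[i], "\t",
             paste(as.integer(x[i, bit_cols]), collapse = ""))
    }, character(1))
  } else {
    lines <- vapply(x, format_fingerprint, character(1))
  }
  writeLines(c("drug_id\tbits", lines), path)
  invisible(path)
}

fingerprints_as_tibble <- function(fps) {
  mat <- do.call(rbind, lapply(fps, `[[`, "bits"))
  colnames(mat) <- sprintf("fp_%03d", seq_len(fingerprint_dim()))
  dplyr::bind_cols(
    tibble::tibble(drug_id = vapply(fps, `[[`, character(1), "drug_id")),
    tibble::as_tibble(mat)
  )
}
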