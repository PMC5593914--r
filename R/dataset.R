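#' Assemble labelled drug-target pair samples
#'
#' Each sample is the protein descriptor followed by the drug fingerprint
#' (raw dimension 256 + 615 = 871), labelled 1 for a known interaction and
#' 0 for a sampled non-edge.
#'
#' @param net An [interaction_network()].
#' @param protein_features Tibble with `protein_id` and descriptor columns
#'   (e.g. from [featurize_proteins()]).
#' @param drug_features Tibble with `drug_id` and fingerprint columns
#'   (e.g. from [read_fingerprints()]).
#' @param negatives Tibble of `(drug_id, target_id)` non-edges, e.g. from
#'   [sample_negatives()].
#' @return Tibble with `drug_id`, `target_id`, `label` (integer 0/1), then
#'   the protein descriptor columns followed by the fingerprint columns.
#' @export
build_pairs <- function(net, protein_features, drug_features, negatives) {
  stopifnot(inherits(net, "interaction_network"))
  pairs <- dplyr::bind_rows(
    dplyr::mutate(net$positive_pairs, label = 1L),
    dplyr::mutate(tibble::as_tibble(negatives)[, c("drug_id", "target_id")],
                  label = 1L * 0L)
  )
  pairs$label <- as.integer(pairs$label)

  miss_t <- setdiff(pairs$target_id, protein_features$protein_id)
  if (length(miss_t)) {
    abort(sprintf("missing protein descriptor for target id(s): %s",
                  paste(head(miss_t, 5L), collapse = ", ")))
  }
  miss_d <- setdiff(pairs$drug_id, drug_features$drug_id)
  if (length(miss_d)) {
    abort(sprintf("missing fingerprint for drug id(s): %s",
                  paste(head(miss_d, 5L), collapse = ", ")))
  }

  prot <- protein_features[match(pairs$target_id, protein_features$protein_id),
                           setdiff(names(protein_features), "protein_id"),
                           drop = FALSE]
  drug <- drug_features[match(pairs$drug_id, drug_features$drug_id),
                        setdiff(names(drug_features), "drug_id"),
                        drop = FALSE]
  dplyr::bind_cols(pairs[, c("drug_id", "target_id", "label")], prot, drug)
}

#' Feature columns of a pair dataset
#'
#' @param pairs A tibble from [build_pairs()].
#' @return Character vector of feature column names (everything except
#'   ids and label).
#' @export
pair_feature_cols <- function(pairs) {
  setdiff(names(pairs), c("drug_id", "target_id", "label"))
}

#' Random fold assignment for cross-validation
#'
#' Partitions `n` samples into `n_folds` folds of sizes differing by at
#' most one, reproducibly under `seed`. With `labels` given, assignment is
#' stratified: each class is shuffled and dealt round-robin so the class
#' ratio is preserved per fold (the dealing position carries across
#' classes, keeping overall fold sizes within one as well).
#'
#' @param n Number of samples.
#' @param n_folds Number of folds, default 5.
#' @param seed Integer seed.
#' @param labels Optional vector of class labels for stratification.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
make_folds <- function(n, n_folds = 5L, seed, labels = NULL) {
  if (n < n_folds) {
    abort(sprintf("cannot split %d samples into %d folds", n, n_folds))
  }
  if (!is.null(labels) && length(labels) != n) {
    abort("labels must have length n")
  }
  withr::with_seed(seed, {
    fold <- integer(n)
    pos <- 0L
    groups <- if (is.null(labels)) list(seq_len(n)) else
      split(seq_len(n), labels)
    for (idx in groups) {
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- (pos + seq_along(idx) - 1L) %% n_folds + 1L
      pos <- pos + length(idx)
    }
    fold
  })
}

#' Write / read an assembled pair dataset
#'
#' TSV with ids, label and feature columns; the exact tibble round-trips.
#'
#' @param pairs Tibble from [build_pairs()].
#' @param path TSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    drug_id = "c", target_id = "c", label = "i", .default = "d"
  ), progress = FALSE)
  tibble::as_tibble(df)
}
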