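#' Bipartite drug-target interaction network
#'
#' Known interactions form a bipartite graph: drugs and targets are nodes,
#' experimentally validated interactions are edges. The non-edges are the
#' candidate pool for negative sampling.
#'
#' @param drugs Character vector of drug ids (the drug node set).
#' @param targets Character vector of target ids (the target node set).
#' @param positive_pairs Data frame with columns `drug_id`, `target_id`;
#'   each row one known interaction. Duplicates are an error.
#' @return Object of class `interaction_network`.
#' @export
interaction_network <- function(drugs, targets, positive_pairs) {
  drugs <- as.character(drugs)
  targets <- as.character(targets)
  if (anyDuplicated(drugs)) abort("duplicate drug ids")
  if (anyDuplicated(targets)) abort("duplicate target ids")
  pp <- tibble::as_tibble(positive_pairs)[, c("drug_id", "target_id")]
  pp$drug_id <- as.character(pp$drug_id)
  pp$target_id <- as.character(pp$target_id)
  bad_d <- setdiff(pp$drug_id, drugs)
  bad_t <- setdiff(pp$target_id, targets)
  if (length(bad_d) || length(bad_t)) {
    abort(sprintf(
      "interaction pairs reference unknown ids: %s",
      paste(head(c(bad_d, bad_t), 5L), collapse = ", ")
    ))
  }
  if (anyDuplicated(paste(pp$drug_id, pp$target_id, sep = "\r"))) {
    abort("duplicate interaction pairs")
  }
  structure(
    list(drugs = drugs, targets = targets, positive_pairs = pp),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "<interaction_network> %d drugs x %d targets, %d known interactions (%d candidate negatives)\n",
    s$n_drugs, s$n_targets, s$n_positive, s$n_negative_pool
  ))
  invisible(x)
}

#' Bipartite accounting of an interaction network
#'
#' @param net An [interaction_network()].
#' @return One-row tibble: `n_drugs`, `n_targets`, `n_positive`,
#'   `n_possible` (all drug x target pairs) and `n_negative_pool`
#'   (non-edges available for negative sampling).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  n_d <- length(net$drugs)
  n_t <- length(net$targets)
  n_pos <- nrow(net$positive_pairs)
  tibble::tibble(
    n_drugs = n_d,
    n_targets = n_t,
    n_positive = n_pos,
    n_possible = n_d * n_t,
    n_negative_pool = n_d * n_t - n_pos
  )
}

#' Read an interaction list
#'
#' Two-column TSV `(drug_id, target_id)`, header optional. Node sets
#' default to the ids appearing in the list; pass `drugs` / `targets`
#' explicitly to include interaction-free nodes.
#'
#' @param path TSV path.
#' @param drugs,targets Optional full node id vectors.
#' @return An [interaction_network()].
#' @export
read_interactions <- function(path, drugs = NULL, targets = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("drug_id", "target_id") %in% names(df))) {
    # headerless: re-read with names
    df <- readr::read_tsv(path, col_names = c("drug_id", "target_id"),
                          col_types = "cc", progress = FALSE)
  }
  interaction_network(
    drugs %||% unique(df$drug_id),
    targets %||% unique(df$target_id),
    df
  )
}

#' Write an interaction list
#' @param net An [interaction_network()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(net, path) {
  readr::write_tsv(net$positive_pairs, path, progress = FALSE)
  invisible(path)
}

#' Sample balanced negatives from the non-edges
#'
#' Class imbalance is severe on real interaction networks (known edges are
#' a tiny fraction of all drug x target pairs), so training sets are
#' balanced by drawing, uniformly at random and without replacement, as
#' many non-interacting pairs as there are known interactions.
#'
#' @param net An [interaction_network()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param n Number of negatives, default `n_positive`.
#' @return Tibble of sampled `(drug_id, target_id)` non-edges.
#' @export
sample_negatives <- function(net, seed, n = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  s <- network_summary(net)
  n <- n %||% s$n_positive
  if (s$n_negative_pool < n) {
    abort(sprintf(
      "cannot sample %d negatives: only %d non-edges exist (%d possible pairs - %d positives)",
      n, s$n_negative_pool, s$n_possible, s$n_positive
    ))
  }
  # linear index over the drug x target grid; drop known edges
  pos_idx <- match(net$positive_pairs$drug_id, net$drugs) +
    (match(net$positive_pairs$target_id, net$targets) - 1L) * s$n_drugs
  pool <- setdiff(seq_len(s$n_possible), pos_idx)
  picked <- withr::with_seed(seed, sample(pool, n))
  tibble::tibble(
    drug_id = net$drugs[(picked - 1L) %% s$n_drugs + 1L],
    target_id = net$targets[(picked - 1L) %/% s$n_drugs + 1L]
  )
}
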