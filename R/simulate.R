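#' Simulate a PSI-BLAST-like PSSM
#'
#' Draws an L x 20 integer matrix with entries in the range typical of
#' PSI-BLAST log-odds scores, [-10, 12]. Row-to-row correlation is added
#' by a small random walk on a per-position baseline so the matrix has
#' local texture rather than pure salt-and-pepper noise. When `path` is
#' given the matrix is also written as an ASCII PSSM file (see
#' [write_pssm()]) so the parser is exercised on simulated data.
#'
#' @param length Protein length L (>= 3).
#' @param seed Integer seed; same seed, same matrix.
#' @param protein_id Identifier, default `"sim"`.
#' @param path Optional output file for the ASCII PSSM.
#' @return A [pssm()] object.
#' @export
simulate_pssm <- function(length, seed, protein_id = "sim", path = NULL) {
  if (length < 3L) abort("simulated PSSM needs length >= 3 (LBP interior)")
  m <- withr::with_seed(seed, {
    base <- cumsum(sample(-2:2, length, replace = TRUE))          # positional drift
    noise <- matrix(sample(-4:4, length * 20L, replace = TRUE), nrow = length)
    round(pmin(pmax(base + noise, -10L), 12L))
  })
  storage.mode(m) <- "integer"
  out <- pssm(protein_id, m)
  if (!is.null(path)) write_pssm(out, path)
  out
}

#' Simulate a drug-target interaction study with plantable signal
#'
#' Block latent-factor generative model, the simplest recoverable form of
#' the premise that similar drugs interact with similar targets. Every
#' drug and every target belongs to one of `latent_dim` latent classes
#' (its latent vector is the one-hot indicator of that class), and a
#' fixed binary affinity table over class pairs - active cells chosen to
#' match the requested `density`, same-class cells first, so interaction
#' propensity increases with the latent inner product - decides which
#' pairs interact. Observable features are noisy functions of the
#' latents:
#'
#' * protein descriptors: a softmax of a fixed random 256 x latent_dim
#'   projection of the target latent plus `noise`-scaled Gaussian
#'   perturbation - histogram-like, non-negative, summing to 1, with the
#'   same columns as [featurize_proteins()];
#' * drug fingerprints: 615 bits, bit j set when a fixed random projection
#'   of the drug latent plus `noise`-scaled Gaussian exceeds 0 -
#'   Bernoulli-like bits whose determinism grows as `noise` shrinks.
#'
#' At `noise = 0` the features are deterministic functions of the latents
#' and the labels are exactly recoverable from the features; at
#' `latent_dim = 0` labels are uniform random pairs independent of all
#' features (a null model). Realised density matches the nominal value
#' only up to the granularity of the class-pair grid.
#'
#' @param n_drugs,n_targets Node counts (>= 1).
#' @param density Fraction of drug x target pairs that interact, in
#'   (0, 1). Default 0.15.
#' @param latent_dim Number of latent classes; 0 gives the no-signal
#'   null. Default 4.
#' @param noise Feature noise standard deviation, default 0.25.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `dti_simulation`: list with `network`
#'   ([interaction_network()]), `protein_features`, `drug_features`
#'   (tibbles), `latents` and `config`.
#' @export
simulate_dti <- function(n_drugs = 30L, n_targets = 25L, density = 0.15,
                         latent_dim = 4L, noise = 0.25, seed = 1L) {
  stopifnot(n_drugs >= 1L, n_targets >= 1L, latent_dim >= 0L, noise >= 0)
  if (density <= 0 || density >= 1) abort("density must be in (0, 1)")
  n_pos_target <- round(density * n_drugs * n_targets)
  if (n_pos_target < 1L) {
    abort(sprintf("density %.3g yields no positive pairs for %d x %d nodes",
                  density, n_drugs, n_targets))
  }
  drugs <- sprintf("D%03d", seq_len(n_drugs))
  targets <- sprintf("T%03d", seq_len(n_targets))

  sim <- withr::with_seed(seed, {
    r <- latent_dim
    if (r > 0L) {
      g_d <- sample.int(r, n_drugs, replace = TRUE)
      g_t <- sample.int(r, n_targets, replace = TRUE)
      U <- diag(r)[g_d, , drop = FALSE]
      V <- diag(r)[g_t, , drop = FALSE]
      # affinity over class pairs: same-class cells first (largest latent
      # inner product), then random off-diagonal cells up to the density
      n_cells <- max(1L, min(r * r, round(density * r * r)))
      diag_cells <- cbind(seq_len(r), seq_len(r))[sample.int(r), , drop = FALSE]
      off <- which(diag(r) == 0, arr.ind = TRUE)
      off <- off[sample.int(nrow(off)), , drop = FALSE]
      cells <- rbind(diag_cells, off)[seq_len(n_cells), , drop = FALSE]
      A <- matrix(0L, r, r)
      A[cells] <- 1L
      pos <- which(A[cbind(rep(g_d, n_targets),
                           rep(g_t, each = n_drugs))] == 1L)
      pos <- cbind((pos - 1L) %% n_drugs + 1L, (pos - 1L) %/% n_drugs + 1L)
    } else {
      g_d <- integer(n_drugs); g_t <- integer(n_targets)
      U <- matrix(0, n_drugs, 0L)
      V <- matrix(0, n_targets, 0L)
      idx <- sample(n_drugs * n_targets, n_pos_target)
      pos <- cbind((idx - 1L) %% n_drugs + 1L, (idx - 1L) %/% n_drugs + 1L)
    }
    if (nrow(pos) == 0L || nrow(pos) == n_drugs * n_targets) {
      abort(sprintf(
        "density %.3g with %d latent classes gives a degenerate network (%d of %d pairs positive)",
        density, r, nrow(pos), n_drugs * n_targets
      ))
    }

    proj_t <- matrix(rnorm(256L * max(r, 1L)), nrow = 256L)
    proj_d <- matrix(rnorm(615L * max(r, 1L)), nrow = 615L)

    lin_t <- if (r > 0L) proj_t[, seq_len(r), drop = FALSE] %*% t(V) else
      matrix(0, 256L, n_targets)
    lin_t <- lin_t + noise * matrix(rnorm(256L * n_targets), nrow = 256L)
    hist_t <- apply(lin_t, 2L, function(v) { e <- exp(v - max(v)); e / sum(e) })

    lin_d <- if (r > 0L) proj_d[, seq_len(r), drop = FALSE] %*% t(U) else
      matrix(0, 615L, n_drugs)
    lin_d <- lin_d + noise * matrix(rnorm(615L * n_drugs), nrow = 615L)
    bits <- 1L * (lin_d > 0)

    list(pos = pos, U = U, V = V, hist_t = hist_t, bits = bits)
  })

  net <- interaction_network(
    drugs, targets,
    tibble::tibble(drug_id = drugs[sim$pos[, 1L]],
                   target_id = targets[sim$pos[, 2L]])
  )

  ph <- t(sim$hist_t)
  colnames(ph) <- sprintf("lbp_%03d", 0:255)
  protein_features <- dplyr::bind_cols(
    tibble::tibble(protein_id = targets), tibble::as_tibble(ph)
  )
  fb <- t(sim$bits)
  colnames(fb) <- sprintf("fp_%03d", seq_len(615L))
  drug_features <- dplyr::bind_cols(
    tibble::tibble(drug_id = drugs), tibble::as_tibble(fb)
  )

  structure(
    list(
      network = net,
      protein_features = protein_features,
      drug_features = drug_features,
      latents = list(drugs = sim$U, targets = sim$V),
      config = list(n_drugs = as.integer(n_drugs),
                    n_targets = as.integer(n_targets),
                    density = density, latent_dim = as.integer(latent_dim),
                    noise = noise, seed = as.integer(seed))
    ),
    class = "dti_simulation"
  )
}

#' @export
print.dti_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<dti_simulation> %d drugs x %d targets, %d interactions (latent_dim %d, noise %g, seed %d)\n",
    cfg$n_drugs, cfg$n_targets, nrow(x$network$positive_pairs),
    cfg$latent_dim, cfg$noise, cfg$seed
  ))
  invisible(x)
}

#' Build the balanced pair dataset of a simulated study
#'
#' Convenience wrapper: samples negatives matching the positives and
#' assembles the labelled pair tibble.
#'
#' @param sim A [simulate_dti()] result.
#' @param seed Seed for negative sampling; defaults to the simulation
#'   seed + 1.
#' @return Pair tibble as from [build_pairs()].
#' @export
simulated_pairs <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "dti_simulation"))
  seed <- seed %||% (sim$config$seed + 1L)
  negs <- sample_negatives(sim$network, seed = seed)
  build_pairs(sim$network, sim$protein_features, sim$drug_features, negs)
}

#' Write a simulated study in the pipeline's file formats
#'
#' Emits `interactions.tsv`, `fingerprints.tsv` and
#' `protein_descriptors.tsv` into `dir` - the same formats the real
#' pipeline reads, so simulated and real inputs are interchangeable. With
#' `pssms = TRUE` an ASCII PSSM file is also written per target (under
#' `dir/pssm/`) to exercise the parser; these matrices are simulated
#' texture and do not carry the latent descriptor signal.
#'
#' @param sim A [simulate_dti()] result.
#' @param dir Output directory.
#' @param pssms Also write per-target ASCII PSSM files.
#' @param protein_length Length range for the optional PSSMs.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, pssms = FALSE,
                             protein_length = c(60L, 120L)) {
  stopifnot(inherits(sim, "dti_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactions(sim$network, file.path(dir, "interactions.tsv"))
  write_fingerprints(sim$drug_features, file.path(dir, "fingerprints.tsv"))
  readr::write_tsv(sim$protein_features,
                   file.path(dir, "protein_descriptors.tsv"),
                   progress = FALSE)
  if (pssms) {
    pd <- file.path(dir, "pssm")
    dir.create(pd, showWarnings = FALSE)
    lens <- withr::with_seed(
      sim$config$seed,
      sample(protein_length[1L]:protein_length[2L],
             length(sim$network$targets), replace = TRUE)
    )
    for (i in seq_along(sim$network$targets)) {
      id <- sim$network$targets[i]
      simulate_pssm(lens[i], seed = sim$config$seed + i, protein_id = id,
                    path = file.path(pd, paste0(id, ".pssm")))
    }
  }
  invisible(dir)
}
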