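#' Min-max scaling to [0, 1]
#'
#' Learns per-feature minimum and maximum on the training matrix only.
#' Transformed training features lie in [0, 1]; features that are constant
#' in training map to 0; out-of-range values in new data (e.g. a test
#' fold) are clipped into [0, 1] so downstream cosine similarities stay
#' non-negative.
#'
#' @param x Numeric matrix or data frame of training samples (rows).
#' @return Object of class `range_scaler`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L) abort("cannot fit scaler on an empty matrix")
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  structure(list(min = mins, max = maxs), class = "range_scaler")
}

#' @param scaler A fitted `range_scaler`.
#' @param clip Clip transformed values into [0, 1] (default `TRUE`).
#' @rdname fit_scaler
#' @export
apply_scaler <- function(scaler, x, clip = TRUE) {
  stopifnot(inherits(scaler, "range_scaler"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$min)) {
    abort(sprintf("scaler expects %d features, got %d", length(scaler$min), ncol(x)))
  }
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2L, scaler$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], "/")
  out[, !nz] <- 0
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Invert a min-max transform
#'
#' Only exact for values that were not clipped.
#'
#' @rdname fit_scaler
#' @export
invert_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "range_scaler"))
  x <- as.matrix(x)
  rng <- scaler$max - scaler$min
  sweep(sweep(x, 2L, rng, "*"), 2L, scaler$min, "+")
}

#' Principal component reduction of pair vectors
#'
#' Fits PCA (via [stats::prcomp()]) on the training matrix only and keeps
#' either the smallest number of components reaching `variance_target`, or
#' a fixed `dim`. Components are orthonormal; projections of the training
#' data are uncorrelated with non-increasing variances.
#'
#' @param x Training matrix (rows = samples).
#' @param variance_target Fraction of total variance to retain, in (0, 1].
#'   Default 0.95.
#' @param dim Optional fixed output dimension (overrides
#'   `variance_target`).
#' @return Object of class `pca_model` with `mean`, `rotation` (columns =
#'   components), `sdev` (all component standard deviations) and `dim`.
#' @export
fit_pca <- function(x, variance_target = 0.95, dim = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort("PCA needs at least 2 training rows")
  if (is.null(dim)) {
    if (!is.numeric(variance_target) || variance_target <= 0 || variance_target > 1) {
      abort("variance_target must be in (0, 1]")
    }
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  if (is.null(dim)) {
    total <- sum(ev)
    if (total == 0) {
      dim <- 1L  # degenerate constant data
    } else {
      dim <- which(cumsum(ev) / total >= variance_target - 1e-12)[1L]
    }
  }
  dim <- min(as.integer(dim), ncol(p$rotation))
  structure(
    list(mean = p$center, rotation = p$rotation[, seq_len(dim), drop = FALSE],
         sdev = p$sdev, dim = dim),
    class = "pca_model"
  )
}

#' @param model A fitted `pca_model`.
#' @rdname fit_pca
#' @export
apply_pca <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean)) {
    abort(sprintf("PCA expects %d features, got %d", length(model$mean), ncol(x)))
  }
  sweep(x, 2L, model$mean, "-") %*% model$rotation
}

#' Persist / restore fitted preprocessing
#'
#' Scaler and PCA are stored as versioned JSON so that a saved model
#' reproduces its predictions exactly.
#'
#' @param scaler A `range_scaler`.
#' @param pca A `pca_model` (or `NULL`).
#' @param path JSON file path.
#' @return `path` (write) / a list `list(scaler, pca)` (read).
#' @export
write_preprocessor <- function(scaler, pca, path) {
  obj <- list(
    format = "dvmdti-preprocessor",
    version = 1L,
    scaler = list(min = unname(scaler$min), max = unname(scaler$max)),
    pca = if (!is.null(pca)) list(
      mean = unname(pca$mean),
      rotation = unname(pca$rotation),
      sdev = unname(pca$sdev),
      dim = pca$dim
    )
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_preprocessor
#' @export
read_preprocessor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dvmdti-preprocessor")) {
    abort(sprintf("%s is not a dvmdti preprocessor file", path))
  }
  scaler <- structure(list(min = obj$scaler$min, max = obj$scaler$max),
                      class = "range_scaler")
  pca <- NULL
  if (length(obj$pca) > 0L) {
    pca <- structure(
      list(mean = obj$pca$mean, rotation = as.matrix(obj$pca$rotation),
           sdev = obj$pca$sdev, dim = as.integer(obj$pca$dim)),
      class = "pca_model"
    )
  }
  list(scaler = scaler, pca = pca)
}
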