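#' Five-fold cross-validation of the DVM pipeline
#'
#' For each fold: fit the min-max scaler and PCA on the training portion
#' only, transform both portions (test values clipped to \[0, 1\]),
#' re-scale the PCA projections to \[0, 1\] (so the DVM's cosine-graph
#' regulariser sees non-negative inputs), train the DVM on the training
#' samples and classify the held-out samples. Per-fold precision,
#' sensitivity, accuracy, MCC and AUC are reported together with their
#' across-fold mean and sample standard deviation (n - 1), the layout
#' used for this family of DTI benchmarks.
#'
#' @param pairs Pair dataset from [build_pairs()] (columns `drug_id`,
#'   `target_id`, `label`, features). A plain matrix plus `labels` also
#'   works via [cross_validate_xy()].
#' @param n_folds Number of folds, default 5.
#' @param seed Integer seed driving the fold split (the only source of
#'   randomness).
#' @param variance_target PCA variance fraction to retain, default 0.95.
#' @param pca_dim Optional fixed PCA dimension (overrides
#'   `variance_target`). `NA` disables PCA.
#' @param stratified Stratify folds by label (default `TRUE`), preserving
#'   the 1:1 class balance per fold.
#' @param k,delta,gamma,theta,max_iter,tol DVM hyperparameters, see
#'   [dvm()].
#' @return Object of class `dvm_cv`: list with `fold_metrics` (tibble,
#'   one row per fold), `summary` (mean and sd per metric), `predictions`
#'   (per-sample tibble with fold, label, `.pred`, `.score`), `curves`
#'   (per-fold ROC tibbles), and `config`.
#' @export
cross_validate <- function(pairs, n_folds = 5L, seed = 1L,
                           variance_target = 0.95, pca_dim = NULL,
                           stratified = TRUE, k = NULL, delta = 1e-3,
                           gamma = 1e-4, theta = 1, max_iter = 50L,
                           tol = 1e-6) {
  feat_cols <- pair_feature_cols(pairs)
  x <- as.matrix(pairs[, feat_cols])
  meta <- pairs[, intersect(c("drug_id", "target_id", "label"), names(pairs))]
  cross_validate_xy(
    x, pairs$label, meta = meta, n_folds = n_folds, seed = seed,
    variance_target = variance_target, pca_dim = pca_dim,
    stratified = stratified, k = k, delta = delta, gamma = gamma,
    theta = theta, max_iter = max_iter, tol = tol
  )
}

#' @param x Feature matrix (rows = samples).
#' @param labels 0/1 labels.
#' @param meta Optional tibble of per-sample metadata carried into
#'   `predictions`.
#' @rdname cross_validate
#' @export
cross_validate_xy <- function(x, labels, meta = NULL, n_folds = 5L,
                              seed = 1L, variance_target = 0.95,
                              pca_dim = NULL, stratified = TRUE, k = NULL,
                              delta = 1e-3, gamma = 1e-4, theta = 1,
                              max_iter = 50L, tol = 1e-6) {
  x <- as.matrix(x)
  labels <- as.integer(as.character(labels))
  n <- nrow(x)
  fold <- make_folds(n, n_folds = n_folds, seed = seed,
                     labels = if (stratified) labels else NULL)
  if (!stratified) {
    per_fold <- table(fold, labels)
    if (any(per_fold == 0L)) {
      abort("a fold contains a single class; use stratified = TRUE or a different seed")
    }
  }

  fold_rows <- list()
  pred_rows <- list()
  curves <- list()
  for (f in sort(unique(fold))) {
    tr <- fold != f
    te <- !tr

    scaler <- fit_scaler(x[tr, , drop = FALSE])
    xtr <- apply_scaler(scaler, x[tr, , drop = FALSE])
    xte <- apply_scaler(scaler, x[te, , drop = FALSE])

    if (!(length(pca_dim) == 1L && is.na(pca_dim))) {
      pca <- fit_pca(xtr, variance_target = variance_target, dim = pca_dim)
      xtr <- apply_pca(pca, xtr)
      xte <- apply_pca(pca, xte)
      post <- fit_scaler(xtr)
      xtr <- apply_scaler(post, xtr)
      xte <- apply_scaler(post, xte)
    }

    model <- dvm(xtr, labels[tr], k = k, delta = delta, gamma = gamma,
                 theta = theta, max_iter = max_iter, tol = tol)
    pred <- predict(model, xte)

    cc <- confusion_counts(labels[te], pred$.pred)
    roc <- roc_auc(pred$.score, labels[te])
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, n_test = sum(te)),
      classification_metrics(cc), cc,
      tibble::tibble(auc = roc$auc)
    )
    curves[[f]] <- dplyr::mutate(roc$curve, fold = f, .before = 1L)
    pr <- tibble::tibble(fold = f, label = labels[te],
                         .pred = as.integer(pred$.pred),
                         .score = pred$.score)
    if (!is.null(meta)) pr <- dplyr::bind_cols(meta[te, , drop = FALSE],
                                               pr[setdiff(names(pr), names(meta))])
    pred_rows[[f]] <- pr
  }

  fold_metrics <- dplyr::bind_rows(fold_rows)
  metric_cols <- c("pre", "sen", "acc", "mcc", "auc")
  if (anyNA(fold_metrics[metric_cols])) {
    warn("some per-fold metrics are undefined; they are excluded from the mean/sd summary")
  }
  summary <- tidyr::pivot_longer(fold_metrics[, c("fold", metric_cols)],
                                 -"fold", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metric, metric_cols))

  structure(
    list(
      fold_metrics = fold_metrics,
      summary = summary,
      predictions = dplyr::bind_rows(pred_rows),
      curves = dplyr::bind_rows(curves),
      config = list(
        n_folds = as.integer(n_folds), seed = as.integer(seed),
        variance_target = variance_target,
        pca_dim = if (is.null(pca_dim)) NULL else as.integer(pca_dim),
        stratified = stratified,
        k = if (is.null(k)) NULL else as.integer(k),
        delta = delta, gamma = gamma, theta = theta,
        max_iter = as.integer(max_iter), tol = tol,
        n_samples = n, n_features = ncol(x)
      )
    ),
    class = "dvm_cv"
  )
}

#' @export
print.dvm_cv <- function(x, ...) {
  cat(sprintf("<dvm_cv> %d-fold cross-validation, %d samples, seed %d\n",
              x$config$n_folds, x$config$n_samples, x$config$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %6.2f%% +/- %.2f%%\n", s$metric[i],
                100 * s$mean[i], 100 * s$sd[i]))
  }
  invisible(x)
}

#' @method tidy dvm_cv
#' @export
tidy.dvm_cv <- function(x, ...) x$fold_metrics

#' @method glance dvm_cv
#' @export
glance.dvm_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"),
                             names_glue = "{metric}_{.value}")
  dplyr::bind_cols(wide, tibble::tibble(
    n_folds = x$config$n_folds, n_samples = x$config$n_samples,
    seed = x$config$seed
  ))
}

#' Write a cross-validation report
#'
#' Emits `fold_metrics.tsv`, `summary.tsv` and `report.json` (config,
#' seed and all metrics) into `dir`. Identical config and seed reproduce
#' the files byte-for-byte.
#'
#' @param x A `dvm_cv` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(x, dir) {
  stopifnot(inherits(x, "dvm_cv"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(x$fold_metrics, file.path(dir, "fold_metrics.tsv"),
                   progress = FALSE)
  readr::write_tsv(x$summary, file.path(dir, "summary.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(config = x$config, summary = x$summary,
         fold_metrics = x$fold_metrics),
    file.path(dir, "report.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Plot per-fold ROC curves of a cross-validation run
#'
#' @param object A `dvm_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dvm_cv
#' @export
autoplot.dvm_cv <- function(object, ...) {
  lab <- sprintf("mean AUC = %.3f",
                 object$summary$mean[object$summary$metric == "auc"])
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = factor(.data$fold))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Fold", title = "DVM cross-validation ROC",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}
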