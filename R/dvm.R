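#' Discriminative vector machine
#'
#' A DVM classifies a test vector y by reconstructing it as a linear
#' combination of its k nearest training neighbours and assigning the
#' class whose own neighbours reconstruct y with the smallest residual.
#' The reconstruction coefficients beta minimise a robust objective
#'
#' \deqn{\sum_i \phi((y - X_k\beta)_i) + \delta\|\beta\|_2^2 +
#'       \gamma \beta^\top L \beta}
#'
#' where phi is the Welsch M-estimator (down-weighting outlying residual
#' components), L = D - W is the graph Laplacian of the cosine-similarity
#' graph over the k neighbours (manifold regularisation: similar
#' neighbours receive similar coefficients), and delta is a ridge penalty
#' that also guarantees invertibility. The objective is minimised by
#' half-quadratic iteration: with the Welsch weights frozen in a diagonal
#' matrix P, beta has the closed form
#' `(X_k' P X_k + delta I + gamma L)^{-1} X_k' P y`, and P is then
#' refreshed from the new residual.
#'
#' Training is lazy (the model stores the training matrix and labels);
#' all computation happens in [predict.dvm()].
#'
#' @param x Numeric matrix or data frame of training samples (rows =
#'   samples). The manifold regulariser assumes non-negative features;
#'   scale inputs to \[0, 1\] first (see [fit_scaler()]).
#' @param labels Vector of class labels, length `nrow(x)`. For DTI work
#'   use 0 = non-interacting, 1 = interacting.
#' @param k Neighbour count; default `min(n_train, 200)`. Performance is
#'   flat in k over a wide range.
#' @param delta Ridge penalty weight, default `1e-3`.
#' @param gamma Manifold-regularisation weight, default `1e-4`.
#' @param theta Kernel-size constant of the Welsch weight, default `1`.
#' @param max_iter Maximum half-quadratic iterations, default 50. Set to 1
#'   for a single weighted-least-squares pass.
#' @param tol Convergence tolerance on `max |delta beta|`, default `1e-6`.
#' @return Object of class `dvm`.
#' @export
dvm <- function(x, labels, k = NULL, delta = 1e-3, gamma = 1e-4,
                theta = 1, max_iter = 50L, tol = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (length(labels) != n) abort("labels must match nrow(x)")
  if (n < 1L) abort("need at least one training sample")
  lv <- sort(unique(as.character(labels)))
  if (length(lv) < 2L) abort("need at least two classes")
  cls <- match(as.character(labels), lv)
  k <- as.integer(k %||% min(n, 200L))
  if (k < 1L || k > n) {
    abort(sprintf("k must be in [1, %d], got %d", n, k))
  }
  stopifnot(delta >= 0, gamma >= 0, theta > 0, max_iter >= 1L, tol > 0)
  if (any(x < 0)) {
    warn("training features contain negative values; cosine similarities in the manifold regulariser may be negative",
         .frequency = "once", .frequency_id = "dvm_negative_features")
  }
  structure(
    list(
      xt = t(x),            # d x n, columns = samples
      classes = cls,        # integer class index per column
      levels = lv,
      params = list(k = k, delta = delta, gamma = gamma, theta = theta,
                    max_iter = as.integer(max_iter), tol = tol)
    ),
    class = "dvm"
  )
}

#' @export
print.dvm <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<dvm> %d training samples, %d features, classes {%s}\n  k = %d, delta = %g, gamma = %g, theta = %g\n",
    ncol(x$xt), nrow(x$xt), paste(x$levels, collapse = ", "),
    p$k, p$delta, p$gamma, p$theta
  ))
  invisible(x)
}

#' k nearest training neighbours of a test vector
#'
#' Euclidean distance; ties broken by training sample order.
#'
#' @param model A [dvm()] model.
#' @param y Numeric test vector of the model's feature dimension.
#' @param k Neighbour count, default the model's `k`.
#' @return List with `X_k` (d x k matrix, columns in increasing distance),
#'   `classes` (class index per column) and `index` (training column ids).
#' @export
dvm_neighbors <- function(model, y, k = NULL) {
  stopifnot(inherits(model, "dvm"))
  k <- as.integer(k %||% model$params$k)
  n <- ncol(model$xt)
  if (k > n) abort(sprintf("k = %d exceeds the %d training samples", k, n))
  if (length(y) != nrow(model$xt)) {
    abort(sprintf("y has length %d, model expects %d", length(y), nrow(model$xt)))
  }
  d2 <- colSums((model$xt - y)^2)
  idx <- order(d2, seq_len(n))[seq_len(k)]
  list(X_k = model$xt[, idx, drop = FALSE],
       classes = model$classes[idx],
       index = idx)
}

#' Cosine-similarity graph Laplacian over the neighbour set
#'
#' `w_pq` is the cosine similarity of neighbours p and q; for non-negative
#' inputs `w_pq` lies in \[0, 1\]. A zero-norm neighbour has all its
#' similarities set to 0 (degenerate rule). `D` is diagonal with row sums
#' of `W`; `L = D - W`, so every row of `L` sums to zero and L is positive
#' semidefinite.
#'
#' @param X_k d x k matrix of neighbours (columns).
#' @return List `W`, `D`, `L` (k x k matrices).
#' @export
dvm_laplacian <- function(X_k) {
  X_k <- as.matrix(X_k)
  if (ncol(X_k) == 0L) abort("empty neighbour matrix")
  nrm <- sqrt(colSums(X_k^2))
  U <- X_k
  nz <- nrm > 0
  U[, nz] <- sweep(X_k[, nz, drop = FALSE], 2L, nrm[nz], "/")
  U[, !nz] <- 0
  W <- crossprod(U)
  W <- (W + t(W)) / 2   # enforce exact symmetry
  D <- diag(rowSums(W), nrow = nrow(W))
  list(W = W, D = D, L = D - W)
}

#' Welsch reweighting step
#'
#' From the current residual `r = y - X_k beta`, the kernel size is
#' `sigma = sqrt(theta * r'r / d)` and the diagonal weights are
#' `p_i = exp(-r_i^2 / sigma^2)`: components with larger residuals get
#' strictly smaller weight, which is what makes the fit robust to
#' outliers. A zero residual (perfect fit) is the limit `P = I`.
#'
#' @param y Test vector.
#' @param X_k Neighbour matrix (d x k).
#' @param beta Current coefficient vector (length k).
#' @param theta Kernel-size constant.
#' @return List with `sigma` and `p` (length-d weight vector).
#' @export
dvm_reweight <- function(y, X_k, beta, theta = 1) {
  r <- as.numeric(y - X_k %*% beta)
  d <- length(y)
  sigma <- sqrt(theta * sum(r^2) / d)
  p <- if (sigma == 0) rep(1, d) else exp(-(r^2) / sigma^2)
  list(sigma = sigma, p = p)
}

#' Closed-form half-quadratic update for beta
#'
#' Solves `(X_k' P X_k + delta I + gamma L) beta = X_k' P y` exactly.
#' With `delta > 0` the system is symmetric positive definite.
#'
#' @param y Test vector.
#' @param X_k Neighbour matrix (d x k).
#' @param p Diagonal of the weight matrix P (length d).
#' @param delta Ridge weight.
#' @param gamma Manifold weight.
#' @param L k x k graph Laplacian.
#' @return Coefficient vector beta (length k).
#' @export
dvm_solve_beta <- function(y, X_k, p, delta, gamma, L) {
  k <- ncol(X_k)
  XP <- t(X_k * p)                 # k x d, rows scaled by p
  A <- XP %*% X_k + delta * diag(k) + gamma * L
  b <- XP %*% y
  beta <- tryCatch(
    solve(A, b),
    error = function(e) {
      abort(sprintf(
        "half-quadratic system is singular (%s); set delta > 0 to regularise",
        conditionMessage(e)
      ))
    }
  )
  as.numeric(beta)
}

# quadratic surrogate value at beta for fixed weights p
dvm_surrogate <- function(y, X_k, beta, p, delta, gamma, L) {
  r <- as.numeric(y - X_k %*% beta)
  sum(p * r^2) + delta * sum(beta^2) + gamma * as.numeric(crossprod(beta, L %*% beta))
}

# full half-quadratic loop for one test vector over a fixed neighbour set
dvm_hq <- function(y, X_k, params, L = NULL, trace = FALSE) {
  d <- length(y)
  L <- L %||% dvm_laplacian(X_k)$L
  p <- rep(1, d)                       # initial pass: P = I
  beta <- dvm_solve_beta(y, X_k, p, params$delta, params$gamma, L)
  tr <- if (trace) list(list(
    iter = 1L, sigma = NA_real_,
    obj_pre = dvm_surrogate(y, X_k, numeric(ncol(X_k)), p, params$delta, params$gamma, L),
    obj_post = dvm_surrogate(y, X_k, beta, p, params$delta, params$gamma, L),
    max_delta_beta = max(abs(beta))
  )) else NULL
  iter <- 1L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    rw <- dvm_reweight(y, X_k, beta, params$theta)
    beta_new <- dvm_solve_beta(y, X_k, rw$p, params$delta, params$gamma, L)
    if (trace) {
      tr[[iter]] <- list(
        iter = iter, sigma = rw$sigma,
        obj_pre = dvm_surrogate(y, X_k, beta, rw$p, params$delta, params$gamma, L),
        obj_post = dvm_surrogate(y, X_k, beta_new, rw$p, params$delta, params$gamma, L),
        max_delta_beta = max(abs(beta_new - beta))
      )
    }
    done <- max(abs(beta_new - beta)) < params$tol
    beta <- beta_new
    if (done) break
  }
  list(beta = beta, iterations = iter,
       trace = if (trace) dplyr::bind_rows(tr) else NULL)
}

#' Classify one test vector with a DVM
#'
#' Runs the half-quadratic loop on the k nearest neighbours of `y`, then
#' computes the per-class reconstruction residual
#' `R_i = || y - X_{k,i} beta_i ||` using only the class-i neighbours and
#' their coefficients. The predicted class minimises the residual; exact
#' ties go to the first class level. The continuous score is
#' `R_1 - R_2` (first level minus second), so for 0/1 labels a larger
#' score means more likely interacting.
#'
#' If a class contributes no neighbours its residual is `||y||` (empty
#' reconstruction) and a warning is raised.
#'
#' @param model A [dvm()] model.
#' @param y Test vector.
#' @param trace Keep the per-iteration objective trace.
#' @return List of class `dvm_decision`: `pred` (class level), `residuals`
#'   (named per level), `score`, `beta`, `neighbors`, `iterations`, and
#'   optionally `trace`.
#' @export
dvm_classify <- function(model, y, trace = FALSE) {
  stopifnot(inherits(model, "dvm"))
  nb <- dvm_neighbors(model, y)
  fit <- dvm_hq(y, nb$X_k, model$params, trace = trace)
  res <- vapply(seq_along(model$levels), function(ci) {
    sel <- nb$classes == ci
    if (!any(sel)) {
      warn(sprintf(
        "class '%s' absent from the %d nearest neighbours; residual falls back to ||y||",
        model$levels[ci], model$params$k
      ))
      return(sqrt(sum(y^2)))
    }
    sqrt(sum((y - nb$X_k[, sel, drop = FALSE] %*% fit$beta[sel])^2))
  }, numeric(1))
  names(res) <- model$levels
  pred <- model$levels[which.min(res)]   # ties -> first level
  score <- if (length(res) == 2L) unname(res[1L] - res[2L]) else NA_real_
  structure(
    list(pred = pred, residuals = res, score = score, beta = fit$beta,
         neighbors = nb$index, iterations = fit$iterations,
         trace = fit$trace),
    class = "dvm_decision"
  )
}

#' @export
print.dvm_decision <- function(x, ...) {
  cat(sprintf("<dvm_decision> class %s (residuals: %s)\n", x$pred,
              paste(sprintf("%s = %.4g", names(x$residuals), x$residuals),
                    collapse = ", ")))
  invisible(x)
}

#' Predict drug-target interaction labels for new samples
#'
#' @param object A [dvm()] model.
#' @param newdata Matrix or data frame of test samples (rows).
#' @param ... Unused.
#' @return Tibble with one row per test sample: `.pred` (class level),
#'   `.score` (first-level residual minus second-level residual; larger
#'   means more like the second class) and one `.residual_<level>` column
#'   per class.
#' @export
predict.dvm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$xt)) {
    abort(sprintf("newdata has %d features, model expects %d",
                  ncol(newdata), nrow(object$xt)))
  }
  rows <- lapply(seq_len(nrow(newdata)), function(i) {
    dec <- dvm_classify(object, as.numeric(newdata[i, ]))
    out <- c(list(.pred = dec$pred, .score = dec$score),
             as.list(dec$residuals))
    names(out)[-(1:2)] <- paste0(".residual_", object$levels)
    out
  })
  dplyr::bind_rows(rows)
}

#' @method tidy dvm
#' @export
tidy.dvm <- function(x, ...) {
  tibble::tibble(
    class = x$levels,
    n_train = as.integer(table(factor(x$classes, levels = seq_along(x$levels))))
  )
}

#' @method glance dvm
#' @export
glance.dvm <- function(x, ...) {
  tibble::tibble(
    n_train = ncol(x$xt),
    n_features = nrow(x$xt),
    n_classes = length(x$levels),
    k = x$params$k,
    delta = x$params$delta,
    gamma = x$params$gamma,
    theta = x$params$theta
  )
}
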