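# helper: random non-negative training setup in the preprocessed regime
random_dvm_instance <- function(n = 20, d = 6, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * d), nrow = n)
    labels <- rep(0:1, length.out = n)
    y <- runif(d)
    list(x = x, labels = labels, y = y)
  })
}

test_that("neighbour selection matches a brute-force distance sort", {
  inst <- random_dvm_instance(20, 6, seed = 21)
  m <- dvm(inst$x, inst$labels, k = 5)
  nb <- dvm_neighbors(m, inst$y)
  d2 <- colSums((t(inst$x) - inst$y)^2)
  expect_identical(nb$index, order(d2)[1:5])
  expect_equal(nb$X_k, t(inst$x)[, order(d2)[1:5]], ignore_attr = TRUE)

  # k = n returns the whole training set in distance order
  nb_all <- dvm_neighbors(m, inst$y, k = 20)
  expect_identical(sort(nb_all$index), 1:20)
  expect_true(all(diff(d2[nb_all$index]) >= 0))

  # a coinciding training point is its own 1-NN
  nb1 <- dvm_neighbors(m, inst$x[7, ], k = 1)
  expect_identical(nb1$index, 7L)

  expect_error(dvm_neighbors(m, inst$y, k = 21), "exceeds")
})

test_that("the cosine Laplacian has the defining algebraic properties", {
  # single neighbour: W = 1, D = 1, L = 0
  lap1 <- dvm_laplacian(matrix(c(1, 2), ncol = 1))
  expect_equal(lap1$W, matrix(1))
  expect_equal(lap1$L, matrix(0))

  set.seed(22)
  for (i in 1:10) {
    X <- matrix(runif(8 * 5), nrow = 8)
    lap <- dvm_laplacian(X)
    expect_equal(unname(rowSums(lap$L)), rep(0, 5), tolerance = 1e-12)
    expect_true(all(lap$W >= -1e-12 & lap$W <= 1 + 1e-12))
    ev <- eigen(lap$L, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10))   # positive semidefinite
  }

  # zero-norm column: similarities defined as 0
  X0 <- cbind(c(0, 0), c(1, 1))
  lap0 <- dvm_laplacian(X0)
  expect_equal(lap0$W[1, ], c(0, 0))
})

test_that("Welsch reweighting follows the kernel-size formula", {
  d <- 6
  y <- runif(d)
  # perfect fit (beta reconstructs y exactly): sigma = 0, P = I
  rw0 <- dvm_reweight(y, diag(d), y, theta = 1)
  expect_identical(rw0$sigma, 0)
  expect_identical(rw0$p, rep(1, d))

  # equal-magnitude residuals rho with theta = 1: sigma = rho, p = exp(-1)
  rho <- 0.3
  y2 <- rep(rho, d)
  X2 <- matrix(0, d, 2)
  rw <- dvm_reweight(y2, X2, c(0, 0), theta = 1)
  expect_equal(rw$sigma, rho)
  expect_equal(rw$p, rep(exp(-1), d))

  # monotone: larger |residual| gets strictly smaller weight
  y3 <- c(0.1, 0.5, 0.9, 0.2, 0.4, 0)
  rw3 <- dvm_reweight(y3, X2, c(0, 0), theta = 1)
  expect_identical(order(rw3$p), order(abs(y3), decreasing = TRUE))
})

test_that("solve_beta reduces to known closed forms in limiting cases", {
  set.seed(23)
  d <- 5
  X <- matrix(runif(d * d) + diag(d), d, d)    # square, well-conditioned
  y <- runif(d)
  L <- dvm_laplacian(X)$L
  # P = I, gamma = 0, delta -> 0: beta -> X^{-1} y, residual -> 0
  b <- dvm_solve_beta(y, X, rep(1, d), delta = 1e-12, gamma = 0, L = L)
  expect_equal(b, as.numeric(solve(X, y)), tolerance = 1e-6)
  expect_lt(sqrt(sum((y - X %*% b)^2)), 1e-6)
  # huge delta: beta -> 0
  b_inf <- dvm_solve_beta(y, X, rep(1, d), delta = 1e12, gamma = 0, L = L)
  expect_lt(max(abs(b_inf)), 1e-9)
})

test_that("closed-form beta matches derivative-free minimisation of the surrogate", {
  set.seed(24)
  for (i in 1:10) {
    d <- 8; k <- 5
    X <- matrix(runif(d * k), d, k)
    y <- runif(d)
    p <- runif(d, 0.2, 1)
    L <- dvm_laplacian(X)$L
    delta <- 1e-3; gamma <- 1e-4
    obj <- function(b) {
      r <- y - X %*% b
      sum(p * r^2) + delta * sum(b^2) + gamma * as.numeric(t(b) %*% L %*% b)
    }
    b_closed <- dvm_solve_beta(y, X, p, delta, gamma, L)
    o <- optim(rep(0, k), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
    expect_lt(abs(obj(b_closed) - o$value), 1e-4)
    expect_lte(obj(b_closed), o$value + 1e-8)   # closed form is the minimiser
  }
})

test_that("each half-quadratic update never increases the current surrogate", {
  set.seed(25)
  for (i in 1:10) {
    d <- 10; k <- 6
    X <- matrix(runif(d * k), d, k)
    y <- runif(d)
    params <- list(delta = 1e-3, gamma = 1e-4, theta = 1,
                   max_iter = 500L, tol = 1e-12)
    fit <- dvmdti:::dvm_hq(y, X, params, trace = TRUE)
    expect_true(all(fit$trace$obj_post <= fit$trace$obj_pre + 1e-10))
    # terminating beta is a fixed point of the reweight/solve cycle
    rw <- dvm_reweight(y, X, fit$beta, 1)
    b2 <- dvm_solve_beta(y, X, rw$p, 1e-3, 1e-4, dvm_laplacian(X)$L)
    expect_lt(max(abs(b2 - fit$beta)), 1e-6)
  }
})

test_that("the fitted beta is competitive with direct Welsch minimisation", {
  set.seed(26)
  worst <- 0
  for (i in 1:50) {
    d <- 8; k <- 5
    X <- matrix(runif(d * k), d, k)
    y <- runif(d)
    params <- list(delta = 1e-3, gamma = 1e-4, theta = 1,
                   max_iter = 50L, tol = 1e-8)
    L <- dvm_laplacian(X)$L
    fit <- dvmdti:::dvm_hq(y, X, params, L = L)
    sigma <- dvm_reweight(y, X, fit$beta, 1)$sigma
    # the closed form is stationary for the Welsch loss at kernel size
    # sigma scaled so its gradient matches the weighted least squares:
    # sigma^2 * (1 - exp(-r^2/sigma^2)) per component
    welsch <- function(b) {
      r <- y - X %*% b
      sigma^2 * sum(1 - exp(-r^2 / sigma^2)) + 1e-3 * sum(b^2) +
        1e-4 * as.numeric(t(b) %*% L %*% b)
    }
    o <- optim(fit$beta, welsch, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
    worst <- max(worst, welsch(fit$beta) - o$value)
  }
  expect_lt(worst, 1e-3)
})

test_that("an exactly reconstructible sample is assigned its own class", {
  set.seed(27)
  x2 <- matrix(runif(5 * 4, 0.5, 1), 5, 4)   # class-1 cluster
  x1 <- matrix(runif(5 * 4, 0, 0.2), 5, 4)   # class-0 cluster
  x <- rbind(x1, x2)
  labels <- rep(c(0, 1), each = 5)
  m <- dvm(x, labels, k = 3)
  dec <- suppressWarnings(dvm_classify(m, x2[2, ]))
  expect_identical(dec$pred, "1")
  # ridge shrinkage leaves a residual of order delta, not machine zero
  expect_lt(dec$residuals[["1"]], 0.05)
  expect_lt(dec$residuals[["1"]], dec$residuals[["0"]] / 10)
  expect_gt(dec$score, 0)
})

test_that("well-separated Gaussian classes are classified almost perfectly", {
  set.seed(28)
  d <- 10; n <- 50
  mu2 <- rep(6 / sqrt(d), d)
  xtr <- rbind(matrix(rnorm(n * d, 0, 1), n),
               sweep(matrix(rnorm(n * d, 0, 1), n), 2, mu2, "+"))
  xte <- rbind(matrix(rnorm(20 * d, 0, 1), 20),
               sweep(matrix(rnorm(20 * d, 0, 1), 20), 2, mu2, "+"))
  sc <- fit_scaler(xtr)
  m <- suppressWarnings(dvm(apply_scaler(sc, xtr), rep(0:1, each = n), k = 30))
  pred <- suppressWarnings(predict(m, apply_scaler(sc, xte)))
  acc <- mean(pred$.pred == rep(0:1, each = 20))
  expect_gte(acc, 0.95)
})

test_that("training-order permutation does not change decisions", {
  inst <- random_dvm_instance(24, 5, seed = 29)
  m1 <- dvm(inst$x, inst$labels, k = 10)
  perm <- withr::with_seed(30, sample(24))
  m2 <- dvm(inst$x[perm, ], inst$labels[perm], k = 10)
  d1 <- suppressWarnings(dvm_classify(m1, inst$y))
  d2 <- suppressWarnings(dvm_classify(m2, inst$y))
  expect_identical(d1$pred, d2$pred)
  expect_equal(d1$residuals, d2$residuals, tolerance = 1e-10)
})

test_that("score sign matches the argmin decision rule", {
  set.seed(31)
  inst <- random_dvm_instance(30, 6, seed = 31)
  m <- dvm(inst$x, inst$labels, k = 12)
  pred <- suppressWarnings(predict(m, matrix(runif(60), ncol = 6)))
  agree <- ifelse(pred$.score > 0, "1", "0")
  expect_identical(pred$.pred, agree)
})

test_that("a class absent among the neighbours falls back to ||y||", {
  x <- rbind(matrix(0.9, 4, 3), matrix(0.05, 2, 3))
  labels <- c(1, 1, 1, 1, 0, 0)
  m <- dvm(x, labels, k = 2)
  y <- c(0.9, 0.9, 0.9)
  expect_warning(dec <- dvm_classify(m, y), "absent")
  expect_equal(unname(dec$residuals[["0"]]), sqrt(sum(y^2)))
  expect_identical(dec$pred, "1")
})

test_that("model constructor and accessors validate their contracts", {
  inst <- random_dvm_instance(10, 4, seed = 32)
  expect_error(dvm(inst$x, inst$labels, k = 11), "k must be in")
  expect_error(dvm(inst$x, rep(1, 10)), "two classes")
  m <- dvm(inst$x, inst$labels)
  expect_identical(m$params$k, 10L)     # default min(n, 200)
  g <- glance(m)
  expect_identical(g$n_train, 10L)
  expect_identical(g$delta, 1e-3)
  expect_identical(g$gamma, 1e-4)
  expect_identical(g$theta, 1)
  expect_identical(sum(tidy(m)$n_train), 10L)
})
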