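test_that("min-max scaling maps training data into [0,1] with the stated rules", {
  x <- matrix(c(2, 3, 4,   # feature 1: min 2, max 4
                5, 5, 5),  # feature 2: constant
              ncol = 2)
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  expect_equal(xs[, 1], c(0, 0.5, 1))
  expect_equal(xs[, 2], c(0, 0, 0))       # constant feature -> 0

  # out-of-range test values are clipped into [0, 1]
  xt <- apply_scaler(sc, matrix(c(1, 10, 4, 6), ncol = 2))
  expect_true(all(xt >= 0 & xt <= 1))
  expect_equal(xt[, 1], c(0, 1))

  expect_error(fit_scaler(matrix(numeric(), 0, 3)), "empty")
})

test_that("scale then invert recovers the original values", {
  set.seed(4)
  x <- matrix(rnorm(60), ncol = 6)
  sc <- fit_scaler(x)
  expect_equal(invert_scaler(sc, apply_scaler(sc, x)), x, ignore_attr = TRUE)
})

test_that("PCA recovers exact low-rank structure", {
  set.seed(8)
  basis <- qr.Q(qr(matrix(rnorm(20), 10, 2)))      # 2-D plane in 10-D
  x <- matrix(rnorm(80), ncol = 2) %*% t(basis)
  p <- fit_pca(x, variance_target = 0.99)
  expect_identical(p$dim, 2L)
  expect_equal(crossprod(p$rotation), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("projections are uncorrelated with non-increasing variances", {
  set.seed(10)
  x <- matrix(rnorm(300), ncol = 6) %*% diag(c(3, 2.5, 2, 1.5, 1, 0.5))
  p <- fit_pca(x, dim = 4)
  z <- apply_pca(p, x)
  v <- apply(z, 2, var)
  expect_true(all(diff(v) <= 1e-10))
  cc <- cov(z)
  expect_equal(cc - diag(diag(cc)), matrix(0, 4, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("reconstruction error equals the discarded eigenvalue mass", {
  set.seed(11)
  x <- matrix(rnorm(25 * 8), ncol = 8)
  m <- 3
  p <- fit_pca(x, dim = m)
  z <- apply_pca(p, x)
  recon <- z %*% t(p$rotation)
  centred <- sweep(x, 2, colMeans(x))
  err <- sum((centred - recon)^2)
  # independent eigendecomposition oracle
  ev <- eigen(cov(centred), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(err, (nrow(x) - 1) * sum(ev[(m + 1):8]), tolerance = 1e-8)
})

test_that("variance target is validated and total variance is conserved", {
  set.seed(12)
  x <- matrix(rnorm(40), ncol = 4)
  expect_error(fit_pca(x, variance_target = 0), "\\(0, 1\\]")
  expect_error(fit_pca(x, variance_target = 1.2), "\\(0, 1\\]")
  p_full <- fit_pca(x, variance_target = 1)
  z <- apply_pca(p_full, x)
  expect_equal(sum(apply(z, 2, var)), sum(apply(x, 2, var)), tolerance = 1e-10)
  p_part <- fit_pca(x, dim = 2)
  z2 <- apply_pca(p_part, x)
  expect_lt(sum(apply(z2, 2, var)), sum(apply(x, 2, var)))
})

test_that("preprocessing never sees the test fold", {
  set.seed(13)
  train <- matrix(rnorm(50), ncol = 5)
  sc1 <- fit_scaler(train)
  p1 <- fit_pca(apply_scaler(sc1, train), dim = 2)
  # plant a huge outlier in the 'test' fold; training statistics unchanged
  test_fold <- matrix(rnorm(10), ncol = 5)
  test_fold[1, 1] <- 1e6
  sc2 <- fit_scaler(train)
  p2 <- fit_pca(apply_scaler(sc2, train), dim = 2)
  expect_identical(sc1, sc2)
  expect_identical(p1$rotation, p2$rotation)
  expect_true(all(apply_scaler(sc1, test_fold) <= 1))
})

test_that("fitted preprocessing persists through the JSON sidecar", {
  set.seed(14)
  x <- matrix(rnorm(60), ncol = 6)
  sc <- fit_scaler(x)
  p <- fit_pca(apply_scaler(sc, x), dim = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_preprocessor(sc, p, f)
  back <- read_preprocessor(f)
  expect_equal(back$scaler$min, unname(sc$min))
  expect_equal(unname(back$pca$rotation), unname(p$rotation))
  y <- matrix(rnorm(12), ncol = 6)
  expect_equal(
    apply_pca(back$pca, apply_scaler(back$scaler, y)),
    apply_pca(p, apply_scaler(sc, y)),
    ignore_attr = TRUE
  )
})
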