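test_that("centering subtracts column means", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)
  ct <- ipcarf:::center_columns(x)
  expect_equal(ct$mean, c(2, 3))
  expect_equal(ct$x, matrix(c(-1, 1, -1, 1), 2, 2))
  expect_equal(ipcarf:::center_columns(matrix(5, 3, 2))$x, matrix(0, 3, 2))
  centred <- matrix(c(-1, 1, -2, 2), 2, 2)
  expect_equal(ipcarf:::center_columns(centred)$x, centred)
  expect_error(ipcarf:::center_columns(matrix(1, 1, 2)), "at least 2 rows")
})

test_that("covariance is symmetric PSD with 1/(n-1) normalisation", {
  xc <- matrix(c(-1, 1, -1, 1), 2, 2)
  C <- ipcarf:::covariance_matrix(xc)
  expect_equal(C, matrix(2, 2, 2))
  # Orthogonal centred columns give a diagonal covariance.
  xo <- cbind(c(-1, 1, -1, 1), c(-1, 1, 1, -1))
  expect_equal(ipcarf:::covariance_matrix(xo),
               diag(c(4 / 3, 4 / 3)), tolerance = 1e-12)
  set.seed(2)
  Cr <- ipcarf:::covariance_matrix(scale(matrix(rnorm(60), 12, 5),
                                         scale = FALSE))
  expect_true(all(eigen(Cr, symmetric = TRUE)$values >= -1e-10))
})

test_that("column selection ranks l2 norms with lower-index ties", {
  C <- diag(c(3, 1, 2))
  expect_equal(ipcarf:::select_columns(C, 2), c(1L, 3L))
  expect_equal(ipcarf:::select_columns(C, 3), c(1L, 3L, 2L))
  Ct <- diag(c(2, 2, 1))
  expect_equal(ipcarf:::select_columns(Ct, 1), 1L)
  expect_error(ipcarf:::select_columns(C, 4), "out of range")
})

test_that("full-k IPCA recovers exact PCA projections up to sign", {
  set.seed(10)
  x <- matrix(rnorm(80), 20, 4)
  fit <- ipca(x, n_components = 4, k = 4)
  proj <- predict(fit, x)
  C <- ipcarf:::covariance_matrix(ipcarf:::center_columns(x)$x)
  eig <- eigen(C, symmetric = TRUE)
  exact <- ipcarf:::center_columns(x)$x %*% eig$vectors
  for (j in 1:4) {
    expect_true(max(abs(proj[, j] - exact[, j])) < 1e-8 ||
                max(abs(proj[, j] + exact[, j])) < 1e-8)
  }
  expect_equal(fit$explained_variance, eig$values, tolerance = 1e-10)
})

test_that("principal angles to the exact eigenspace vanish at k = p", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(rnorm(60 * 20), 60, 20)
    nc <- 5
    fit <- ipca(x, n_components = nc, k = 20)
    C <- ipcarf:::covariance_matrix(ipcarf:::center_columns(x)$x)
    V <- eigen(C, symmetric = TRUE)$vectors[, 1:nc]
    expect_lt(max(principal_angles(fit$basis, V)), 1e-8)
  }
})

test_that("basis is orthonormal with deterministic signs and sorted variance", {
  set.seed(4)
  x <- matrix(rnorm(200), 40, 5)
  fit <- ipca(x, n_components = 3, k = 4)
  expect_equal(crossprod(fit$basis), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
  for (j in 1:3) expect_gt(fit$basis[which.max(abs(fit$basis[, j])), j], 0)
  expect_identical(ipca(x, n_components = 3, k = 4)$basis, fit$basis)
})

test_that("captured variance is nondecreasing in k and n_components", {
  set.seed(6)
  x <- matrix(rnorm(50 * 12), 50, 12)
  var_k <- vapply(3:12, function(k)
    sum(ipca(x, n_components = 3, k = k)$explained_variance), 0)
  expect_true(all(diff(var_k) >= -1e-10))
  var_nc <- vapply(1:6, function(nc)
    sum(ipca(x, n_components = nc, k = 12)$explained_variance), 0)
  expect_true(all(diff(var_nc) >= -1e-10))
})

test_that("near-1D data put essentially all variance on the first component", {
  set.seed(8)
  t <- rnorm(100)
  x <- cbind(t, 2 * t, -t) + matrix(rnorm(300, sd = 1e-6), 100, 3)
  fit <- suppressWarnings(ipca(x, n_components = 3, k = 3))
  expect_gt(fit$explained_variance[1] / fit$total_variance, 0.999)
})

test_that("degenerate inputs: constant matrix and rank fallback", {
  xconst <- matrix(3, 10, 4)
  fit <- ipca(xconst, n_components = 2, k = 4)
  expect_equal(fit$explained_variance, c(0, 0))
  expect_equal(predict(fit, xconst), matrix(0, 10, 2), ignore_attr = TRUE)

  # Rank-1 data cannot support 3 components.
  x1 <- outer(1:10, c(1, 2, 3))
  expect_warning(f1 <- ipca(x1, n_components = 3, k = 3), "rank-deficient")
  expect_equal(f1$n_components, 1L)
})

test_that("transform is affine-correct and distance-preserving at full rank", {
  set.seed(12)
  x <- matrix(rnorm(30 * 6), 30, 6)
  fit <- ipca(x, n_components = 6, k = 6)
  expect_equal(unname(predict(fit, matrix(fit$mean, 1))), matrix(0, 1, 6),
               tolerance = 1e-10)
  expect_equal(dim(predict(fit, x)), c(30, 6))
  d_orig <- dist(ipcarf:::center_columns(x)$x)
  d_proj <- dist(predict(fit, x))
  expect_equal(as.numeric(d_proj), as.numeric(d_orig), tolerance = 1e-8)
  expect_error(predict(fit, matrix(0, 2, 5)), "expected 6")
})
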