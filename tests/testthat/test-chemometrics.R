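# PCA, OPLS-DA and RDA variance partitioning.

test_that("PCA recovers planted low-rank structure", {
  u <- rnorm(20)
  m <- outer(u, rnorm(6))          # rank 1
  p1 <- suppressWarnings(feature_pca(m, 2))
  expect_equal(p1$explained[1], 1, tolerance = 1e-12)
  set.seed(15)
  m2 <- matrix(rnorm(200), 20, 10)
  p2 <- feature_pca(m2, 4)
  expect_equal(crossprod(p2$loadings), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(!is.unsorted(rev(p2$explained)))
  expect_lte(sum(p2$explained), 1 + 1e-12)
  # planted 2-cluster structure separates on PC1
  cl <- rep(c(0, 6), each = 10)
  m3 <- matrix(rnorm(200), 20, 10) + cl
  p3 <- feature_pca(m3, 2)
  expect_gt(silhouette_1d(p3$scores[, 1], cl), 0.5)
})

test_that("OPLS-DA with 0 orthogonal components is 1-component PLS-DA", {
  set.seed(16)
  x <- matrix(rnorm(30 * 12), 30, 12)
  y <- factor(rep(c("a", "b"), each = 15))
  fit <- opls_da(x, y, n_ortho = 0, cv_folds = 5, n_perm = 0, seed = 1)
  ref <- nipals_pls1(x, as.numeric(y) - 1)
  expect_equal(unname(fit$scores), unname(ref$scores), tolerance = 1e-8)
  expect_equal(unname(fit$weights), unname(ref$weights),
               tolerance = 1e-8)
})

test_that("VIP normalisation and R2Y monotonicity hold", {
  set.seed(17)
  x <- matrix(rnorm(40 * 25), 40, 25)
  x[, 1:5] <- x[, 1:5] + rep(c(0, 1.5), each = 20)
  y <- factor(rep(c("a", "b"), each = 20))
  r2y <- vapply(0:3, function(k) {
    fit <- opls_da(x, y, n_ortho = k, cv_folds = 5, n_perm = 0, seed = 2)
    expect_equal(mean(fit$vip^2), 1, tolerance = 1e-9)
    fit$R2Y
  }, numeric(1))
  expect_true(all(diff(r2y) >= -1e-10))
})

test_that("a separable two-class design is fitted and predicted", {
  set.seed(18)
  x <- matrix(rnorm(40 * 30), 40, 30)
  x[, 1:10] <- x[, 1:10] + rep(c(0, 2), each = 20)
  y <- factor(rep(c("a", "b"), each = 20))
  fit <- opls_da(x, y, n_ortho = 1, cv_folds = 7, n_perm = 99, seed = 3)
  expect_gt(fit$Q2, 0.5)
  expect_lt(fit$p_perm, 0.05)
  expect_lte(fit$Q2, fit$R2Y)
  expect_identical(predict(fit, x), y)
  # residuals + fitted reconstruct the centred class code
  y_num <- as.numeric(y) - 1
  expect_equal(residuals(fit) + fit$scores * fit$q, y_num - mean(y_num),
               tolerance = 1e-12)
  # markers dominate the VIP ranking
  vr <- vip_ranking(fit, threshold = 1)
  expect_gt(mean(as.integer(sub("V", "", vr$markers$feature_id[1:10]))
                 %in% 1:10), 0.8)
})

test_that("labels independent of the data give a null model", {
  set.seed(19)
  x <- matrix(rnorm(30 * 40), 30, 40)
  y <- factor(rep(c("a", "b"), each = 15))
  fit <- opls_da(x, y, n_ortho = 1, cv_folds = 5, n_perm = 99, seed = 4)
  expect_lt(fit$Q2, 0.1)
  expect_gt(fit$p_perm, 0.05)
})

test_that("single-class input and tiny classes are rejected", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(opls_da(x, rep("a", 10), seed = 1), "two classes")
  expect_error(opls_da(x, rep(c("a", "b"), c(8, 2)), cv_folds = 5,
                       seed = 1), "cv_folds")
  expect_error(opls_da(x, rep(c("a", "b"), each = 5), cv_folds = 2,
                       n_perm = 0), "seed")
})

test_that("permutation p-values are uniform under the null", {
  set.seed(20)
  pvals <- vapply(1:200, function(i) {
    x <- matrix(rnorm(16 * 20), 16, 20)
    y <- factor(rep(c("a", "b"), each = 8))
    opls_da(x, y, n_ortho = 0, cv_folds = 4, n_perm = 49,
            seed = 1000 + i)$p_perm
  }, numeric(1))
  # Kolmogorov band at alpha = 0.01 (n = 200), plus the 1/50 grid step
  d <- max(abs(sort(pvals) - (seq_along(pvals) - 0.5) / length(pvals)))
  expect_lt(d, 1.628 / sqrt(200) + 1 / 50)
})

test_that("RDA eigenvalues equal the regression-then-PCA oracle", {
  set.seed(22)
  n <- 8
  x <- matrix(rnorm(n * 6), n, 6)
  f <- data.frame(a = factor(rep(c("u", "v"), 4)),
                  b = factor(rep(c("p", "q"), each = 4)))
  eig <- constrained_eigen(x, f)
  # oracle: multivariate regression on the dummy design, PCA of fits
  xc <- scale(x, scale = FALSE)
  D <- model.matrix(~ a + b, f)
  fitted <- D %*% solve(crossprod(D), crossprod(D, xc))
  ev <- svd(fitted)$d^2 / (n - 1)
  expect_equal(eig, ev[seq_along(eig)], tolerance = 1e-9)
})

test_that("variance partition fractions decompose to one", {
  pm <- simulate_factor_matrix(n = 54, p = 20,
                               fractions = c(variety = 0.2), seed = 23)
  vp <- rda_varpart(pm$x, pm$factors, n_perm = 99, seed = 23)
  total <- sum(vp$unique) + sum(vp$shared) + vp$unexplained
  expect_equal(total, 1, tolerance = 1e-6)
  expect_true(all(c(vp$unique, vp$shared, vp$unexplained) >= -0.05))
  expect_lt(vp$significance$p[vp$significance$factor == "variety"],
            0.05)
})

test_that("factors independent of the response explain nothing", {
  pm <- simulate_factor_matrix(n = 100, p = 30, fractions = c(variety = 0),
                               seed = 24)
  vp <- rda_varpart(pm$x, pm$factors, n_perm = 99, seed = 24)
  expect_true(all(abs(vp$unique) < 0.02))
  expect_error(rda_varpart(pm$x, pm$factors, n_perm = 9), "seed")
  expect_warning(
    rda_varpart(pm$x, cbind(pm$factors,
                            const = factor(rep("z", 100)))[, c(1, 2, 4)],
                n_perm = 9, seed = 1), "constant")
})
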