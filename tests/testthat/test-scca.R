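test_that("cross-product counts drug co-occurrence", {
  X <- matrix(1, 3, 1, dimnames = list(paste0("d", 1:3), "t1"))
  mp <- new("MatrixPair", X = X, Y = `colnames<-`(X, "s1"),
            targetClasses = "protein")
  expect_equal(crossProduct(mp), matrix(3, 1, 1,
                                        dimnames = list("t1", "s1")))

  set.seed(7)
  mp2 <- randomPair(m = 6, p = 4, q = 3, seed = 7)
  Z <- crossProduct(mp2)
  X <- targetMatrix(mp2); Y <- diseaseMatrix(mp2)
  for (i in seq_len(ncol(X))) for (j in seq_len(ncol(Y)))
    expect_equal(Z[i, j], sum(X[, i] == 1 & Y[, j] == 1))
})

test_that("soft threshold matches its closed form", {
  expect_equal(softThreshold(c(2, -1, 0.5), 1), c(1, 0, 0))
  v <- c(-3, 0.2, 5)
  expect_equal(softThreshold(v, 0), v)
  expect_equal(softThreshold(c(3, -3), 3), c(0, 0))
  expect_error(softThreshold(v, -1), "nonnegative")
})

test_that("L1-bounded projection finds the smallest sufficient threshold", {
  expect_equal(l1BoundedUnit(c(1, 0, 0), 1), c(1, 0, 0))
  expect_equal(l1BoundedUnit(c(1, 1), sqrt(2)), c(1, 1) / sqrt(2))
  expect_error(l1BoundedUnit(c(0, 0), 1.5), "zero vector")
  expect_error(l1BoundedUnit(c(1, 2), 0.8), "infeasible")

  # delta-grid oracle at 1e-6 resolution on the constraint boundary
  v <- c(3, 2, 1); cB <- 1.2
  grid <- seq(0, max(abs(v)) - 1e-9, by = 1e-6)
  l1 <- vapply(grid, function(d) {
    s <- softThreshold(v, d); sum(abs(s)) / sqrt(sum(s^2))
  }, numeric(1))
  dstar <- grid[which.min(abs(l1 - cB))]
  w.oracle <- softThreshold(v, dstar) / sqrt(sum(softThreshold(v, dstar)^2))
  w <- l1BoundedUnit(v, cB)
  expect_equal(w, w.oracle, tolerance = 1e-4)
  expect_lte(sum(abs(w)), cB + 1e-6)
  expect_equal(sum(w^2), 1)
})

test_that("projection handles exactly tied maxima without leaving the constraint set", {
  w <- l1BoundedUnit(rep(2, 9), 1.5)
  expect_equal(sum(w^2), 1, tolerance = 1e-12)
  expect_equal(sum(abs(w)), 1.5, tolerance = 1e-9)
  expect_true(all(w > 0))  # the whole tied set stays in the support
})

test_that("rank-1 extraction recovers dominant singular structure", {
  Z <- diag(c(3, 1))
  comp <- fitRank1(Z, mode = "OCCA")
  expect_equal(abs(comp$alpha), c(1, 0), tolerance = 1e-8)
  expect_equal(abs(comp$beta), c(1, 0), tolerance = 1e-8)
  expect_equal(comp$d, 3, tolerance = 1e-8)

  u <- c(1, 0, 0, 0); v <- c(0, 1, 0)
  comp2 <- fitRank1(u %*% t(v), c1Bound = 1.3, c2Bound = 1.3, mode = "SCCA")
  expect_equal(abs(comp2$alpha), u, tolerance = 1e-8)
  expect_equal(abs(comp2$beta), v, tolerance = 1e-8)
  expect_equal(comp2$d, 1, tolerance = 1e-8)

  expect_error(fitRank1(matrix(0, 2, 2), mode = "OCCA"), "all zero")
  expect_error(fitRank1(diag(2), c1Bound = 0.5, c2Bound = 1.3), "infeasible")
})

test_that("rank-1 PMD objective reaches the exhaustive-search optimum", {
  for (s in 1:3) {
    set.seed(s)
    Z <- matrix(rnorm(20), 5, 4)
    cB <- 1.3
    comp <- fitRank1(Z, c1Bound = cB, c2Bound = cB, mode = "SCCA")
    expect_equal(comp$d, rank1Oracle(Z, cB, cB), tolerance = 1e-4)
  }
})

test_that("deflation is exact and pure", {
  u <- c(0.6, 0.8); v <- c(1, 0, 0)
  Z <- 2.5 * u %*% t(v)
  comp <- fitRank1(Z, mode = "OCCA")
  expect_equal(max(abs(deflate(Z, comp))), 0, tolerance = 1e-8)
  expect_equal(Z, 2.5 * u %*% t(v))  # input untouched

  comp0 <- comp; comp0$d <- 0
  expect_equal(deflate(Z, comp0), Z)

  # residual after removing the top pair of diag(3, 1) has norm 1
  D <- diag(c(3, 1))
  r <- deflate(D, fitRank1(D, mode = "OCCA"))
  expect_equal(svd(r)$d[1], 1, tolerance = 1e-7)
})

test_that("canonical correlation matches the term-by-term formula", {
  mp <- toyPair()
  p <- ncol(targetMatrix(mp)); q <- ncol(diseaseMatrix(mp))
  set.seed(11)
  alpha <- rnorm(p); beta <- rnorm(q)
  u <- as.vector(targetMatrix(mp) %*% alpha)
  v <- as.vector(diseaseMatrix(mp) %*% beta)
  byHand <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  expect_equal(canonicalCorrelation(mp, alpha, beta), byHand)

  # perfect alignment and orthogonality
  X <- diag(2); dimnames(X) <- list(c("a", "b"), c("t1", "t2"))
  mp2 <- new("MatrixPair", X = X, Y = `colnames<-`(X, c("s1", "s2")),
             targetClasses = rep("protein", 2))
  expect_equal(canonicalCorrelation(mp2, c(1, 1), c(1, 1)), 1.0)
  expect_equal(canonicalCorrelation(mp2, c(1, 0), c(0, 1)), 0.0)
  # zero projection: defined as 0
  expect_equal(canonicalCorrelation(mp2, c(0, 0), c(1, 0)), 0)
})

test_that("OCCA fit equals the singular value decomposition", {
  mp <- randomPair(seed = 2)
  Z <- crossProduct(mp)
  k <- 5
  model <- fitSCCA(mp, k = k, mode = "OCCA", cfg = fitConfig(tol = 1e-12,
                                                             maxIter = 2000))
  sv <- svd(Z)
  expect_equal(singularValues(model), sv$d[1:k], tolerance = 1e-6)
  expect_true(all(diff(singularValues(model)) <= 1e-8))
  for (i in 1:k) {
    expect_equal(abs(model@alpha[, i]), abs(sv$u[, i]), tolerance = 1e-5)
    expect_equal(abs(model@beta[, i]), abs(sv$v[, i]), tolerance = 1e-5)
  }
  # completeness: deflating all rank(Z) components annihilates Z
  full <- fitSCCA(mp, k = min(dim(Z)), mode = "OCCA",
                  cfg = fitConfig(tol = 1e-12, maxIter = 5000))
  resid <- Z
  for (i in seq_len(nComponents(full)))
    resid <- resid - full@d[i] * tcrossprod(full@alpha[, i], full@beta[, i])
  expect_lt(sqrt(sum(resid^2)), 1e-5 * sqrt(sum(Z^2)))
})

test_that("fitted components satisfy the norm constraints", {
  mp <- randomPair(seed = 4)
  c1 <- 0.4; c2 <- 0.45
  model <- fitSCCA(mp, k = 4, c1 = c1, c2 = c2)
  p <- length(targetIds(model)); q <- length(diseaseIds(model))
  for (i in 1:4) {
    expect_lte(sum(model@alpha[, i]^2), 1 + 1e-6)
    expect_lte(sum(model@beta[, i]^2), 1 + 1e-6)
    expect_lte(sum(abs(model@alpha[, i])), c1 * sqrt(p) + 1e-6)
    expect_lte(sum(abs(model@beta[, i])), c2 * sqrt(q) + 1e-6)
    Zi <- crossProduct(mp)
    expect_gte(model@d[i], 0)
    expect_gte(model@rho[i], -1 - 1e-12)
    expect_lte(model@rho[i], 1 + 1e-12)
  }
})

test_that("slack sparsity constraints reproduce the OCCA solution", {
  mp <- randomPair(seed = 5)
  cfg <- fitConfig(tol = 1e-10, maxIter = 1000)
  slack <- fitSCCA(mp, k = 3, c1 = 1, c2 = 1, mode = "SCCA", cfg = cfg)
  occa <- fitSCCA(mp, k = 3, mode = "OCCA", cfg = cfg)
  expect_equal(slack@alpha, occa@alpha, tolerance = 1e-6)
  expect_equal(slack@beta, occa@beta, tolerance = 1e-6)
  expect_equal(slack@d, occa@d, tolerance = 1e-6)
})

test_that("objective is nondecreasing across alternating iterations", {
  set.seed(8)
  Z <- matrix(rnorm(12 * 9), 12, 9)
  cB <- 1.5
  beta <- svd(Z)$v[, 1]
  prev <- -Inf
  for (i in 1:30) {
    alpha <- l1BoundedUnit(as.vector(Z %*% beta), cB)
    beta <- l1BoundedUnit(as.vector(t(Z) %*% alpha), cB)
    obj <- drop(t(alpha) %*% Z %*% beta)
    # tolerance reflects the 1e-8 bisection resolution of the L1 step
    expect_gte(obj, prev - 1e-6)
    prev <- obj
  }
})

test_that("sign convention and seed make refits identical", {
  mp <- randomPair(seed = 6)
  m1 <- fitSCCA(mp, k = 3, c1 = 0.5, c2 = 0.5)
  m2 <- fitSCCA(mp, k = 3, c1 = 0.5, c2 = 0.5)
  expect_identical(m1@alpha, m2@alpha)
  for (i in 1:3)
    expect_gt(m1@alpha[which.max(abs(m1@alpha[, i])), i], 0)
})

test_that("alpha support grows with the sparsity parameter", {
  mp <- randomPair(seed = 9)
  nnz <- vapply(c(0.3, 0.5, 0.7, 0.9, 1), function(cc)
    sum(fitSCCA(mp, k = 1, c1 = cc, c2 = 0.9)@alpha != 0), numeric(1))
  expect_true(all(diff(nnz) >= 0))
})

test_that("infeasible sparsity parameters are rejected with the computed bound", {
  mp <- randomPair(m = 20, p = 6, q = 6, seed = 10)
  expect_error(fitSCCA(mp, k = 1, c1 = 0.2, c2 = 0.9), "c1\\*sqrt\\(p\\)")
  expect_error(fitSCCA(mp, k = 99, c1 = 0.9, c2 = 0.9), "min\\(p, q\\)")
})
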