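## Sparse canonical correlation analysis by rank-one penalized matrix
## decomposition (PMD) of the cross-product matrix Z = X'Y, with L1
## constraints ||alpha||_1 <= c1*sqrt(p), ||beta||_1 <= c2*sqrt(q) on
## top of the unit L2 balls, and iterative deflation between components.

#' Fit configuration for the rank-one PMD inner loop
#'
#' @param tol convergence tolerance on the successive change of beta
#'   (max absolute difference); must be > 0.
#' @param maxIter iteration cap for the alternating updates; >= 1.
#' @param init \code{"svd"} (leading right singular vector of Z,
#'   deterministic; the default) or \code{"random"} (seeded Gaussian).
#' @param seed integer seed used only when \code{init = "random"}.
#' @return a list of class \code{FitConfig}.
#' @export
fitConfig <- function(tol = 1e-6, maxIter = 200L, init = c("svd", "random"),
                      seed = 1L) {
  stopifnot(tol > 0, maxIter >= 1)
  init <- match.arg(init)
  structure(list(tol = tol, maxIter = as.integer(maxIter), init = init,
                 seed = as.integer(seed)), class = "FitConfig")
}

#' Cross-product matrix of the two views
#'
#' Computes Z = X'Y. For binary X, Y, entry Z[i, j] is the number of
#' drugs carrying both target i and disease j.
#'
#' @param mp a \code{\linkS4class{MatrixPair}}.
#' @return a p x q numeric matrix with target/disease dimnames.
#' @export
crossProduct <- function(mp) crossprod(targetMatrix(mp), diseaseMatrix(mp))

#' Soft-thresholding operator
#'
#' Elementwise \code{sign(v) * pmax(|v| - delta, 0)}, the proximal
#' operator realizing the L1 constraints of the PMD updates.
#'
#' @param v numeric vector.
#' @param delta nonnegative threshold.
#' @return the shrunken vector.
#' @export
softThreshold <- function(v, delta) {
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0)
    stop("delta must be a single nonnegative number", call. = FALSE)
  sign(v) * pmax(abs(v) - delta, 0)
}

#' L1-constrained projection onto the unit sphere
#'
#' Returns w = S(v, delta) / ||S(v, delta)||_2 with the smallest
#' delta >= 0 (found by bisection) such that ||w||_1 <= cBound. When
#' delta = 0 already satisfies the bound, w = v / ||v||_2. This is the
#' exact maximizer of w'v over {||w||_2 <= 1, ||w||_1 <= cBound}, the
#' closed-form coordinate step of the PMD algorithm.
#'
#' When the largest-magnitude entries of \code{v} are exactly tied and
#' the tied set is larger than \code{cBound^2}, no soft-threshold
#' solution attains the bound (the thresholded vector tends to equal
#' weights on the tied set, whose L1 norm is the square root of its
#' size). The maximizer is then flat in how weight is spread over the
#' tied set; the deterministic choice here keeps EVERY tied coordinate
#' in the support via a two-level weight profile (sizes chosen to make
#' the light level as large as possible), with heavy weights assigned
#' in coordinate order.
#'
#' @param v numeric vector, not all zero.
#' @param cBound L1 bound; must be >= 1 (the unit L2 sphere intersects
#'   the L1 ball only for bounds >= 1).
#' @param l1tol bisection resolution on ||w||_1.
#' @return a unit vector with ||w||_1 <= cBound (+ l1tol).
#' @export
l1BoundedUnit <- function(v, cBound, l1tol = 1e-8) {
  if (all(v == 0)) stop("cannot project the zero vector", call. = FALSE)
  if (cBound < 1)
    stop(sprintf("infeasible L1 bound %g: the constraint set is empty below 1",
                 cBound), call. = FALSE)
  w <- v / sqrt(sum(v^2))
  if (sum(abs(w)) <= cBound) return(w)
  lo <- 0; hi <- max(abs(v))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    s <- softThreshold(v, mid)
    if (all(s == 0)) { hi <- mid; next }
    w <- s / sqrt(sum(s^2))
    l1 <- sum(abs(w))
    if (l1 > cBound) lo <- mid else hi <- mid
    if (hi - lo < l1tol * max(1, max(abs(v)))) break
  }
  s <- softThreshold(v, hi)
  if (!all(s == 0)) {
    w <- s / sqrt(sum(s^2))
    if (sum(abs(w)) <= cBound + 1e-6) return(w)
  }
  tiedTopSolution(v, cBound)
}

## exact maximizer when the top |v| entries are tied and the tied set
## exceeds cBound^2: two levels (a on the first j tied coordinates, b
## on the rest), solving j*a + r*b = cBound, j*a^2 + r*b^2 = 1 with the
## feasible j (< cBound^2) that maximizes the light level b
tiedTopSolution <- function(v, cBound) {
  vmax <- max(abs(v))
  idx <- which(abs(v) >= vmax * (1 - 1e-12))
  n <- length(idx)
  w <- numeric(length(v))
  if (sqrt(n) <= cBound) {
    w[idx] <- sign(v[idx]) / sqrt(n)
    return(w)
  }
  best <- NULL
  for (j in seq_len(min(n - 1, ceiling(cBound^2) - 1))) {
    r <- n - j
    disc <- cBound^2 * r^2 - r * n * (cBound^2 - j)
    if (disc < 0) next
    b <- (cBound * r - sqrt(disc)) / (r * n)
    a <- (cBound - r * b) / j
    if (b <= 0 || a < b) next
    if (is.null(best) || b > best$b) best <- list(j = j, a = a, b = b)
  }
  stopifnot(!is.null(best))
  lv <- rep(best$b, n)
  lv[seq_len(best$j)] <- best$a
  w[idx] <- sign(v[idx]) * lv
  w
}

unitOrL1 <- function(v, cBound, mode) {
  if (mode == "OCCA") {
    if (all(v == 0)) stop("cannot project the zero vector", call. = FALSE)
    v / sqrt(sum(v^2))
  } else l1BoundedUnit(v, cBound)
}

#' Rank-one penalized matrix decomposition
#'
#' Extracts one (alpha, beta, d) triple from Z by alternating the exact
#' constrained updates alpha <- argmax alpha'(Z beta) and
#' beta <- argmax beta'(Z' alpha) until the change in beta falls below
#' \code{cfg$tol}. In SCCA mode each update is L1-constrained
#' (\code{\link{l1BoundedUnit}}); in OCCA mode the bounds are ignored
#' and the iteration converges to the leading singular pair of Z.
#' The sign convention flips (alpha, beta) jointly so the
#' largest-magnitude entry of alpha is positive; d = alpha' Z beta is
#' unaffected.
#'
#' @param Z numeric matrix (typically \code{\link{crossProduct}} output
#'   or a deflated residual); must not be all zero.
#' @param c1Bound,c2Bound absolute L1 bounds (already scaled, i.e.
#'   c1*sqrt(p) and c2*sqrt(q)); ignored in OCCA mode.
#' @param cfg a \code{\link{fitConfig}}.
#' @param mode \code{"SCCA"} or \code{"OCCA"}.
#' @return a list of class \code{CanonicalComponent} with elements
#'   \code{alpha}, \code{beta}, \code{d}, \code{rho} (NA until computed
#'   against data), \code{iterations}, \code{converged}.
#' @export
fitRank1 <- function(Z, c1Bound = NA_real_, c2Bound = NA_real_,
                     cfg = fitConfig(), mode = c("SCCA", "OCCA")) {
  mode <- match.arg(mode)
  if (all(Z == 0)) stop("Z is all zero: nothing to decompose", call. = FALSE)
  if (mode == "SCCA") {
    if (is.na(c1Bound) || c1Bound < 1)
      stop(sprintf("c1 bound %g infeasible: need c1*sqrt(p) >= 1", c1Bound),
           call. = FALSE)
    if (is.na(c2Bound) || c2Bound < 1)
      stop(sprintf("c2 bound %g infeasible: need c2*sqrt(q) >= 1", c2Bound),
           call. = FALSE)
  }
  beta <- switch(cfg$init,
    svd = La.svd(Z, nu = 0, nv = 1)$vt[1, ],
    random = localSeed(cfg$seed, stats::rnorm(ncol(Z))))
  beta <- beta / sqrt(sum(beta^2))
  alpha <- NULL
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(cfg$maxIter)) {
    alpha <- unitOrL1(drop(Z %*% beta), c1Bound, mode)
    betaNew <- unitOrL1(drop(crossprod(Z, alpha)), c2Bound, mode)
    delta <- max(abs(betaNew - beta))
    beta <- betaNew
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("rank-1 PMD did not converge in %d iterations",
                    cfg$maxIter))
  # deterministic sign: largest-|.| entry of alpha positive
  if (alpha[which.max(abs(alpha))] < 0) { alpha <- -alpha; beta <- -beta }
  d <- drop(crossprod(alpha, Z %*% beta))
  structure(list(alpha = alpha, beta = beta, d = d, rho = NA_real_,
                 iterations = iter, converged = converged),
            class = "CanonicalComponent")
}

#' Deflate a matrix by one component
#'
#' Returns Z - d * alpha beta', removing the captured rank-one
#' structure so the next extraction targets the remainder. Pure
#' function; the input is not modified.
#'
#' @param Z numeric matrix.
#' @param comp a \code{CanonicalComponent} from \code{\link{fitRank1}}.
#' @return the deflated matrix.
#' @export
deflate <- function(Z, comp) Z - comp$d * tcrossprod(comp$alpha, comp$beta)

#' Uncentered canonical correlation of a weight pair
#'
#' rho = sum_i (alpha't_i)(beta'd_i) /
#'       (sqrt(sum_i (alpha't_i)^2) * sqrt(sum_i (beta'd_i)^2)),
#' the cosine between the projected sample vectors X alpha and Y beta.
#' The variables are deliberately NOT mean-centered (set
#' \code{centered = TRUE} for the centered Pearson variant). If either
#' projection is identically zero the correlation is defined as 0.
#'
#' @param mp a \code{\linkS4class{MatrixPair}}.
#' @param alpha,beta weight vectors of lengths p and q.
#' @param centered center the projections before correlating.
#' @return a number in [-1, 1].
#' @export
canonicalCorrelation <- function(mp, alpha, beta, centered = FALSE) {
  stopifnot(length(alpha) == ncol(targetMatrix(mp)),
            length(beta) == ncol(diseaseMatrix(mp)))
  u <- drop(targetMatrix(mp) %*% alpha)
  v <- drop(diseaseMatrix(mp) %*% beta)
  if (centered) { u <- u - mean(u); v <- v - mean(v) }
  du <- sqrt(sum(u^2)); dv <- sqrt(sum(v^2))
  if (du == 0 || dv == 0) return(0)
  sum(u * v) / (du * dv)
}

#' Fit k canonical components by PMD with deflation
#'
#' Extracts components in order from Z = X'Y: each via
#' \code{\link{fitRank1}} on the current residual, which is then
#' deflated by \code{\link{deflate}}. Each component's canonical
#' correlation rho is computed against the ORIGINAL (undeflated)
#' training matrices, since prediction weights components by their
#' correlation with the data. If the residual vanishes before k
#' components the fit stops early with a warning and the model carries
#' fewer components.
#'
#' @param mp training \code{\linkS4class{MatrixPair}}.
#' @param k number of components, 1 <= k <= min(p, q).
#' @param c1,c2 sparsity parameters in (0, 1]; the L1 bounds are
#'   c1*sqrt(p) and c2*sqrt(q) and must be >= 1 (error otherwise).
#'   Ignored in OCCA mode.
#' @param mode \code{"SCCA"} (default) or \code{"OCCA"}.
#' @param cfg a \code{\link{fitConfig}}.
#' @return a \code{\linkS4class{ComponentModel}}.
#' @examples
#' gen <- generatePlanted(plantedSpec(m = 60, p = 30, q = 20,
#'                                    nComponents = 2, seed = 1))
#' fitSCCA(gen$pair, k = 2, c1 = 0.4, c2 = 0.4)
#' @export
fitSCCA <- function(mp, k, c1 = 0.1, c2 = 0.1, mode = c("SCCA", "OCCA"),
                    cfg = fitConfig()) {
  mode <- match.arg(mode)
  Z <- crossProduct(mp)
  p <- nrow(Z); q <- ncol(Z)
  if (k < 1 || k > min(p, q))
    stop(sprintf("k must lie in [1, min(p, q)] = [1, %d]", min(p, q)),
         call. = FALSE)
  c1Bound <- c2Bound <- NA_real_
  if (mode == "SCCA") {
    stopifnot(c1 > 0, c1 <= 1, c2 > 0, c2 <= 1)
    c1Bound <- c1 * sqrt(p); c2Bound <- c2 * sqrt(q)
    if (c1Bound < 1)
      stop(sprintf("infeasible c1 = %g: c1*sqrt(p) = %g < 1", c1, c1Bound),
           call. = FALSE)
    if (c2Bound < 1)
      stop(sprintf("infeasible c2 = %g: c2*sqrt(q) = %g < 1", c2, c2Bound),
           call. = FALSE)
  }
  z0 <- sqrt(sum(Z^2))
  comps <- vector("list", k)
  nFit <- 0L
  for (i in seq_len(k)) {
    if (sqrt(sum(Z^2)) < cfg$tol * z0) {
      warning(sprintf(
        "residual vanished after %d component(s); returning a smaller model",
        nFit))
      break
    }
    comp <- fitRank1(Z, c1Bound, c2Bound, cfg, mode)
    comp$rho <- canonicalCorrelation(mp, comp$alpha, comp$beta)
    Z <- deflate(Z, comp)
    nFit <- i
    comps[[i]] <- comp
  }
  comps <- comps[seq_len(nFit)]
  new("ComponentModel",
      alpha = matrix(vapply(comps, `[[`, numeric(p), "alpha"), nrow = p),
      beta  = matrix(vapply(comps, `[[`, numeric(q), "beta"),  nrow = q),
      d = vapply(comps, `[[`, numeric(1), "d"),
      rho = vapply(comps, `[[`, numeric(1), "rho"),
      c1 = if (mode == "SCCA") c1 else NA_real_,
      c2 = if (mode == "SCCA") c2 else NA_real_,
      mode = mode,
      targetIds = rownames(Z), diseaseIds = colnames(Z),
      iterations = vapply(comps, function(x) as.integer(x$iterations),
                          integer(1)),
      converged = vapply(comps, `[[`, logical(1), "converged"))
}

## evaluate code with a private RNG state, restoring the caller's
localSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
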