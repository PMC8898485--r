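# Fixtures are built in code; nothing is read from disk except files
# the tests themselves write to tempdir().

writeTSV <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

interactionFile <- function(rows, header = "drug_id\ttarget_id\ttarget_class")
  writeTSV(c(header, rows))

associationFile <- function(rows, header = "drug_id\tdisease_id")
  writeTSV(c(header, rows))

# a small 5-drug two-view table with known incidence counts
toyTables <- function() {
  it <- data.frame(
    drug_id = c("d1", "d1", "d1", "d2", "d3", "d3", "d4", "d5", "d5"),
    target_id = c("t1", "t2", "m1", "t1", "t2", "l1", "m1", "t3", "m2"),
    target_class = c("protein", "protein", "miRNA", "protein", "protein",
                     "lncRNA", "miRNA", "protein", "miRNA"))
  at <- data.frame(
    drug_id = c("d1", "d2", "d2", "d3", "d4", "d5"),
    disease_id = c("s1", "s1", "s2", "s3", "s2", "s3"))
  list(it = it, at = at)
}

toyPair <- function() {
  tt <- toyTables()
  buildMatrixPair(tt$it, tt$at)
}

randomPair <- function(m = 40, p = 15, q = 12, seed = 1) {
  set.seed(seed)
  repeat {
    X <- matrix(rbinom(m * p, 1, 0.25), m, p,
                dimnames = list(sprintf("d%02d", 1:m), sprintf("t%02d", 1:p)))
    Y <- matrix(rbinom(m * q, 1, 0.25), m, q,
                dimnames = list(sprintf("d%02d", 1:m), sprintf("s%02d", 1:q)))
    if (all(rowSums(X) > 0) && all(rowSums(Y) > 0) &&
        all(colSums(X) > 0) && all(colSums(Y) > 0)) break
  }
  new("MatrixPair", X = X, Y = Y,
      targetClasses = rep(c("protein", "miRNA", "lncRNA"), length.out = p))
}

# exhaustive-search oracle for the rank-one PMD objective on small Z:
# max over support pairs of the submatrix leading singular pair (kept
# when L1-feasible, plus its L1-projected variant), refined by exact
# closed-form coordinate ascent from 200 random starts
rank1Oracle <- function(Z, c1Bound, c2Bound, nStarts = 200, seed = 99) {
  p <- nrow(Z); q <- ncol(Z)
  obj <- function(a, b) drop(crossprod(a, Z %*% b))
  best <- -Inf
  evalCand <- function(a, b) {
    a <- l1BoundedUnit(a, c1Bound)
    b <- l1BoundedUnit(b, c2Bound)
    # one exact coordinate pass keeps candidates at stationary quality
    for (i in 1:50) {
      a2 <- l1BoundedUnit(drop(Z %*% b), c1Bound)
      b2 <- l1BoundedUnit(drop(crossprod(Z, a2)), c2Bound)
      if (max(abs(b2 - b)) < 1e-10) { a <- a2; b <- b2; break }
      a <- a2; b <- b2
    }
    obj(a, b)
  }
  for (sa in seq_len(2^p - 1)) {
    Sa <- which(bitwAnd(sa, 2^(seq_len(p) - 1)) > 0)
    for (sb in seq_len(2^q - 1)) {
      Sb <- which(bitwAnd(sb, 2^(seq_len(q) - 1)) > 0)
      sv <- svd(Z[Sa, Sb, drop = FALSE], nu = 1, nv = 1)
      a <- numeric(p); b <- numeric(q)
      a[Sa] <- sv$u[, 1]; b[Sb] <- sv$v[, 1]
      if (sum(abs(a)) <= c1Bound && sum(abs(b)) <= c2Bound)
        best <- max(best, abs(obj(a, b)))
      best <- max(best, evalCand(a, b), evalCand(-a, -b))
    }
  }
  set.seed(seed)
  for (i in seq_len(nStarts))
    best <- max(best, evalCand(rnorm(p), rnorm(q)))
  best
}

# O(n^2) Mann-Whitney pair-count oracle for AUC
aucPairOracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# exhaustive-enumeration oracle for the two-sided rank-sum p-value
# (no ties assumed): p = 2 * min(P(W <= w), P(W >= w)), capped at 1
ranksumEnumOracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all.w <- apply(utils::combn(n1 + n2, n1), 2,
                 function(s) sum(seq_len(n1 + n2)[s]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(all.w <= w), mean(all.w >= w)))
}
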