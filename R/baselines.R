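## Jaccard-similarity collaborative filtering baseline (the DBSI
## adaptation): drug-drug similarity on binary target profiles drives a
## neighborhood-weighted average over the known indication rows.

#' Jaccard drug-drug similarity on target profiles
#'
#' sim(a, b) = |T_a intersect T_b| / |T_a union T_b| for the target
#' sets of drugs a and b. An all-zero profile gets similarity 0 against
#' everything (with a warning) and 0 on its own diagonal.
#'
#' @param X binary drug x target matrix with rownames.
#' @return a symmetric m x m matrix in [0, 1] with drug dimnames.
#' @export
jaccardSimilarity <- function(X) {
  sz <- rowSums(X)
  if (any(sz == 0)) warning("drug(s) with empty target profile: similarity 0")
  inter <- tcrossprod(X)
  un <- outer(sz, sz, "+") - inter
  sim <- ifelse(un == 0, 0, inter / un)
  dimnames(sim) <- list(rownames(X), rownames(X))
  sim
}

#' Neighborhood-average indication scores
#'
#' score(d, s) = sum over training drugs d' of sim(d, d') * Y[d', s],
#' divided by the total similarity mass sum sim(d, d') (weighted mean,
#' so scores stay in [0, 1] and comparable across drugs; set
#' \code{normalize = FALSE} for the raw weighted sum). A drug similar
#' to no training drug scores 0 everywhere. Self-similarity is zeroed
#' when a test drug also appears among the training rows.
#'
#' @param sim similarity matrix over all drugs (train + test), from
#'   \code{\link{jaccardSimilarity}} on the combined X.
#' @param Ytrain binary indication matrix, training drugs only, with
#'   rownames.
#' @param testIds character ids of the drugs to score (must be rows of
#'   \code{sim}).
#' @param normalize divide by the similarity mass (default TRUE).
#' @return a matrix of scores, testIds x diseases.
#' @export
cfPredict <- function(sim, Ytrain, testIds, normalize = TRUE) {
  stopifnot(all(testIds %in% rownames(sim)),
            all(rownames(Ytrain) %in% rownames(sim)))
  W <- sim[testIds, rownames(Ytrain), drop = FALSE]
  self <- cbind(match(testIds, testIds), match(testIds, rownames(Ytrain)))
  self <- self[!is.na(self[, 2]), , drop = FALSE]
  W[self] <- 0
  scores <- W %*% Ytrain
  if (normalize) {
    mass <- rowSums(W)
    scores <- scores / ifelse(mass == 0, 1, mass)  # 0/0 -> 0
  }
  dimnames(scores) <- list(testIds, colnames(Ytrain))
  scores
}
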