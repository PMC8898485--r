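## Repeated 10-fold cross-validation over drugs with pooled ROC/AUC
## scoring, parameter-grid sweeps under paired fold seeds, and the
## Wilcoxon rank-sum comparison between methods.

#' Seeded k-fold split of drug indices
#'
#' Shuffles 1..m under the given seed, then cuts consecutive blocks so
#' fold sizes differ by at most one. Deterministic per (m, nFolds,
#' seed); disjoint and covering.
#'
#' @param m number of drugs; must be >= nFolds.
#' @param nFolds number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @return a list of nFolds integer index vectors.
#' @export
kfoldSplit <- function(m, nFolds = 10L, seed = 1L) {
  if (m < nFolds)
    stop(sprintf("cannot split %d drugs into %d folds", m, nFolds),
         call. = FALSE)
  perm <- localSeed(seed, sample.int(m))
  sizes <- rep(m %/% nFolds, nFolds)
  extra <- m %% nFolds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(nFolds), sizes))
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of positive-negative score pairs the
#' positive wins, ties counted one half — computed from midranks, which
#' is algebraically identical to the pair count and equals the area
#' under the empirical ROC curve.
#'
#' @param labels binary 0/1 vector; both classes must be present.
#' @param scores numeric vector of the same length.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties as half-wins
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

scoreTestFold <- function(mp, trainIdx, testIdx, method, k, c1, c2, cfg,
                          sim = NULL) {
  X <- targetMatrix(mp); Y <- diseaseMatrix(mp)
  q <- ncol(Y)
  scores <- matrix(0, length(testIdx), q,
                   dimnames = list(rownames(X)[testIdx], colnames(Y)))
  if (method == "JaccardCF") {
    scores[] <- cfPredict(sim, Y[trainIdx, , drop = FALSE],
                          rownames(X)[testIdx])
  } else {
    trainPair <- subsetDrugs(mp, trainIdx)
    model <- fitSCCA(trainPair, k = min(k, ncol(targetMatrix(trainPair)),
                                        ncol(diseaseMatrix(trainPair))),
                     c1 = c1, c2 = c2, mode = method, cfg = cfg)
    for (i in seq_along(testIdx)) {
      ps <- scoreDrug(model, X[testIdx[i], ], quiet = TRUE)
      scores[i, names(ps$scores)] <- ps$scores
    }
  }
  scores
}

## row subset of a MatrixPair; drops the columns the kept drugs never use
subsetDrugs <- function(mp, idx) {
  X <- targetMatrix(mp)[idx, , drop = FALSE]
  Y <- diseaseMatrix(mp)[idx, , drop = FALSE]
  keepT <- colSums(X) > 0; keepD <- colSums(Y) > 0
  new("MatrixPair", X = X[, keepT, drop = FALSE],
      Y = Y[, keepD, drop = FALSE],
      targetClasses = mp@targetClasses[keepT])
}

#' Repeated k-fold cross-validation over drugs
#'
#' For each repeat (one fold seed per repeat) and each fold: the model
#' is fitted on the training drugs only, every test drug is scored
#' against all diseases, and all (test drug, disease) cells of the fold
#' are POOLED into a single ROC whose AUC is recorded (micro pooling;
#' per-drug macro averaging is available via \code{pooling = "macro"},
#' where drugs whose held-out row is single-class are skipped).
#' Held-out positives are the drug's known associations; every
#' unobserved cell counts as negative (positive-unlabeled convention).
#' Bit-reproducible given the same seeds.
#'
#' @param mp a \code{\linkS4class{MatrixPair}}.
#' @param method \code{"SCCA"}, \code{"OCCA"} or \code{"JaccardCF"}.
#' @param k,c1,c2 model parameters (ignored for JaccardCF; c1, c2
#'   ignored for OCCA).
#' @param nFolds,nRepeats cross-validation geometry (defaults 10 x 10).
#' @param seeds one fold seed per repeat; default \code{seed + 0:(nRepeats-1)}.
#' @param seed base seed used when \code{seeds} is NULL.
#' @param pooling \code{"micro"} (pool all cells per fold) or
#'   \code{"macro"} (mean of per-drug AUCs).
#' @param cfg a \code{\link{fitConfig}} for the inner fits.
#' @return a \code{\linkS4class{CVReport}}.
#' @export
crossValidate <- function(mp, method = c("SCCA", "OCCA", "JaccardCF"),
                          k = 400L, c1 = 0.1, c2 = 0.1,
                          nFolds = 10L, nRepeats = 10L, seeds = NULL,
                          seed = 1L, pooling = c("micro", "macro"),
                          cfg = fitConfig()) {
  method <- match.arg(method)
  pooling <- match.arg(pooling)
  if (is.null(seeds)) seeds <- seed + seq_len(nRepeats) - 1L
  stopifnot(length(seeds) == nRepeats, nFolds >= 2)
  m <- nrow(targetMatrix(mp))
  Y <- diseaseMatrix(mp)
  sim <- if (method == "JaccardCF") jaccardSimilarity(targetMatrix(mp))
  aucMat <- matrix(NA_real_, nRepeats, nFolds)
  for (r in seq_len(nRepeats)) {
    folds <- kfoldSplit(m, nFolds, seeds[r])
    for (f in seq_len(nFolds)) {
      testIdx <- folds[[f]]
      trainIdx <- sort(unlist(folds[-f], use.names = FALSE))
      scores <- scoreTestFold(mp, trainIdx, testIdx, method, k, c1, c2,
                              cfg, sim)
      truth <- Y[testIdx, , drop = FALSE]
      if (pooling == "micro") {
        if (length(unique(as.vector(truth))) < 2) {
          warning(sprintf("repeat %d fold %d skipped: single-class labels",
                          r, f))
          next
        }
        aucMat[r, f] <- aucScore(as.vector(truth), as.vector(scores))
      } else {
        ok <- rowSums(truth) > 0 & rowSums(truth) < ncol(truth)
        if (!any(ok)) {
          warning(sprintf("repeat %d fold %d skipped: no scorable drugs",
                          r, f))
          next
        }
        aucMat[r, f] <- mean(vapply(which(ok), function(i)
          aucScore(truth[i, ], scores[i, ]), numeric(1)))
      }
    }
  }
  perRepeat <- rowMeans(aucMat, na.rm = TRUE)
  new("CVReport", aucPerFold = aucMat, aucPerRepeat = perRepeat,
      meanAUC = mean(perRepeat), sdAUC = stats::sd(perRepeat),
      config = list(method = method, k = k, c1 = c1, c2 = c2,
                    nFolds = nFolds, nRepeats = nRepeats, seeds = seeds,
                    pooling = pooling))
}

#' Cross-validated AUC over a (c, k) parameter grid
#'
#' Runs \code{\link{crossValidate}} once per grid cell with the SAME
#' fold seeds everywhere (paired design), so cells are directly
#' comparable. Cells whose sparsity bound is infeasible for the data
#' dimensions are marked, not fatal.
#'
#' @param mp a \code{\linkS4class{MatrixPair}}.
#' @param cGrid values used for both c1 and c2 (the usual tuning ties
#'   them together).
#' @param kGrid component counts.
#' @param method \code{"SCCA"} or \code{"OCCA"}.
#' @inheritParams crossValidate
#' @return a \code{data.frame} with columns \code{c}, \code{k},
#'   \code{meanAUC}, \code{sdAUC}, \code{feasible}.
#' @export
parameterSweep <- function(mp, cGrid, kGrid, method = "SCCA",
                           nFolds = 10L, nRepeats = 10L, seeds = NULL,
                           seed = 1L, cfg = fitConfig()) {
  stopifnot(length(cGrid) >= 1, length(kGrid) >= 1)
  if (is.null(seeds)) seeds <- seed + seq_len(nRepeats) - 1L
  grid <- expand.grid(c = cGrid, k = kGrid, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cc <- grid$c[i]; kk <- grid$k[i]
    rep <- tryCatch(
      crossValidate(mp, method = method, k = kk, c1 = cc, c2 = cc,
                    nFolds = nFolds, nRepeats = nRepeats, seeds = seeds,
                    cfg = cfg),
      error = function(e) e)
    if (inherits(rep, "error"))
      data.frame(c = cc, k = kk, meanAUC = NA_real_, sdAUC = NA_real_,
                 feasible = FALSE)
    else
      data.frame(c = cc, k = kk, meanAUC = meanAUC(rep),
                 sdAUC = sdAUC(rep), feasible = TRUE)
  })
  do.call(rbind, res)
}

#' Two-sided Wilcoxon rank-sum test between two AUC samples
#'
#' Exact null distribution when the combined sample size is <= 25 and
#' there are no ties; otherwise the normal approximation with tie
#' correction (and continuity correction).
#'
#' @param aucA,aucB numeric vectors, each of length >= 2.
#' @return the two-sided p-value.
#' @export
rankSumTest <- function(aucA, aucB) {
  stopifnot(length(aucA) >= 2, length(aucB) >= 2)
  n <- length(aucA) + length(aucB)
  exact <- n <= 25 && !anyDuplicated(c(aucA, aucB))
  suppressWarnings(
    stats::wilcox.test(aucA, aucB, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}

#' Write a CVReport as TSV plus a JSON run manifest
#'
#' @param report a \code{\linkS4class{CVReport}}.
#' @param path output TSV path (one row per repeat x fold plus the
#'   aggregate); the manifest is written next to it as
#'   \code{<path>.manifest.json}.
#' @return invisibly, \code{path}.
#' @export
writeCVReport <- function(report, path) {
  a <- aucPerFold(report)
  long <- data.frame(repeat_index = rep(seq_len(nrow(a)), ncol(a)),
                     fold = rep(seq_len(ncol(a)), each = nrow(a)),
                     auc = as.vector(a))
  utils::write.table(long[order(long$repeat_index, long$fold), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(report@config,
                list(mean_auc = meanAUC(report), sd_auc = sdAUC(report),
                     auc_per_repeat = aucPerRepeat(report)))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
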