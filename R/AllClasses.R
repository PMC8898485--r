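#' @import methods
NULL

TARGET_CLASSES <- c("protein", "miRNA", "lncRNA")

#' MatrixPair: aligned binary drug-by-target and drug-by-disease matrices
#'
#' Holds the two views of a drug set: a binary drug x target incidence
#' matrix \code{X} (m x p) and a binary drug x disease incidence matrix
#' \code{Y} (m x q) sharing one drug ordering. Every row and every column
#' of both matrices carries at least one nonzero entry; drugs lacking
#' either targets or indications, and unused target/disease columns, are
#' excluded at construction time by \code{\link{buildMatrixPair}}.
#'
#' @slot X binary numeric matrix, drugs x targets, with dimnames.
#' @slot Y binary numeric matrix, drugs x diseases, with dimnames.
#' @slot targetClasses character vector aligned to \code{colnames(X)},
#'   each one of \code{"protein"}, \code{"miRNA"}, \code{"lncRNA"}.
#'
#' @seealso \code{\link{buildMatrixPair}}, \code{\link{summarizeMatrixPair}}
#' @export
setClass("MatrixPair",
  representation(X = "matrix", Y = "matrix", targetClasses = "character"))

setValidity("MatrixPair", function(object) {
  X <- object@X; Y <- object@Y
  msg <- character()
  if (is.null(rownames(X)) || is.null(colnames(X)) ||
      is.null(rownames(Y)) || is.null(colnames(Y)))
    msg <- c(msg, "X and Y must have full dimnames")
  else if (!identical(rownames(X), rownames(Y)))
    msg <- c(msg, "X and Y must share an identical drug (row) ordering")
  if (!all(X %in% c(0, 1)) || !all(Y %in% c(0, 1)))
    msg <- c(msg, "entries of X and Y must be 0 or 1")
  if (nrow(X) > 0) {
    if (any(rowSums(X) == 0) || any(rowSums(Y) == 0))
      msg <- c(msg, "every drug must have >=1 target and >=1 disease")
    if (any(colSums(X) == 0) || any(colSums(Y) == 0))
      msg <- c(msg, "every target and disease column must be nonzero")
  }
  if (length(object@targetClasses) != ncol(X))
    msg <- c(msg, "targetClasses must align with the columns of X")
  if (!all(object@targetClasses %in% TARGET_CLASSES))
    msg <- c(msg, sprintf("targetClasses must be in {%s}",
                          paste(TARGET_CLASSES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn MatrixPair compact summary of dimensions and density
#' @param object a \code{MatrixPair}
#' @export
setMethod("show", "MatrixPair", function(object) {
  cat(sprintf("MatrixPair: %d drugs x (%d targets | %d diseases)\n",
              nrow(object@X), ncol(object@X), ncol(object@Y)))
  tc <- table(factor(object@targetClasses, levels = TARGET_CLASSES))
  cat(sprintf("  target classes: %s\n",
              paste(sprintf("%s=%d", names(tc), tc), collapse = ", ")))
  cat(sprintf("  nonzeros: %d drug-target, %d drug-disease\n",
              sum(object@X), sum(object@Y)))
})

#' ComponentModel: an ordered set of fitted canonical components
#'
#' Result of \code{\link{fitSCCA}}. Component i is the quadruple
#' (alpha_i, beta_i, d_i, rho_i): sparse target and disease weight
#' vectors (columns i of \code{alpha} and \code{beta}), the singular
#' value d_i of the rank-one decomposition step, and the canonical
#' correlation rho_i of the projections X alpha_i and Y beta_i on the
#' original training data.
#'
#' @slot alpha numeric p x k matrix of target weights (unit L2 columns).
#' @slot beta numeric q x k matrix of disease weights (unit L2 columns).
#' @slot d numeric length-k vector of decomposition singular values.
#' @slot rho numeric length-k vector of canonical correlations.
#' @slot c1,c2 sparsity parameters in (0, 1] (NA_real_ in OCCA mode).
#' @slot mode "SCCA" or "OCCA".
#' @slot targetIds,diseaseIds training column registries.
#' @slot iterations integer per-component inner iteration counts.
#' @slot converged logical per-component convergence flags.
#'
#' @export
setClass("ComponentModel",
  representation(alpha = "matrix", beta = "matrix",
                 d = "numeric", rho = "numeric",
                 c1 = "numeric", c2 = "numeric", mode = "character",
                 targetIds = "character", diseaseIds = "character",
                 iterations = "integer", converged = "logical"))

setValidity("ComponentModel", function(object) {
  k <- ncol(object@alpha)
  msg <- character()
  if (ncol(object@beta) != k || length(object@d) != k ||
      length(object@rho) != k || length(object@iterations) != k ||
      length(object@converged) != k)
    msg <- c(msg, "component count must agree across slots")
  if (nrow(object@alpha) != length(object@targetIds))
    msg <- c(msg, "alpha rows must match targetIds")
  if (nrow(object@beta) != length(object@diseaseIds))
    msg <- c(msg, "beta rows must match diseaseIds")
  if (!object@mode %in% c("SCCA", "OCCA"))
    msg <- c(msg, "mode must be SCCA or OCCA")
  if (any(object@d < -1e-8))
    msg <- c(msg, "singular values d must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @describeIn ComponentModel print k, mode, sparsity and per-component d/rho
#' @param object a \code{ComponentModel}
#' @export
setMethod("show", "ComponentModel", function(object) {
  k <- nComponents(object)
  cat(sprintf("ComponentModel: %s, k = %d (%d targets, %d diseases)\n",
              object@mode, k, length(object@targetIds),
              length(object@diseaseIds)))
  if (object@mode == "SCCA")
    cat(sprintf("  c1 = %g, c2 = %g\n", object@c1, object@c2))
  show_k <- seq_len(min(k, 5L))
  cat(sprintf("  d   = %s%s\n",
              paste(signif(object@d[show_k], 4), collapse = ", "),
              if (k > 5) ", ..." else ""))
  cat(sprintf("  rho = %s%s\n",
              paste(signif(object@rho[show_k], 4), collapse = ", "),
              if (k > 5) ", ..." else ""))
  if (!all(object@converged))
    cat(sprintf("  warning: %d component(s) did not converge\n",
                sum(!object@converged)))
})

#' CVReport: AUC values from repeated k-fold cross-validation
#'
#' @slot aucPerFold numeric nRepeats x nFolds matrix of pooled per-fold
#'   AUCs (NA where a fold was skipped for single-class labels).
#' @slot aucPerRepeat per-repeat means over folds.
#' @slot meanAUC,sdAUC mean and standard deviation of the per-repeat means.
#' @slot config list echoing method, parameters, fold seeds and pooling.
#'
#' @export
setClass("CVReport",
  representation(aucPerFold = "matrix", aucPerRepeat = "numeric",
                 meanAUC = "numeric", sdAUC = "numeric", config = "list"))

setValidity("CVReport", function(object) {
  msg <- character()
  if (length(object@aucPerRepeat) != nrow(object@aucPerFold))
    msg <- c(msg, "one per-repeat AUC per row of aucPerFold")
  a <- object@aucPerFold[!is.na(object@aucPerFold)]
  if (length(a) && (any(a < 0) || any(a > 1)))
    msg <- c(msg, "AUC values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn CVReport print mean AUC +/- sd and the grid shape
#' @param object a \code{CVReport}
#' @export
setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %s, %d repeats x %d folds\n",
              object@config$method %||% "?",
              nrow(object@aucPerFold), ncol(object@aucPerFold)))
  cat(sprintf("  AUC = %.4f +/- %.4f\n", object@meanAUC, object@sdAUC))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
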