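#' Accessors for MatrixPair and ComponentModel
#'
#' Small accessor functions in place of direct slot access.
#'
#' @param x a \code{MatrixPair} or \code{ComponentModel}
#' @return \code{targetMatrix}/\code{diseaseMatrix}: the binary incidence
#'   matrix; \code{drugIds}/\code{targetIds}/\code{diseaseIds}: character
#'   label vectors; \code{targetClasses}: per-target class labels;
#'   \code{nComponents}: integer; \code{componentWeights}: list with
#'   \code{alpha}, \code{beta} weight matrices; \code{singularValues} and
#'   \code{canonicalCorrelations}: numeric vectors.
#' @name accessors
NULL

#' @rdname accessors
#' @export
targetMatrix <- function(x) x@X

#' @rdname accessors
#' @export
diseaseMatrix <- function(x) x@Y

#' @rdname accessors
#' @export
drugIds <- function(x) rownames(x@X)

#' @rdname accessors
#' @export
targetIds <- function(x) {
  if (is(x, "ComponentModel")) x@targetIds else colnames(x@X)
}

#' @rdname accessors
#' @export
diseaseIds <- function(x) {
  if (is(x, "ComponentModel")) x@diseaseIds else colnames(x@Y)
}

#' @rdname accessors
#' @export
targetClasses <- function(x) stats::setNames(x@targetClasses, colnames(x@X))

#' @rdname accessors
#' @export
nComponents <- function(x) ncol(x@alpha)

#' @rdname accessors
#' @export
componentWeights <- function(x) list(alpha = x@alpha, beta = x@beta)

#' @rdname accessors
#' @export
singularValues <- function(x) x@d

#' @rdname accessors
#' @export
canonicalCorrelations <- function(x) x@rho

#' @rdname accessors
#' @export
aucPerFold <- function(x) x@aucPerFold

#' @rdname accessors
#' @export
aucPerRepeat <- function(x) x@aucPerRepeat

#' @rdname accessors
#' @export
meanAUC <- function(x) x@meanAUC

#' @rdname accessors
#' @export
sdAUC <- function(x) x@sdAUC
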