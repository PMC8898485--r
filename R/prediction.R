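## Indication scoring: y_new = sum_i beta_i rho_i alpha_i' x_new, i.e.
## B diag(rho) A' x_new over the model's components, plus ranking and
## per-component correlated-set export.

#' Score candidate indications for one drug
#'
#' Computes the prediction vector y_new = sum over components of
#' beta_i * rho_i * (alpha_i' x_new) for a drug described by its target
#' set. Targets unknown to the model are ignored (new drugs routinely
#' carry targets absent from training); their count is reported.
#'
#' @param model a \code{\linkS4class{ComponentModel}}.
#' @param targets the drug's targets: either a character vector of
#'   target ids or a named binary vector (names = target ids).
#' @param drugId identifier carried through to the output.
#' @param known character vector of the drug's already-known disease
#'   ids, used to flag which scores are novel.
#' @param quiet suppress the unknown-target message.
#' @return a list of class \code{PredictionScores} with elements
#'   \code{drug_id}, \code{scores} (named numeric over the model's
#'   diseases) and \code{novel} (logical mask, TRUE where no known
#'   association).
#' @export
scoreDrug <- function(model, targets, drugId = "drug", known = character(),
                      quiet = FALSE) {
  stopifnot(is(model, "ComponentModel"))
  tid <- targetIds(model)
  if (is.character(targets)) {
    x <- as.numeric(tid %in% targets)
    nUnknown <- sum(!targets %in% tid)
  } else {
    if (is.null(names(targets)))
      stop("binary target vectors must be named by target id", call. = FALSE)
    nUnknown <- sum(!names(targets)[targets != 0] %in% tid)
    x <- as.numeric(targets[match(tid, names(targets))])
    x[is.na(x)] <- 0
  }
  if (nUnknown > 0 && !quiet)
    message(sprintf("%s: ignored %d target(s) not in the model", drugId,
                    nUnknown))
  if (length(x) != nrow(model@alpha))
    stop("target vector does not align with the model", call. = FALSE)
  s <- drop(model@beta %*% (canonicalCorrelations(model) *
                              drop(crossprod(model@alpha, x))))
  names(s) <- diseaseIds(model)
  structure(list(drug_id = drugId, scores = s,
                 novel = !diseaseIds(model) %in% known),
            class = "PredictionScores")
}

#' Rank predicted indications
#'
#' Orders diseases by descending score, ties broken lexicographically
#' by disease id so output is deterministic. Known associations (the
#' \code{novel == FALSE} entries) are excluded by default, matching the
#' repositioning use where only new indications are of interest.
#'
#' @param ps a \code{PredictionScores} from \code{\link{scoreDrug}}.
#' @param excludeKnown drop diseases already associated with the drug.
#' @param topN keep at most this many rows.
#' @return a \code{data.frame} with columns \code{drug_id},
#'   \code{disease_id}, \code{score}, \code{rank}.
#' @export
rankIndications <- function(ps, excludeKnown = TRUE, topN = 50L) {
  stopifnot(topN >= 1)
  keep <- if (excludeKnown) ps$novel else rep(TRUE, length(ps$scores))
  s <- ps$scores[keep]
  if (length(s) == 0) {
    warning(sprintf("%s: no candidate diseases left to rank", ps$drug_id))
    return(data.frame(drug_id = character(), disease_id = character(),
                      score = numeric(), rank = integer()))
  }
  ord <- order(-s, names(s), method = "radix")
  s <- s[ord]
  n <- min(length(s), as.integer(topN))
  data.frame(drug_id = ps$drug_id, disease_id = names(s)[seq_len(n)],
             score = unname(s[seq_len(n)]), rank = seq_len(n))
}

#' Extract the correlated set of one component
#'
#' The correlated set of component i is its strictly positive-weight
#' targets and diseases, each side sorted by decreasing weight with
#' competition ranking (tied weights share a rank; the next distinct
#' weight skips accordingly). Interpreted as one mechanism-of-action
#' hypothesis: drugs hitting the top targets may treat the top diseases.
#'
#' @param model a \code{\linkS4class{ComponentModel}}.
#' @param index component index, 1 <= index <= k.
#' @param topN optional truncation of each side after ranking.
#' @return a list of class \code{CorrelatedSet} with
#'   \code{component}, and data.frames \code{targets}, \code{diseases}
#'   (columns \code{id}, \code{weight}, \code{rank}).
#' @export
extractCorrelatedSet <- function(model, index, topN = Inf) {
  stopifnot(is(model, "ComponentModel"))
  if (index < 1 || index > nComponents(model))
    stop(sprintf("component index %d out of range [1, %d]", index,
                 nComponents(model)), call. = FALSE)
  side <- function(w, ids, what) {
    pos <- w > 0
    if (!any(pos)) {
      warning(sprintf("component %d has no positive %s weights", index, what))
      return(data.frame(id = character(), weight = numeric(),
                        rank = integer()))
    }
    w <- w[pos]; ids <- ids[pos]
    ord <- order(-w, ids, method = "radix")
    w <- w[ord]; ids <- ids[ord]
    rk <- rank(-w, ties.method = "min")  # competition ranking
    n <- min(length(w), topN)
    data.frame(id = ids[seq_len(n)], weight = w[seq_len(n)],
               rank = as.integer(rk[seq_len(n)]))
  }
  structure(list(component = as.integer(index),
                 targets = side(model@alpha[, index], targetIds(model),
                                "target"),
                 diseases = side(model@beta[, index], diseaseIds(model),
                                 "disease")),
            class = "CorrelatedSet")
}

fmtFloat <- function(x) sprintf("%.17g", x)

#' Serialize a ComponentModel to a two-file TSV format
#'
#' Writes (1) a weights TSV with columns \code{component}, \code{side}
#' (\code{target}/\code{disease}), \code{feature_id}, \code{weight}
#' containing every entry of alpha and beta in training column order,
#' and (2) a header TSV of \code{key}/\code{value} rows carrying k, c1,
#' c2, mode and the comma-joined d, rho, iteration and convergence
#' vectors. Floats are written with 17 significant digits so the
#' round-trip through \code{\link{readComponentModel}} is bit-exact.
#'
#' @param model a \code{\linkS4class{ComponentModel}}.
#' @param weightsPath,headerPath output paths.
#' @return invisibly, the two paths.
#' @export
writeComponentModel <- function(model, weightsPath, headerPath) {
  k <- nComponents(model)
  p <- length(targetIds(model)); q <- length(diseaseIds(model))
  wt <- data.frame(
    component = rep(seq_len(k), each = p + q),
    side = rep(rep(c("target", "disease"), c(p, q)), k),
    feature_id = rep(c(targetIds(model), diseaseIds(model)), k),
    weight = fmtFloat(as.vector(rbind(model@alpha, model@beta))))
  utils::write.table(wt, weightsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hdr <- data.frame(
    key = c("k", "c1", "c2", "mode", "d", "rho", "iterations", "converged"),
    value = c(k, fmtFloat(model@c1), fmtFloat(model@c2), model@mode,
              paste(fmtFloat(model@d), collapse = ","),
              paste(fmtFloat(model@rho), collapse = ","),
              paste(model@iterations, collapse = ","),
              paste(model@converged, collapse = ",")))
  utils::write.table(hdr, headerPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(weightsPath, headerPath))
}

#' Read a ComponentModel written by \code{\link{writeComponentModel}}
#'
#' @param weightsPath,headerPath the two files.
#' @return a \code{\linkS4class{ComponentModel}}.
#' @export
readComponentModel <- function(weightsPath, headerPath) {
  hdr <- utils::read.delim(headerPath, colClasses = "character")
  hv <- stats::setNames(hdr$value, hdr$key)
  splitNum <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  k <- as.integer(hv[["k"]])
  wt <- utils::read.delim(weightsPath, colClasses = "character")
  one <- wt[wt$component == "1", ]
  tid <- one$feature_id[one$side == "target"]
  did <- one$feature_id[one$side == "disease"]
  w <- as.numeric(wt$weight)
  isT <- wt$side == "target"
  new("ComponentModel",
      alpha = matrix(w[isT], nrow = length(tid), ncol = k),
      beta = matrix(w[!isT], nrow = length(did), ncol = k),
      d = splitNum(hv[["d"]]), rho = splitNum(hv[["rho"]]),
      c1 = as.numeric(hv[["c1"]]), c2 = as.numeric(hv[["c2"]]),
      mode = hv[["mode"]], targetIds = tid, diseaseIds = did,
      iterations = as.integer(strsplit(hv[["iterations"]], ",")[[1]]),
      converged = as.logical(strsplit(hv[["converged"]], ",")[[1]]))
}

#' Export correlated sets of all components as one TSV
#'
#' Long-format TSV with columns \code{component}, \code{side},
#' \code{feature_id}, \code{weight}, \code{rank}; positive-weight
#' entries only, competition-ranked per component and side.
#'
#' @param model a \code{\linkS4class{ComponentModel}}.
#' @param path output TSV path.
#' @param topN optional per-side truncation.
#' @return invisibly, \code{path}.
#' @export
writeCorrelatedSets <- function(model, path, topN = Inf) {
  rows <- lapply(seq_len(nComponents(model)), function(i) {
    cs <- suppressWarnings(extractCorrelatedSet(model, i, topN))
    rbind(
      if (nrow(cs$targets))
        cbind(component = i, side = "target", cs$targets),
      if (nrow(cs$diseases))
        cbind(component = i, side = "disease", cs$diseases))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "id"] <- "feature_id"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
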