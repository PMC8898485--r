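## Reading, validating and binarizing the two long-format input tables,
## and assembling the aligned MatrixPair. Identifiers are opaque strings:
## whitespace-trimmed, case preserved. All orderings are lexicographic in
## the C locale (radix sort) so results never depend on file row order.

sortIds <- function(x) sort(unique(x), method = "radix")

readDelimTable <- function(path, delim, minCols, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < minCols)
    stop(sprintf("%s file must have >= %d columns, found %d: %s",
                 what, minCols, ncol(df), path), call. = FALSE)
  df[] <- lapply(df, trimws)
  df
}

#' Read a drug-target interaction table
#'
#' Reads a delimited long-format table whose first three columns are
#' drug id, target id and target class (one of \code{protein},
#' \code{miRNA}, \code{lncRNA}). One header line is required. Duplicate
#' (drug, target) pairs are collapsed and their count reported. The
#' loader consumes already-filtered tables; any upstream selection
#' (species, approval status) is the caller's responsibility.
#'
#' @param path path to the file.
#' @param delim field delimiter, tab by default; pass \code{","} for CSV.
#' @return a \code{data.frame} with columns \code{drug_id},
#'   \code{target_id}, \code{target_class}.
#' @seealso \code{\link{readAssociations}}, \code{\link{buildMatrixPair}}
#' @export
readInteractions <- function(path, delim = "\t") {
  df <- readDelimTable(path, delim, 3L, "interaction")
  df <- stats::setNames(df[, 1:3],
                        c("drug_id", "target_id", "target_class"))
  bad <- which(!df$target_class %in% TARGET_CLASSES)
  if (length(bad))
    stop(sprintf(
      "unknown target_class '%s' at data row %d (allowed: %s)",
      df$target_class[bad[1]], bad[1],
      paste(TARGET_CLASSES, collapse = ", ")), call. = FALSE)
  dup <- duplicated(df[, c("drug_id", "target_id")])
  if (any(dup))
    message(sprintf("collapsed %d duplicate drug-target pair(s)", sum(dup)))
  df <- df[!dup, , drop = FALSE]
  if (nrow(df) == 0) warning("interaction table is empty")
  message(sprintf("read %d drug-target interaction(s) from %s",
                  nrow(df), path))
  rownames(df) <- NULL
  df
}

#' Read a drug-disease association table
#'
#' Reads a delimited long-format table whose first two columns are drug
#' id and disease id; one header line required; duplicates collapsed.
#'
#' @inheritParams readInteractions
#' @return a \code{data.frame} with columns \code{drug_id},
#'   \code{disease_id}.
#' @export
readAssociations <- function(path, delim = "\t") {
  df <- readDelimTable(path, delim, 2L, "association")
  df <- stats::setNames(df[, 1:2], c("drug_id", "disease_id"))
  dup <- duplicated(df)
  if (any(dup))
    message(sprintf("collapsed %d duplicate drug-disease pair(s)", sum(dup)))
  df <- df[!dup, , drop = FALSE]
  if (nrow(df) == 0) warning("association table is empty")
  message(sprintf("read %d drug-disease association(s) from %s",
                  nrow(df), path))
  rownames(df) <- NULL
  df
}

#' Build the aligned binary matrix pair
#'
#' Restricts both tables to drugs carrying at least one target of a
#' selected class AND at least one disease, then binarizes into a
#' \code{\linkS4class{MatrixPair}}. Columns never used by a retained drug
#' are dropped. Rows and columns are ordered lexicographically by id.
#'
#' @param interactions a deduplicated interaction \code{data.frame}
#'   (from \code{\link{readInteractions}} or equivalent).
#' @param associations a deduplicated association \code{data.frame}.
#' @param classes target classes to keep; default all three. Restricting
#'   (e.g. \code{"protein"}) reproduces single-view ablation runs.
#' @return a \code{\linkS4class{MatrixPair}}.
#' @examples
#' it <- data.frame(drug_id = c("a", "a", "b"),
#'                  target_id = c("t1", "t2", "t1"),
#'                  target_class = "protein")
#' at <- data.frame(drug_id = c("a", "b"), disease_id = c("d1", "d2"))
#' buildMatrixPair(it, at)
#' @export
buildMatrixPair <- function(interactions, associations,
                            classes = TARGET_CLASSES) {
  classes <- match.arg(classes, TARGET_CLASSES, several.ok = TRUE)
  it <- interactions[interactions$target_class %in% classes, , drop = FALSE]
  drugs <- intersect(sortIds(it$drug_id), sortIds(associations$drug_id))
  if (length(drugs) == 0)
    stop("no drugs with both views (targets of the selected classes and diseases)",
         call. = FALSE)
  it <- it[it$drug_id %in% drugs, , drop = FALSE]
  at <- associations[associations$drug_id %in% drugs, , drop = FALSE]
  targets  <- sortIds(it$target_id)
  diseases <- sortIds(at$disease_id)
  X <- matrix(0, length(drugs), length(targets),
              dimnames = list(drugs, targets))
  X[cbind(it$drug_id, it$target_id)] <- 1
  Y <- matrix(0, length(drugs), length(diseases),
              dimnames = list(drugs, diseases))
  Y[cbind(at$drug_id, at$disease_id)] <- 1
  cls <- it$target_class[match(targets, it$target_id)]
  new("MatrixPair", X = X, Y = Y, targetClasses = cls)
}

#' Summary statistics of a MatrixPair
#'
#' Counts drugs, targets (total and per class), diseases, interactions
#' (total and per class) and associations, plus the mean number of
#' targets and diseases per drug. Means are exact ratios; rounding is
#' left to display.
#'
#' @param mp a \code{\linkS4class{MatrixPair}}.
#' @return a list of class \code{DatasetSummary}.
#' @export
summarizeMatrixPair <- function(mp) {
  stopifnot(is(mp, "MatrixPair"))
  X <- targetMatrix(mp); Y <- diseaseMatrix(mp)
  cls <- mp@targetClasses
  perClassTargets <- vapply(TARGET_CLASSES,
                            function(cl) sum(cls == cl), integer(1))
  perClassInter <- vapply(TARGET_CLASSES,
                          function(cl) sum(X[, cls == cl, drop = FALSE]),
                          numeric(1))
  out <- list(
    n_drugs = nrow(X),
    n_targets = ncol(X),
    n_targets_per_class = perClassTargets,
    n_diseases = ncol(Y),
    n_interactions = sum(X),
    n_interactions_per_class = perClassInter,
    n_associations = sum(Y),
    mean_targets_per_drug = sum(X) / nrow(X),
    mean_diseases_per_drug = sum(Y) / nrow(Y))
  class(out) <- "DatasetSummary"
  out
}

#' @export
print.DatasetSummary <- function(x, ...) {
  cat("Dataset summary\n")
  cat(sprintf("  drugs:        %d\n", x$n_drugs))
  cat(sprintf("  targets:      %d (%s)\n", x$n_targets,
              paste(sprintf("%s=%d", names(x$n_targets_per_class),
                            x$n_targets_per_class), collapse = ", ")))
  cat(sprintf("  diseases:     %d\n", x$n_diseases))
  cat(sprintf("  interactions: %d (%s)\n", x$n_interactions,
              paste(sprintf("%s=%d", names(x$n_interactions_per_class),
                            x$n_interactions_per_class), collapse = ", ")))
  cat(sprintf("  associations: %d\n", x$n_associations))
  cat(sprintf("  mean targets/drug:  %.1f\n", x$mean_targets_per_drug))
  cat(sprintf("  mean diseases/drug: %.1f\n", x$mean_diseases_per_drug))
  invisible(x)
}

#' Write a MatrixPair back to long-format TSV tables
#'
#' Inverse of \code{\link{readInteractions}} /
#' \code{\link{readAssociations}} + \code{\link{buildMatrixPair}}:
#' re-reading and rebuilding reproduces identical matrices.
#'
#' @param mp a \code{\linkS4class{MatrixPair}}.
#' @param interactionsPath,associationsPath output TSV paths.
#' @return invisibly, the two paths.
#' @export
writeMatrixPair <- function(mp, interactionsPath, associationsPath) {
  X <- targetMatrix(mp); Y <- diseaseMatrix(mp)
  ix <- which(X == 1, arr.ind = TRUE)
  it <- data.frame(drug_id = rownames(X)[ix[, 1]],
                   target_id = colnames(X)[ix[, 2]],
                   target_class = mp@targetClasses[ix[, 2]])
  iy <- which(Y == 1, arr.ind = TRUE)
  at <- data.frame(drug_id = rownames(Y)[iy[, 1]],
                   disease_id = colnames(Y)[iy[, 2]])
  utils::write.table(it, interactionsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(at, associationsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(interactionsPath, associationsPath))
}

#' Write a DatasetSummary as TSV
#'
#' @param x a \code{DatasetSummary}.
#' @param path output TSV path (columns \code{statistic}, \code{value}).
#' @return invisibly, \code{path}.
#' @export
writeDatasetSummary <- function(x, path) {
  flat <- c(n_drugs = x$n_drugs, n_targets = x$n_targets,
            stats::setNames(x$n_targets_per_class,
                            paste0("n_targets_", TARGET_CLASSES)),
            n_diseases = x$n_diseases, n_interactions = x$n_interactions,
            stats::setNames(x$n_interactions_per_class,
                            paste0("n_interactions_", TARGET_CLASSES)),
            n_associations = x$n_associations,
            mean_targets_per_drug = x$mean_targets_per_drug,
            mean_diseases_per_drug = x$mean_diseases_per_drug)
  utils::write.table(
    data.frame(statistic = names(flat), value = unname(flat)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
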