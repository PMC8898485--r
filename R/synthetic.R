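## Planted-component generator: binary drug x target and drug x disease
## matrices with latent sparse blocks linking target subsets to disease
## subsets, plus background noise, mimicking the sparsity of curated
## drug-target / drug-indication data (a few links per drug).
##
## Expected nonzeros of X (documented formula, checked in tests):
##   E[nnz(X)] ~= nC * drugsPerComponent * targetsPerComponent * hitProb
##                + m * p * backgroundRate (overlap-corrected via 1-(1-h)(1-b)
##                on in-block cells); analogously for Y.

#' Specification of a planted two-view dataset
#'
#' @param m,p,q numbers of drugs, targets, diseases.
#' @param nComponents number of planted components.
#' @param targetsPerComponent,diseasesPerComponent,drugsPerComponent
#'   sizes of each component's target support, disease support and
#'   drug membership.
#' @param hitProb probability that a member drug carries each of its
#'   component's targets/diseases.
#' @param backgroundRate independent background 1-rate on every cell.
#' @param classFractions length-3 fractions (protein, miRNA, lncRNA)
#'   used to label target columns; defaults follow the observed
#'   composition of curated interactomes (roughly 70/21/9).
#' @param overlap allow component supports to overlap; by default they
#'   are disjoint, which makes recovery scoring unambiguous.
#' @param seed integer seed; generation is deterministic per seed.
#' @return a list of class \code{PlantedSpec}.
#' @export
plantedSpec <- function(m = 300L, p = 120L, q = 100L, nComponents = 5L,
                        targetsPerComponent = 8L, diseasesPerComponent = 6L,
                        drugsPerComponent = 30L, hitProb = 0.8,
                        backgroundRate = 0.01,
                        classFractions = c(protein = 1167, miRNA = 348,
                                           lncRNA = 153) / 1668,
                        overlap = FALSE, seed = 1L) {
  stopifnot(hitProb > 0, hitProb <= 1, backgroundRate >= 0,
            backgroundRate < 1, length(classFractions) == 3,
            abs(sum(classFractions) - 1) < 1e-8)
  if (!overlap) {
    stopifnot(nComponents * targetsPerComponent <= p,
              nComponents * diseasesPerComponent <= q,
              nComponents * drugsPerComponent <= m)
  }
  structure(as.list(environment()), class = "PlantedSpec")
}

idPad <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Generate a planted MatrixPair with ground truth
#'
#' Each of the \code{nComponents} planted components ties a target
#' subset to a disease subset through a set of member drugs: a member
#' drug carries each support target/disease with probability
#' \code{hitProb}; every cell additionally turns on independently with
#' probability \code{backgroundRate}. Drugs violating the row
#' invariants (no target or no disease) are resampled up to 100 times.
#' Zero columns are dropped (their ids simply do not appear in the
#' output pair). Deterministic per \code{spec$seed}.
#'
#' @param spec a \code{\link{plantedSpec}}.
#' @return a list with \code{pair} (a
#'   \code{\linkS4class{MatrixPair}}) and \code{truth}, a list of class
#'   \code{PlantedTruth}: per component, the character id sets
#'   \code{targets}, \code{diseases}, \code{drugs}.
#' @export
generatePlanted <- function(spec = plantedSpec()) {
  stopifnot(inherits(spec, "PlantedSpec"))
  localSeed(spec$seed, {
    drugs <- idPad("drug", spec$m)
    targets <- idPad("t", spec$p)
    diseases <- idPad("dz", spec$q)
    pickSupports <- function(ids, size) {
      if (spec$overlap)
        lapply(seq_len(spec$nComponents), function(i) sample(ids, size))
      else {
        picked <- sample(ids, size * spec$nComponents)
        split(picked, rep(seq_len(spec$nComponents), each = size))
      }
    }
    tSup <- pickSupports(targets, spec$targetsPerComponent)
    dSup <- pickSupports(diseases, spec$diseasesPerComponent)
    gSup <- pickSupports(drugs, spec$drugsPerComponent)
    # per-cell on-probability: background everywhere, hit inside blocks
    probX <- matrix(spec$backgroundRate, spec$m, spec$p,
                    dimnames = list(drugs, targets))
    probY <- matrix(spec$backgroundRate, spec$m, spec$q,
                    dimnames = list(drugs, diseases))
    onRate <- 1 - (1 - spec$hitProb) * (1 - spec$backgroundRate)
    for (i in seq_len(spec$nComponents)) {
      probX[gSup[[i]], tSup[[i]]] <- onRate
      probY[gSup[[i]], dSup[[i]]] <- onRate
    }
    X <- matrix(as.numeric(stats::rbinom(length(probX), 1, probX)), spec$m,
                dimnames = dimnames(probX))
    Y <- matrix(as.numeric(stats::rbinom(length(probY), 1, probY)), spec$m,
                dimnames = dimnames(probY))
    for (i in seq_len(spec$m)) {
      tries <- 0
      while (sum(X[i, ]) == 0 || sum(Y[i, ]) == 0) {
        tries <- tries + 1
        if (tries > 100)
          stop("row resampling budget exhausted; increase hitProb or backgroundRate",
               call. = FALSE)
        X[i, ] <- stats::rbinom(spec$p, 1, probX[i, ])
        Y[i, ] <- stats::rbinom(spec$q, 1, probY[i, ])
      }
    }
    keepT <- colSums(X) > 0; keepD <- colSums(Y) > 0
    X <- X[, keepT, drop = FALSE]; Y <- Y[, keepD, drop = FALSE]
    nCls <- diff(round(c(0, cumsum(spec$classFractions)) * ncol(X)))
    cls <- rep(TARGET_CLASSES, nCls)
    pair <- new("MatrixPair", X = X, Y = Y, targetClasses = cls)
    truth <- lapply(seq_len(spec$nComponents), function(i)
      list(targets = sort(intersect(tSup[[i]], colnames(X))),
           diseases = sort(intersect(dSup[[i]], colnames(Y))),
           drugs = sort(gSup[[i]])))
    class(truth) <- "PlantedTruth"
    list(pair = pair, truth = truth)
  })
}

jaccardSets <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0) return(0)
  length(intersect(a, b)) / length(u)
}

#' Recovery of planted supports by a fitted model
#'
#' For each planted component, the best match over fitted components of
#' the Jaccard overlap between the component's positive-weight support
#' and the planted support, reported separately for the target and
#' disease sides.
#'
#' @param model a \code{\linkS4class{ComponentModel}} fitted on the
#'   generated pair.
#' @param truth the \code{PlantedTruth} from \code{\link{generatePlanted}}.
#' @return a \code{data.frame} with one row per planted component:
#'   \code{component}, \code{targetJaccard}, \code{diseaseJaccard},
#'   \code{bestTargetMatch}, \code{bestDiseaseMatch} (fitted indices).
#' @export
recoveryScore <- function(model, truth) {
  stopifnot(is(model, "ComponentModel"), inherits(truth, "PlantedTruth"))
  fittedT <- lapply(seq_len(nComponents(model)), function(i)
    targetIds(model)[model@alpha[, i] > 0])
  fittedD <- lapply(seq_len(nComponents(model)), function(i)
    diseaseIds(model)[model@beta[, i] > 0])
  rows <- lapply(seq_along(truth), function(i) {
    jt <- vapply(fittedT, jaccardSets, numeric(1), truth[[i]]$targets)
    jd <- vapply(fittedD, jaccardSets, numeric(1), truth[[i]]$diseases)
    data.frame(component = i, targetJaccard = max(jt),
               diseaseJaccard = max(jd),
               bestTargetMatch = which.max(jt),
               bestDiseaseMatch = which.max(jd))
  })
  do.call(rbind, rows)
}

#' Write planted ground truth as TSV
#'
#' @param truth a \code{PlantedTruth}.
#' @param path output TSV path (columns \code{component}, \code{kind},
#'   \code{id}).
#' @return invisibly, \code{path}.
#' @export
writePlantedTruth <- function(truth, path) {
  rows <- lapply(seq_along(truth), function(i)
    data.frame(component = i,
               kind = rep(c("target", "disease", "drug"),
                          lengths(truth[[i]])[c("targets", "diseases",
                                                "drugs")]),
               id = unlist(truth[[i]], use.names = FALSE)))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
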