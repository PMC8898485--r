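test_that("fold splits are balanced, covering and seeded", {
  expect_equal(lengths(kfoldSplit(10, 10, 1)), rep(1L, 10),
               ignore_attr = TRUE)
  sz <- sort(lengths(kfoldSplit(23, 10, 1)))
  expect_equal(unname(sz), c(rep(2L, 7), rep(3L, 3)))
  f <- kfoldSplit(23, 10, 4)
  expect_setequal(unlist(f), 1:23)
  expect_identical(f, kfoldSplit(23, 10, 4))
  expect_false(identical(f, kfoldSplit(23, 10, 5)))
  expect_error(kfoldSplit(5, 10), "cannot split")
})

test_that("AUC equals the pairwise Mann-Whitney count", {
  expect_equal(aucScore(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(aucScore(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(aucScore(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1)),
               aucPairOracle(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1)))
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    sc <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(aucScore(lab, sc), aucPairOracle(lab, sc))
  }
  expect_error(aucScore(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  lab <- rbinom(40, 1, 0.5); sc <- rnorm(40)
  a <- aucScore(lab, sc)
  expect_equal(aucScore(lab, exp(sc)), a)
  expect_equal(aucScore(lab, 5 * sc - 2), a)
})

test_that("cross-validation is reproducible and holds out test rows", {
  gen <- generatePlanted(plantedSpec(m = 80, p = 40, q = 30,
                                     nComponents = 3,
                                     drugsPerComponent = 20, seed = 5))
  r1 <- suppressWarnings(
    crossValidate(gen$pair, "SCCA", k = 3, c1 = 0.5, c2 = 0.5,
                  nFolds = 5, nRepeats = 2, seed = 7))
  r2 <- suppressWarnings(
    crossValidate(gen$pair, "SCCA", k = 3, c1 = 0.5, c2 = 0.5,
                  nFolds = 5, nRepeats = 2, seed = 7))
  expect_identical(aucPerFold(r1), aucPerFold(r2))
  expect_equal(meanAUC(r1), mean(aucPerRepeat(r1)))
  expect_true(all(aucPerFold(r1) >= 0 & aucPerFold(r1) <= 1, na.rm = TRUE))
})

test_that("training never sees held-out indication rows", {
  # poison the Y rows of one fold with all-ones sentinels; if training
  # used them, the planted model and scores would change
  gen <- generatePlanted(plantedSpec(m = 60, p = 30, q = 20,
                                     nComponents = 2,
                                     drugsPerComponent = 20, seed = 8))
  mp <- gen$pair
  folds <- kfoldSplit(nrow(targetMatrix(mp)), 5, 1)
  testIdx <- folds[[1]]
  trainIdx <- sort(unlist(folds[-1]))
  fitTrain <- function(pair) {
    Xs <- targetMatrix(pair)[trainIdx, ]
    Ys <- diseaseMatrix(pair)[trainIdx, ]
    keepT <- colSums(Xs) > 0; keepD <- colSums(Ys) > 0
    tp <- new("MatrixPair", X = Xs[, keepT], Y = Ys[, keepD],
              targetClasses = pair@targetClasses[keepT])
    fitSCCA(tp, k = 2, c1 = 0.5, c2 = 0.5)
  }
  mPoison <- mp
  mPoison@Y[testIdx, ] <- 1  # direct slot poke on a throwaway copy
  expect_identical(fitTrain(mp)@alpha, fitTrain(mPoison)@alpha)
})

test_that("labels independent of the features give chance-level AUC", {
  # pure-noise pair: X and Y independent Bernoulli
  set.seed(40)
  m <- 100
  repeat {
    X <- matrix(rbinom(m * 30, 1, 0.15), m, 30,
                dimnames = list(sprintf("d%03d", 1:m), sprintf("t%02d", 1:30)))
    Y <- matrix(rbinom(m * 25, 1, 0.15), m, 25,
                dimnames = list(sprintf("d%03d", 1:m), sprintf("s%02d", 1:25)))
    if (all(rowSums(X) > 0) && all(rowSums(Y) > 0) &&
        all(colSums(X) > 0) && all(colSums(Y) > 0)) break
  }
  mp <- new("MatrixPair", X = X, Y = Y,
            targetClasses = rep("protein", 30))
  r <- suppressWarnings(
    crossValidate(mp, "SCCA", k = 3, c1 = 0.5, c2 = 0.5, nFolds = 5,
                  nRepeats = 10, seed = 1))
  se <- sdAUC(r) / sqrt(length(aucPerRepeat(r)))
  expect_lt(abs(meanAUC(r) - 0.5), 3 * max(se, 0.02))
})

test_that("planted structure beats the baseline run on shuffled targets", {
  gen <- generatePlanted(plantedSpec(seed = 11))
  mp <- gen$pair
  scca <- suppressWarnings(
    crossValidate(mp, "SCCA", k = 5, c1 = 0.3, c2 = 0.3, nFolds = 5,
                  nRepeats = 2, seed = 3))
  # destroy the target-disease link by permuting X rows, keep identical folds
  set.seed(99)
  Xs <- targetMatrix(mp)[sample(nrow(targetMatrix(mp))), ]
  rownames(Xs) <- rownames(targetMatrix(mp))
  mpS <- new("MatrixPair", X = Xs, Y = diseaseMatrix(mp),
             targetClasses = mp@targetClasses)
  base <- suppressWarnings(
    crossValidate(mpS, "JaccardCF", nFolds = 5, nRepeats = 2, seed = 3))
  expect_gt(meanAUC(scca), meanAUC(base))
})

test_that("a single-cell sweep reproduces a direct cross-validation", {
  gen <- generatePlanted(plantedSpec(m = 60, p = 30, q = 20,
                                     nComponents = 2,
                                     drugsPerComponent = 25, seed = 12))
  tab <- parameterSweep(gen$pair, cGrid = 0.5, kGrid = 2, nFolds = 5,
                        nRepeats = 2, seed = 5)
  direct <- crossValidate(gen$pair, "SCCA", k = 2, c1 = 0.5, c2 = 0.5,
                          nFolds = 5, nRepeats = 2, seed = 5)
  expect_equal(tab$meanAUC, meanAUC(direct))
  expect_true(tab$feasible)

  # infeasible cells are marked, not fatal
  tab2 <- parameterSweep(gen$pair, cGrid = c(0.1, 0.5), kGrid = 2,
                         nFolds = 5, nRepeats = 1, seed = 5)
  expect_false(tab2$feasible[tab2$c == 0.1])  # 0.1*sqrt(30) < 1
  expect_true(tab2$feasible[tab2$c == 0.5])
})

test_that("more components help when more components are planted", {
  gen <- generatePlanted(plantedSpec(m = 90, p = 60, q = 45,
                                     nComponents = 3,
                                     drugsPerComponent = 30, seed = 13))
  tab <- parameterSweep(gen$pair, cGrid = 0.3, kGrid = c(1, 3),
                        nFolds = 5, nRepeats = 2, seed = 2)
  expect_gte(tab$meanAUC[tab$k == 3], tab$meanAUC[tab$k == 1])
})

test_that("rank-sum p-values match exact enumeration", {
  expect_equal(rankSumTest(c(1, 2, 3), c(10, 20, 30)), 0.1)
  expect_equal(rankSumTest(c(1, 2, 3), c(10, 20, 30)),
               ranksumEnumOracle(c(1, 2, 3), c(10, 20, 30)))
  a <- seq(0.81, 0.90, by = 0.01)  # two disjoint 10-vs-10 samples
  b <- seq(0.61, 0.70, by = 0.01)
  expect_equal(rankSumTest(a, b), ranksumEnumOracle(a, b))
  set.seed(50)
  x <- rnorm(8); y <- rnorm(9) + 0.5
  expect_equal(rankSumTest(x, y), ranksumEnumOracle(x, y))
  # identical samples: no evidence of a shift
  expect_gt(rankSumTest(c(1, 2), c(1, 2)), 0.99)
})

test_that("CV report export writes per-fold rows and a manifest", {
  gen <- generatePlanted(plantedSpec(m = 60, p = 30, q = 20,
                                     nComponents = 2,
                                     drugsPerComponent = 25, seed = 14))
  r <- crossValidate(gen$pair, "JaccardCF", nFolds = 5, nRepeats = 2,
                     seed = 1)
  p <- tempfile(fileext = ".tsv")
  writeCVReport(r, p)
  tab <- read.delim(p)
  expect_equal(nrow(tab), 10)
  man <- jsonlite::read_json(paste0(p, ".manifest.json"))
  expect_equal(man$method, "JaccardCF")
  expect_equal(unlist(man$seeds), 1:2)
})
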