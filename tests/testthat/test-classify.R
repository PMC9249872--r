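# Class weights, LOOCV folds, undersampling, one-vs-one training, metrics.

test_that("class weights follow the inverse-frequency formula", {
  counts <- c(S = 27, N = 30, D = 26, F = 22, A = 25)
  w <- classWeights(counts)
  expect_equal(unname(w["F"]), 130 / (5 * 22), tolerance = 1e-12)
  expect_equal(unname(w["N"]), 130 / (5 * 30), tolerance = 1e-12)
  # balanced counts give unit weights
  expect_equal(unname(classWeights(c(A = 4, B = 4, C = 4))), rep(1, 3))
  # hand-evaluated two-class case
  expect_equal(unname(classWeights(c(A = 10, B = 30))), c(2, 2 / 3),
               tolerance = 1e-12)
  expect_error(classWeights(c(A = 0, B = 3)), "positive")
})

test_that("leave-one-subject-out folds partition by subject", {
  ids <- rep(c("a", "b", "c"), times = c(4, 5, 3))
  folds <- loocvFolds(ids)
  expect_length(folds, 3)
  for (f in folds) {
    expect_length(intersect(f$test, f$train), 0)
    expect_setequal(c(f$test, f$train), seq_along(ids))
    expect_true(all(ids[f$test] == f$subject))
    expect_false(f$subject %in% ids[f$train]) # never in its own train fold
  }
  expect_equal(vapply(folds, function(f) length(f$train), numeric(1)),
               12 - c(4, 5, 3))
  expect_error(loocvFolds(rep("a", 5)), "at least 2")
})

test_that("test folds are undersampled to the smallest class", {
  labels <- rep(c("S", "N", "D", "F", "A"), times = c(27, 30, 26, 22, 25))
  keep <- undersampleTest(labels, seed = 3L)
  expect_equal(unname(table(labels[keep])), rep(22L, 5),
               ignore_attr = TRUE)
  # balanced folds pass through whole
  bal <- rep(c("A", "N"), each = 4)
  expect_length(undersampleTest(bal, classes = c("A", "N"), seed = 1L), 8)
  # seeded determinism
  expect_identical(undersampleTest(labels, seed = 9L),
                   undersampleTest(labels, seed = 9L))
  expect_warning(undersampleTest(rep(c("A", "N"), 5), seed = 1L), "absent")
})

test_that("one-vs-one trains k(k-1)/2 models and separates by construction", {
  set.seed(12)
  x <- matrix(rnorm(60 * 30), 60, 30)
  y <- rep(c("A", "D", "F", "S", "N"), each = 12)
  x[, 1] <- x[, 1] + 5 * as.integer(factor(y)) # perfectly ordered feature
  m5 <- trainOvo(x, y, seed = 1L)
  expect_length(m5@models, 10)
  y2 <- rep(c("A", "N"), each = 30)
  m2 <- trainOvo(x[, 1:5], y2, seed = 1L)
  expect_length(m2@models, 1)
  prob <- predictOvo(m5, x)
  expect_equal(rowSums(prob), rep(1, 60), tolerance = 1e-9)
  expect_true(all(prob >= 0))
  pred <- colnames(prob)[max.col(prob)]
  expect_equal(mean(pred == y), 1.0)
  expect_error(trainOvo(x[1:3, ], y[c(1, 13, 25)]), "at least 2")
})

test_that("training is deterministic for a fixed seed", {
  set.seed(30)
  x <- matrix(rnorm(40 * 50), 40, 50)
  y <- rep(c("A", "N"), 20)
  p1 <- predictOvo(trainOvo(x, y, seed = 7L), x)
  p2 <- predictOvo(trainOvo(x, y, seed = 7L), x)
  expect_identical(p1, p2)
})

test_that("subset accuracy is the exact-match fraction", {
  expect_equal(subsetAccuracy(c("A", "B"), c("A", "B")), 1.0)
  expect_equal(subsetAccuracy(rep("A", 10),
                              c(rep("A", 5), rep("B", 5))), 0.5)
  expect_error(subsetAccuracy(character(0), character(0)), "empty")
  # uniform-random predictions over 5 balanced classes approach 0.2
  set.seed(5)
  y <- rep(c("A", "D", "F", "S", "N"), each = 400)
  pred <- sample(c("A", "D", "F", "S", "N"), 2000, replace = TRUE)
  expect_lt(abs(subsetAccuracy(pred, y) - 0.2), 0.03)
})

test_that("per-class AUC agrees with the Mann-Whitney rank oracle", {
  prob <- matrix(c(0.7, 0.2, 0.4, 0.1, 0.9, 0.3), ncol = 2,
                 dimnames = list(NULL, c("A", "N")))
  prob <- cbind(prob, 1 - prob[, 1] - prob[, 2]) # filler third column
  colnames(prob)[3] <- "D"
  y <- c("A", "N", "A")
  auc <- tstms:::.aucPerClass(prob, y, c("A", "N"))
  bruteAuc <- function(score, pos) {
    s1 <- score[pos]
    s0 <- score[!pos]
    mean(outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(unname(auc["A"]), bruteAuc(prob[, "A"], y == "A"))
  expect_equal(unname(auc["N"]), bruteAuc(prob[, "N"], y == "N"))
  # random scores drift to 0.5
  set.seed(8)
  pr <- matrix(runif(600), 300, 2, dimnames = list(NULL, c("A", "N")))
  yr <- sample(c("A", "N"), 300, replace = TRUE)
  aucR <- tstms:::.aucPerClass(pr / rowSums(pr), yr, c("A", "N"))
  expect_lt(abs(aucR["A"] - 0.5), 0.1)
})

test_that("balanced accuracy averages sensitivity and specificity", {
  y <- c(rep("A", 4), rep("N", 6))
  pred <- c("A", "A", "N", "N", rep("N", 5), "A")
  b <- tstms:::.balancedAccPerClass(pred, y, c("A", "N"))
  expect_equal(unname(b["A"]), (2 / 4 + 5 / 6) / 2)
})

test_that("metrics are invariant to trial order within a fold", {
  set.seed(14)
  prob <- matrix(runif(120), 60, 2)
  prob <- prob / rowSums(prob)
  colnames(prob) <- c("A", "N")
  y <- sample(c("A", "N"), 60, replace = TRUE)
  pred <- colnames(prob)[max.col(prob)]
  perm <- sample(60)
  expect_equal(tstms:::.aucPerClass(prob, y, c("A", "N")),
               tstms:::.aucPerClass(prob[perm, ], y[perm], c("A", "N")))
  expect_equal(tstms:::.balancedAccPerClass(pred, y, c("A", "N")),
               tstms:::.balancedAccPerClass(pred[perm], y[perm],
                                            c("A", "N")))
  expect_equal(subsetAccuracy(pred, y), subsetAccuracy(pred[perm], y[perm]))
})

test_that("LOOCV evaluation reports coherent, reproducible metrics", {
  fm <- syntheticFeatureMatrix(n = 32, informative = 101:110, effect = 2,
                               nSubjects = 4)
  # light column set for speed; evaluation is dimension-agnostic
  x <- fm$x[, 1:200]
  r1 <- evaluateLoocv(x, fm$meta, params = boostParams(nrounds = 10),
                      seed = 2L)
  r2 <- evaluateLoocv(x, fm$meta, params = boostParams(nrounds = 10),
                      seed = 2L)
  expect_equal(r1@aucPerClass, r2@aucPerClass, tolerance = 1e-12)
  expect_equal(r1@subsetAccuracy, r2@subsetAccuracy, tolerance = 1e-12)
  # a strongly informative signal is learned
  expect_gt(mean(r1@aucPerClass), 0.8)
  # confusion rows sum to 100
  expect_equal(unname(rowSums(r1@confusion)), rep(100, 2), tolerance = 1e-9)
})
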