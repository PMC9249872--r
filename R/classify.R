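`%||%` <- function(a, b) if (is.null(a)) b else a

## Class-weighted one-vs-one gradient-boosted classification under
## leave-one-subject-out cross-validation (LOOCV), with test-fold
## undersampling and the reported metrics.
##
## Training uses xgboost binary gradient-boosted trees, one per unordered
## class pair; imbalance is handled by inverse-frequency class weights in
## the training loss, while each held-out subject's trials are randomly
## undersampled to its smallest class before scoring.

#' Inverse-frequency class weights
#'
#' \code{weight[i] = n_samples / (n_classes * n_samples_in_class_i)}, so a
#' balanced design gives every class weight 1 and rarer classes weigh more.
#'
#' @param counts named per-class trial counts, all positive.
#' @return Named numeric weights.
#' @examples
#' classWeights(c(S = 27, N = 30, D = 26, F = 22, A = 25))["F"] # 130/(5*22)
#' @export
classWeights <- function(counts) {
  if (any(counts <= 0)) stop("every class count must be positive")
  sum(counts) / (length(counts) * counts)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: test = that subject's trials, train = everyone
#' else's.
#'
#' @param subjectIds character vector, one entry per trial.
#' @return List of folds, each with \code{subject}, \code{test} and
#'   \code{train} index vectors.
#' @export
loocvFolds <- function(subjectIds) {
  subjects <- sort(unique(subjectIds)) # canonical fold order
  if (length(subjects) < 2) {
    stop("leave-one-subject-out needs at least 2 subjects")
  }
  lapply(subjects, function(s) {
    test <- which(subjectIds == s)
    list(subject = s, test = test, train = setdiff(seq_along(subjectIds),
                                                   test))
  })
}

#' Undersample a test fold to its smallest class
#'
#' Randomly reduces every class present in the fold to the fold's minimum
#' per-class count, seeded for reproducibility. Classes absent from the
#' fold are skipped with a warning.
#'
#' @param labels class labels of the fold's trials.
#' @param classes the full class set expected.
#' @param seed integer seed.
#' @return Integer indices (into \code{labels}) of the retained trials.
#' @export
undersampleTest <- function(labels, classes = CLASS_LEVELS, seed = 1L) {
  missing <- setdiff(classes, unique(labels))
  if (length(missing)) {
    warning("class(es) absent from fold, skipped: ",
            paste(missing, collapse = ", "))
  }
  present <- intersect(classes, unique(labels))
  m <- min(table(factor(labels, levels = present)))
  .withSeed(seed, {
    sort(unlist(lapply(present, function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > m) sample(idx, m) else idx
    }), use.names = FALSE))
  })
}

#' Default gradient-boosting hyperparameters
#'
#' Modest defaults for the high-dimensional, low-sample-size feature
#' matrices this pipeline produces: shallow trees, a conservative learning
#' rate, and single-threaded deterministic training.
#'
#' @param nrounds boosting rounds.
#' @param maxDepth tree depth.
#' @param eta learning rate.
#' @param colsample fraction of columns sampled per tree. With tens of
#'   thousands of highly correlated pixel columns, column subsampling both
#'   regularizes and spreads split gain across a correlated informative
#'   region instead of crediting one arbitrary member.
#' @param maxBin histogram bins per feature; 64 keeps the per-model
#'   histogram footprint small at 61k features with no accuracy cost at
#'   these sample sizes.
#' @param ... further xgboost parameters.
#' @return List of hyperparameters.
#' @export
boostParams <- function(nrounds = 60L, maxDepth = 3L, eta = 0.3,
                        colsample = 0.3, maxBin = 64L, ...) {
  c(list(nrounds = as.integer(nrounds), max_depth = as.integer(maxDepth),
         eta = eta, colsample_bytree = colsample,
         max_bin = as.integer(maxBin)), list(...))
}

#' Train the one-vs-one ensemble
#'
#' Fits \code{k (k - 1) / 2} binary gradient-boosted classifiers, one per
#' unordered class pair, each trained on the trials of its two classes with
#' per-trial weights from \code{\link{classWeights}} computed on the full
#' training label distribution.
#'
#' @param x trials x features matrix.
#' @param y class labels.
#' @param weights optional named per-class weights; default
#'   \code{classWeights(table(y))}.
#' @param params from \code{\link{boostParams}}.
#' @param seed training seed.
#' @return An \code{\linkS4class{OvoModel}}.
#' @export
trainOvo <- function(x, y, weights = NULL, params = boostParams(),
                     seed = 1L) {
  levels <- sort(unique(as.character(y)))
  counts <- table(y)
  if (any(counts < 2)) {
    stop("every training class needs at least 2 trials")
  }
  if (is.null(weights)) weights <- classWeights(c(counts))
  pairs <- utils::combn(levels, 2L, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    idx <- which(y %in% pr)
    lab <- as.integer(y[idx] == pr[2]) # positive class = second of pair
    dtrain <- xgboost::xgb.DMatrix(x[idx, , drop = FALSE], label = lab,
                                   weight = weights[as.character(y[idx])],
                                   nthread = 1)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    colsample_bytree = params$colsample_bytree,
                    max_bin = params$max_bin %||% 64L,
                    nthread = 1, seed = seed,
                    tree_method = "hist"),
      data = dtrain, nrounds = params$nrounds, verbose = 0
    )
    # round-trip through the serialized form so the booster drops its
    # reference to the training matrix; with 61k-column folds, keeping
    # ten of those alive per fold would dominate memory
    bst <- xgboost::xgb.load.raw(xgboost::xgb.save.raw(bst))
    rm(dtrain)
    bst
  })
  names(models) <- vapply(pairs, paste, character(1), collapse = "|")
  new("OvoModel", models = models, classLevels = levels,
      params = params, seed = as.integer(seed))
}

#' Predict class probabilities from a one-vs-one ensemble
#'
#' Each pairwise model yields P(second | pair); per class, the pairwise
#' probabilities in its favor are averaged over the k - 1 pairs involving
#' it and the k class scores renormalized to sum to 1 (average pairwise
#' coupling).
#'
#' @param model an \code{\linkS4class{OvoModel}}.
#' @param x trials x features matrix.
#' @return Matrix (trials x classes) of probabilities, rows summing to 1.
#' @export
predictOvo <- function(model, x) {
  k <- length(model@classLevels)
  acc <- matrix(0, nrow(x), k, dimnames = list(NULL, model@classLevels))
  dm <- xgboost::xgb.DMatrix(x, nthread = 1)
  for (nm in names(model@models)) {
    pr <- strsplit(nm, "|", fixed = TRUE)[[1]]
    p2 <- predict(model@models[[nm]], dm)
    acc[, pr[1]] <- acc[, pr[1]] + (1 - p2)
    acc[, pr[2]] <- acc[, pr[2]] + p2
  }
  acc <- acc / (k - 1)
  acc / rowSums(acc)
}

#' Subset (exact-match) accuracy
#'
#' Fraction of trials whose label is predicted exactly; chance level for 5
#' balanced classes is 0.2.
#'
#' @param yPred,yTrue equal-length label vectors.
#' @return Fraction in [0, 1].
#' @export
subsetAccuracy <- function(yPred, yTrue) {
  if (length(yPred) == 0 || length(yPred) != length(yTrue)) {
    stop("need equal-length, non-empty label vectors")
  }
  mean(as.character(yPred) == as.character(yTrue))
}

# one-vs-rest AUC per class from a probability matrix; folds lacking both
# a positive and a negative for a class return NA there
.aucPerClass <- function(prob, yTrue, classes) {
  vapply(classes, function(cl) {
    pos <- yTrue == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(
      response = factor(pos, levels = c(FALSE, TRUE)),
      predictor = prob[, cl], quiet = TRUE, direction = "<"
    )))
  }, numeric(1))
}

# balanced accuracy per class: mean of one-vs-rest sensitivity and
# specificity of the final decisions
.balancedAccPerClass <- function(yPred, yTrue, classes) {
  vapply(classes, function(cl) {
    pos <- yTrue == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    sens <- mean(yPred[pos] == cl)
    spec <- mean(yPred[!pos] != cl)
    (sens + spec) / 2
  }, numeric(1))
}

#' Evaluate the pipeline under leave-one-subject-out cross-validation
#'
#' For each subject: train the one-vs-one ensemble on all other subjects
#' (class-weighted loss), undersample the held-out subject's trials to its
#' smallest class, and score. Reports fold-averaged per-class one-vs-rest
#' ROC AUC, fold-averaged per-class balanced accuracy, overall subset
#' accuracy, and the elementwise median of the per-fold confusion matrices,
#' row-normalized to 100 percent.
#'
#' @param x trials x features matrix.
#' @param meta data.frame with \code{subjectId} and \code{classLabel}.
#' @param params from \code{\link{boostParams}}.
#' @param seed seed for undersampling and training.
#' @param undersample undersample each test fold to its smallest class.
#' @return A \code{\linkS4class{MetricsReport}}.
#' @export
evaluateLoocv <- function(x, meta, params = boostParams(), seed = 1L,
                          undersample = TRUE) {
  classes <- sort(unique(meta$classLabel))
  folds <- loocvFolds(meta$subjectId)
  aucs <- NULL
  baccs <- NULL
  confs <- list()
  rows <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    model <- trainOvo(x[fold$train, , drop = FALSE],
                      meta$classLabel[fold$train], params = params,
                      seed = seed)
    test <- fold$test
    if (undersample) {
      keep <- undersampleTest(meta$classLabel[test], classes,
                              seed = seed + fi)
      test <- test[keep]
    }
    prob <- predictOvo(model, x[test, , drop = FALSE])
    yTrue <- meta$classLabel[test]
    yPred <- classes[max.col(prob[, classes, drop = FALSE],
                             ties.method = "first")]
    aucs <- rbind(aucs, .aucPerClass(prob, yTrue, classes))
    baccs <- rbind(baccs, .balancedAccPerClass(yPred, yTrue, classes))
    cm <- table(factor(yTrue, classes), factor(yPred, classes))
    confs[[fi]] <- unclass(cm)
    rows[[fi]] <- data.frame(subjectId = fold$subject, yTrue = yTrue,
                             yPred = yPred, prob,
                             stringsAsFactors = FALSE)
    rm(model)
    gc(FALSE)
  }
  foldDf <- do.call(rbind, rows)
  med <- apply(simplify2array(confs), c(1, 2), stats::median)
  rn <- rowSums(med)
  rn[rn == 0] <- 1
  new("MetricsReport",
      aucPerClass = colMeans(aucs, na.rm = TRUE),
      balancedAccPerClass = colMeans(baccs, na.rm = TRUE),
      subsetAccuracy = subsetAccuracy(foldDf$yPred, foldDf$yTrue),
      confusion = med / rn * 100, folds = foldDf, seed = as.integer(seed))
}
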