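## Feature-importance analysis: per-parameter importance from the trained
## one-vs-one ensemble, aggregated into spatial maps, temporal profiles,
## per-wavelength totals, pairwise-classifier maps, ROI statistics and
## grouped (e.g. per-gender) analyses.

.emptyImportance <- function() {
  array(0, dim = c(7L, N_PULSE, GRID_ROWS, GRID_COLS))
}

# turn a length-61251 nonnegative vector into a normalized tensor (percent)
.importanceFromVector <- function(v) {
  v[v < 0] <- 0
  tot <- sum(v)
  if (tot <= 0) stop("all importances are zero")
  v <- v / tot * 100
  a <- array(v[seq_len(N_FLAT - 1L)],
             dim = c(N_PULSE, GRID_ROWS, GRID_COLS, 7L))
  new("ImportanceTensor", values = aperm(a, c(4, 1, 2, 3)),
      f8Value = v[N_FLAT])
}

#' Per-parameter importance of a one-vs-one ensemble
#'
#' Measures how much each of the 61,251 input parameters contributes to the
#' trained model. \code{method = "native"} uses the boosting backend's
#' loss-reduction (gain) score summed over the ensemble's binary models --
#' parameters never used by any tree score 0. \code{method = "permutation"}
#' is a model-agnostic surrogate: the increase in multiclass log-loss when
#' a parameter's column (or a whole (feature, pulse) slab, for speed) is
#' permuted, seeded, with negative changes clipped to 0. Either way the
#' result is normalized to percent.
#'
#' @param model an \code{\linkS4class{OvoModel}}.
#' @param x,y evaluation data (needed for \code{"permutation"}).
#' @param method \code{"native"} or \code{"permutation"}.
#' @param slab for \code{"permutation"}: permute whole (feature, pulse)
#'   slabs instead of single columns (much faster; spatial structure is
#'   then uniform within a slab).
#' @param seed permutation seed.
#' @return An \code{\linkS4class{ImportanceTensor}}.
#' @export
lfcImportance <- function(model, x = NULL, y = NULL,
                          method = c("native", "permutation"),
                          slab = FALSE, seed = 1L) {
  method <- match.arg(method)
  if (method == "native") {
    v <- numeric(N_FLAT)
    for (m in model@models) {
      imp <- xgboost::xgb.importance(model = m)
      if (is.null(imp) || nrow(imp) == 0) next
      idx <- as.integer(sub("^f", "", imp$Feature)) + 1L
      v[idx] <- v[idx] + imp$Gain
    }
    return(.importanceFromVector(v))
  }
  if (is.null(x) || is.null(y)) {
    stop("permutation importance needs evaluation data")
  }
  base <- .ovoLogLoss(model, x, y)
  v <- numeric(N_FLAT)
  .withSeed(seed, {
    if (slab) {
      fmap <- featureIndexMap()
      for (f in 1:7) {
        for (p in seq_len(N_PULSE)) {
          cols <- which(fmap$feature == paste0("F", f) & fmap$pulse == p)
          xp <- x
          perm <- sample(nrow(x))
          xp[, cols] <- x[perm, cols]
          v[cols] <- max(.ovoLogLoss(model, xp, y) - base, 0) /
            length(cols)
        }
      }
      xp <- x
      xp[, N_FLAT] <- x[sample(nrow(x)), N_FLAT]
      v[N_FLAT] <- max(.ovoLogLoss(model, xp, y) - base, 0)
    } else {
      active <- which(apply(x, 2, function(cc) any(cc != cc[1])))
      for (j in active) {
        xp <- x
        xp[, j] <- x[sample(nrow(x)), j]
        v[j] <- max(.ovoLogLoss(model, xp, y) - base, 0)
      }
    }
  })
  .importanceFromVector(v)
}

# multiclass log-loss of the coupled one-vs-one probabilities
.ovoLogLoss <- function(model, x, y) {
  prob <- predictOvo(model, x)
  p <- prob[cbind(seq_along(y), match(as.character(y),
                                      colnames(prob)))]
  -mean(log(pmax(p, 1e-15)))
}

#' Spatial importance maps
#'
#' Per feature F1..F7, sums the importance tensor over pulse frames into a
#' 50 x 35 map; the spatial summary is the mean of the seven maps. The
#' per-feature percents plus the F8 percent account for all 100 percent.
#'
#' @param it an \code{\linkS4class{ImportanceTensor}}.
#' @return List with \code{maps} (named list of 50 x 35 matrices),
#'   \code{summary} (50 x 35), \code{percents} (named, F1..F7),
#'   \code{f8Percent} and \code{spatialPercent} (= 100 - f8Percent).
#' @export
spatialMaps <- function(it) {
  maps <- lapply(1:7, function(f) {
    apply(it@values[f, , , ], c(2, 3), sum)
  })
  names(maps) <- paste0("F", 1:7)
  percents <- vapply(maps, sum, numeric(1))
  list(maps = maps, summary = Reduce(`+`, maps) / 7, percents = percents,
       f8Percent = it@f8Value, spatialPercent = 100 - it@f8Value)
}

#' Temporal importance profile
#'
#' Total importance per pulse frame (summed over features and pixels); the
#' five entries plus the F8 percent sum to 100.
#'
#' @param it an \code{\linkS4class{ImportanceTensor}}.
#' @return Numeric vector of length 5.
#' @export
temporalProfile <- function(it) {
  apply(it@values, 2, sum)
}

#' Pairwise binary-classifier importance maps
#'
#' Retrains an independent binary classifier for every unordered class pair
#' and emits each pair's spatial summary map and its overall spatiotemporal
#' percent (the remainder to 100 is that pair's F8 share).
#'
#' @param x trials x features matrix.
#' @param meta data.frame with \code{classLabel}.
#' @param params from \code{\link{boostParams}}.
#' @param seed training seed.
#' @return Named list over pairs \code{"X|Y"}, each with \code{summary}
#'   (50 x 35), \code{spatialPercent}, \code{f8Percent} and the
#'   \code{tensor}.
#' @export
pairwiseMaps <- function(x, meta, params = boostParams(), seed = 1L) {
  classes <- sort(unique(meta$classLabel))
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  out <- list()
  for (pr in pairs) {
    idx <- which(meta$classLabel %in% pr)
    if (length(unique(meta$classLabel[idx])) < 2) {
      warning("pair ", paste(pr, collapse = "|"), " lacks data, skipped")
      next
    }
    model <- trainOvo(x[idx, , drop = FALSE], meta$classLabel[idx],
                      params = params, seed = seed)
    it <- lfcImportance(model, method = "native")
    sm <- spatialMaps(it)
    out[[paste(pr, collapse = "|")]] <-
      list(summary = sm$summary, spatialPercent = sm$spatialPercent,
           f8Percent = sm$f8Percent, tensor = it)
  }
  out
}

#' Default facial regions of interest
#'
#' Rectangular-ish regions (forehead, eyes, cheeks, mouth) on the 50 x 35
#' grid, anatomically placed for the simulator's face geometry;
#' non-overlapping by construction.
#'
#' @return Named list of 50 x 35 logical matrices.
#' @export
defaultRois <- function() {
  .faceRegions()
}

#' ROI statistics of an importance map
#'
#' Mean importance over each region's pixels, the SD of that mean across
#' per-fold maps, and a two-sided bootstrap comparison (resampling folds)
#' of each region against the rest of the face.
#'
#' @param map 50 x 35 overall importance map (e.g. the fold-mean summary).
#' @param rois named list of logical matrices.
#' @param foldMaps list of per-fold 50 x 35 maps (at least 2).
#' @param faceMask logical matrix delimiting the face; defaults to the
#'   union of regions' bounding face.
#' @param nBoot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return data.frame with region, mean, sd, restMean and pValue.
#' @export
roiStats <- function(map, rois = defaultRois(), foldMaps = NULL,
                     faceMask = faceMaskDefault(), nBoot = 1e4, seed = 1L) {
  if (any(vapply(rois, sum, numeric(1)) == 0)) stop("empty ROI")
  rows <- lapply(names(rois), function(nm) {
    roi <- rois[[nm]]
    rest <- faceMask & !roi
    m <- mean(map[roi])
    restM <- mean(map[rest])
    sdev <- NA_real_
    pv <- NA_real_
    if (!is.null(foldMaps) && length(foldMaps) >= 2) {
      perFold <- vapply(foldMaps, function(fm) mean(fm[roi]), numeric(1))
      diffs <- vapply(foldMaps, function(fm) {
        mean(fm[roi]) - mean(fm[rest])
      }, numeric(1))
      sdev <- stats::sd(perFold)
      obs <- mean(diffs)
      nF <- length(diffs)
      pv <- .withSeed(seed, {
        boot <- vapply(seq_len(nBoot), function(b) {
          mean(diffs[sample.int(nF, nF, replace = TRUE)])
        }, numeric(1))
        # two-sided: how often the resampled mean difference crosses zero
        2 * min(mean(boot <= 0), mean(boot >= 0))
      })
      pv <- min(max(pv, 1 / nBoot), 1)
    }
    data.frame(region = nm, mean = m, sd = sdev, restMean = restM,
               pValue = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Grouped importance analysis
#'
#' Reruns training and importance separately per metadata group (e.g.
#' gender), as in training with each gender's data separately. Groups with
#' fewer than 2 subjects are skipped with a warning.
#'
#' @param x trials x features matrix.
#' @param meta data.frame with \code{subjectId}, \code{classLabel} and the
#'   grouping column.
#' @param groupBy name of the metadata column to split on.
#' @param params from \code{\link{boostParams}}.
#' @param seed training seed.
#' @return Named list per group with \code{tensor} and \code{spatial} (the
#'   \code{\link{spatialMaps}} output).
#' @export
groupedAnalysis <- function(x, meta, groupBy = "gender",
                            params = boostParams(), seed = 1L) {
  if (!groupBy %in% names(meta)) {
    stop("unknown metadata key: ", groupBy)
  }
  out <- list()
  for (g in sort(unique(meta[[groupBy]]))) {
    idx <- which(meta[[groupBy]] == g)
    if (length(unique(meta$subjectId[idx])) < 2) {
      warning("group ", g, " has fewer than 2 subjects, skipped")
      next
    }
    model <- trainOvo(x[idx, , drop = FALSE], meta$classLabel[idx],
                      params = params, seed = seed)
    it <- lfcImportance(model, method = "native")
    out[[as.character(g)]] <- list(tensor = it, spatial = spatialMaps(it))
  }
  out
}
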