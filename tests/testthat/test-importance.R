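# Importance tensor, aggregation views, ROI statistics, grouped analysis.

test_that("importance tensors normalize to 100 percent", {
  v <- numeric(61251)
  v[c(10, 5000, 61251)] <- c(3, 1, 1)
  it <- tstms:::.importanceFromVector(v)
  expect_equal(sum(it@values) + it@f8Value, 100, tolerance = 1e-9)
  expect_equal(it@f8Value, 20)
  expect_error(tstms:::.importanceFromVector(numeric(61251)), "zero")
})

test_that("a single informative column dominates native importance", {
  fm <- syntheticFeatureMatrix(n = 40, informative = 2345, effect = 4)
  model <- trainOvo(fm$x, fm$meta$classLabel,
                    params = boostParams(nrounds = 20, colsample = 1),
                    seed = 1L)
  it <- lfcImportance(model, method = "native")
  v <- c(aperm(it@values, c(2, 3, 4, 1)), it@f8Value)
  expect_gt(v[2345], 50)
  # columns the model never uses score exactly zero
  expect_equal(v[1], 0)
})

test_that("permutation surrogate agrees with the native score", {
  fm <- syntheticFeatureMatrix(n = 60, informative = c(100, 200, 300),
                               effect = c(3), nSubjects = 4, seed = 77L)
  # grade the three signal columns differently
  fm$x[fm$meta$classLabel == "A", 200] <-
    fm$x[fm$meta$classLabel == "A", 200] + 2
  fm$x[fm$meta$classLabel == "A", 300] <-
    fm$x[fm$meta$classLabel == "A", 300] + 4
  keepCols <- c(100, 200, 300, 400, 500)
  x <- matrix(0, 60, 61251)
  x[, keepCols] <- fm$x[, keepCols] # all other columns constant
  model <- trainOvo(x, fm$meta$classLabel,
                    params = boostParams(nrounds = 20, colsample = 1),
                    seed = 1L)
  nat <- lfcImportance(model, method = "native")
  per <- lfcImportance(model, x, fm$meta$classLabel,
                       method = "permutation", seed = 4L)
  vn <- c(aperm(nat@values, c(2, 3, 4, 1)), nat@f8Value)[keepCols]
  vp <- c(aperm(per@values, c(2, 3, 4, 1)), per@f8Value)[keepCols]
  expect_gte(cor(vn, vp, method = "spearman"), 0.8)
})

test_that("spatial maps propagate mass and account for 100 percent", {
  v <- numeric(61251)
  idx <- featureIndexMap()
  hot <- idx$index[idx$feature == "F4" & idx$row == 30 & idx$col == 12]
  v[hot] <- 1
  v[61251] <- 1
  it <- tstms:::.importanceFromVector(v)
  sm <- spatialMaps(it)
  expect_equal(which(sm$maps$F4 == max(sm$maps$F4), arr.ind = TRUE)[1, ],
               c(row = 30, col = 12))
  expect_equal(sum(sm$maps$F1), 0)
  expect_equal(sum(sm$percents) + sm$f8Percent, 100, tolerance = 1e-9)
  expect_equal(sm$spatialPercent, 100 - sm$f8Percent)
  # uniform tensor gives flat maps
  vu <- rep(1, 61251)
  smu <- spatialMaps(tstms:::.importanceFromVector(vu))
  expect_lt(diff(range(smu$summary)), 1e-9)
})

test_that("temporal profile sums per pulse frame", {
  v <- numeric(61251)
  idx <- featureIndexMap()
  v[idx$index[!is.na(idx$pulse) & idx$pulse == 1]] <- 1
  v[61251] <- 25 * sum(v) / 75 # give F8 a 25% share
  it <- tstms:::.importanceFromVector(v)
  prof <- temporalProfile(it)
  expect_equal(prof[1], 100 - it@f8Value, tolerance = 1e-9)
  expect_equal(sum(prof[2:5]), 0)
  # uniform tensor: equal fifths of the spatiotemporal share
  itu <- tstms:::.importanceFromVector(rep(1, 61251))
  expect_equal(temporalProfile(itu),
               rep((100 - itu@f8Value) / 5, 5), tolerance = 1e-9)
})

test_that("ROI statistics summarize maps and flag genuine hotspots", {
  rois <- defaultRois()
  flat <- matrix(1, 50, 35)
  rs <- roiStats(flat, rois, foldMaps = replicate(5, flat,
                                                  simplify = FALSE))
  expect_true(all(abs(rs$mean - 1) < 1e-12))
  expect_true(all(rs$pValue >= 0.9)) # no difference anywhere
  # hotspot fully inside the cheeks
  cheeks <- rois$left_cheek | rois$right_cheek
  set.seed(21)
  foldMaps <- replicate(20, {
    m <- matrix(rnorm(50 * 35, 0, 0.01), 50, 35)
    m[cheeks] <- m[cheeks] + 1
    m
  }, simplify = FALSE)
  avg <- Reduce(`+`, foldMaps) / length(foldMaps)
  rs2 <- roiStats(avg, rois, foldMaps = foldMaps, seed = 2L)
  lc <- rs2[rs2$region == "left_cheek", ]
  expect_gt(lc$mean, lc$restMean)
  expect_lt(lc$pValue, 0.05)
  # one-pixel region reduces to that pixel
  one <- matrix(FALSE, 50, 35)
  one[10, 10] <- TRUE
  rs3 <- roiStats(avg, list(px = one))
  expect_equal(rs3$mean, avg[10, 10])
  expect_error(roiStats(avg, list(empty = matrix(FALSE, 50, 35))), "empty")
})

test_that("default regions are disjoint and inside the face", {
  rois <- defaultRois()
  total <- Reduce(`+`, rois)
  expect_lte(max(total), 1)
  face <- faceMaskDefault()
  for (r in rois) {
    expect_gt(sum(r), 0)
    expect_true(all(face[r]))
  }
})

test_that("grouped analysis recovers group-specific signal regions", {
  idx <- featureIndexMap()
  colsF <- idx$index[idx$feature == "F4" & idx$row %in% 13:16 &
                       idx$col %in% 14:22] # forehead block
  colsM <- idx$index[idx$feature == "F4" & idx$row %in% 37:40 &
                       idx$col %in% 15:21] # mouth block
  fm <- syntheticFeatureMatrix(n = 48, informative = 1, effect = 0,
                               nSubjects = 6, seed = 31L)
  fm$meta$gender <- rep(c("F", "M"), each = 24)
  fm$meta$subjectId <- rep(sprintf("S%02d", 1:6), each = 8)
  fm$meta$classLabel <- rep(c("A", "N"), 24)
  a <- fm$meta$classLabel == "A"
  fm$x[a & fm$meta$gender == "F", colsF] <-
    fm$x[a & fm$meta$gender == "F", colsF] + 3
  fm$x[a & fm$meta$gender == "M", colsM] <-
    fm$x[a & fm$meta$gender == "M", colsM] + 3
  res <- groupedAnalysis(fm$x, fm$meta, "gender",
                         params = boostParams(nrounds = 15), seed = 2L)
  reg <- defaultRois()
  fMap <- res$F$spatial$summary
  mMap <- res$M$spatial$summary
  expect_gt(mean(fMap[reg$forehead]), mean(fMap[reg$mouth]))
  expect_gt(mean(mMap[reg$mouth]), mean(mMap[reg$forehead]))
  expect_error(groupedAnalysis(fm$x, fm$meta, "nope"), "unknown")
})

test_that("pairwise maps localize what separates each class pair", {
  idx <- featureIndexMap()
  lc <- defaultRois()$left_cheek
  inRegion <- !is.na(idx$row) & lc[cbind(idx$row, idx$col)]
  cheekCols <- idx$index[idx$feature == "F4" & inRegion]
  fm <- syntheticFeatureMatrix(n = 42, informative = 1, effect = 0,
                               nSubjects = 4, seed = 51L)
  fm$meta$classLabel <- rep(c("A", "N", "S"), 14)
  # cheeks separate A; the scalar F8 column alone separates S
  fm$x[fm$meta$classLabel == "A", cheekCols] <-
    fm$x[fm$meta$classLabel == "A", cheekCols] + 2
  fm$x[fm$meta$classLabel == "S", 61251] <-
    fm$x[fm$meta$classLabel == "S", 61251] + 6
  out <- pairwiseMaps(fm$x, fm$meta, params = boostParams(nrounds = 15),
                      seed = 3L)
  expect_length(out, 3)
  reg <- defaultRois()
  an <- out[["A|N"]]
  cheeks <- reg$left_cheek | reg$right_cheek
  expect_gt(mean(an$summary[cheeks]),
            mean(an$summary[faceMaskDefault() & !cheeks]))
  # the pair separated only by heart rate leans on F8: its share there
  # dwarfs both the amplitude-separated pair's F8 share and any single
  # spatiotemporal parameter of its own model
  expect_gt(out[["N|S"]]$f8Percent, 10)
  expect_gt(out[["N|S"]]$f8Percent, 5 * (out[["A|N"]]$f8Percent + 0.1))
})
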