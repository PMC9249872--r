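# TSTMS feature arithmetic, guards, chin mask, flattening.

stackOf <- function(val) array(val, dim = c(5, 50, 35))

test_that("pulsatile amplitude subtracts and respects padding", {
  expect_equal(pulsatileAmplitude(stackOf(120), stackOf(100))[1, 1, 1], 20)
  a <- stackOf(120)
  b <- stackOf(100)
  a[1, 1, 1] <- 0
  b[1, 1, 1] <- 0 # padded entry
  expect_equal(pulsatileAmplitude(a, b)[1, 1, 1], 0)
})

test_that("absorption ratio is ln(Imax/Imin) with zero guards", {
  expect_equal(absorptionRatio(stackOf(120), stackOf(100))[2, 3, 4],
               log(1.2), tolerance = 1e-12)
  expect_equal(absorptionRatio(stackOf(100), stackOf(100))[1, 1, 1], 0)
  expect_equal(absorptionRatio(stackOf(100), stackOf(0))[1, 1, 1], 0)
})

test_that("amplitude dissimilarity is B/R with zero guard", {
  expect_equal(amplitudeDissimilarity(stackOf(10), stackOf(20))[1, 1, 1],
               0.5)
  expect_equal(amplitudeDissimilarity(stackOf(10), stackOf(0))[1, 1, 1], 0)
})

test_that("absorption difference matches the hand-computed example", {
  out <- absorptionDifference(stackOf(0.10), stackOf(0.25), stackOf(150),
                              stackOf(100))
  expect_equal(out[3, 10, 10], abs((-0.15) / 50), tolerance = 1e-12)
  # identical channels: 0/0 guarded to 0
  same <- absorptionDifference(stackOf(0.1), stackOf(0.1), stackOf(150),
                               stackOf(150))
  expect_equal(same[1, 1, 1], 0)
})

test_that("pulsatile features follow Beer-Lambert closed forms", {
  rec <- oracleRecording()
  cube <- preprocessRecording(rec)
  st <- buildPulseStack(cube, 1.25)
  iac <- pulsatileAmplitude(st@imax$G, st@imin$G)[2, 27, 18]
  ir <- absorptionRatio(st@imax$G, st@imin$G)[2, 27, 18]
  # detection runs through the band-pass, so extremes carry a small
  # filter-shaping error; one gray level bounds it comfortably
  expect_lt(abs(iac - 120 * exp(-0.8) * (1 - exp(-0.8 * 0.15))), 1)
  expect_lt(abs(ir - 0.8 * 0.15), 0.02)
  # F5 equals the ratio of the two channels' closed-form amplitudes
  iacB <- pulsatileAmplitude(st@imax$B, st@imin$B)
  iacR <- pulsatileAmplitude(st@imax$R, st@imin$R)
  f5 <- amplitudeDissimilarity(iacB, iacR)[2, 27, 18]
  th <- (90 * exp(-0.9) * (1 - exp(-0.9 * 0.15))) /
    (160 * exp(-0.3) * (1 - exp(-0.3 * 0.15)))
  expect_equal(f5, th, tolerance = 0.05)
})

test_that("amplitude is offset-invariant but the absorption ratio is not", {
  rec <- oracleRecording()
  cube <- preprocessRecording(rec)
  shifted <- cube
  shifted@data[2, , , ] <- shifted@data[2, , , ] + 25
  st <- buildPulseStack(cube, 1.25)
  st2 <- buildPulseStack(shifted, 1.25)
  iac1 <- pulsatileAmplitude(st@imax$G, st@imin$G)[2, 27, 18]
  iac2 <- pulsatileAmplitude(st2@imax$G, st2@imin$G)[2, 27, 18]
  ir1 <- absorptionRatio(st@imax$G, st@imin$G)[2, 27, 18]
  ir2 <- absorptionRatio(st2@imax$G, st2@imin$G)[2, 27, 18]
  expect_equal(iac1, iac2, tolerance = 1e-6)
  expect_gt(abs(ir1 - ir2), 0.01)
})

test_that("the chin mask zeroes bottom rows and rejects oversized masks", {
  x <- noisyCube()
  ft <- computeTstmsFeatures(x$cube, chinMask = NULL)
  masked <- applyChinMask(ft, defaultChinMask())
  for (f in paste0("F", 1:7)) {
    expect_true(all(featureArray(masked, f)[, 45:50, ] == 0))
  }
  expect_equal(flattenFeatures(masked)[61251], flattenFeatures(ft)[61251])
  # empty mask is the identity
  id <- applyChinMask(ft, matrix(FALSE, 50, 35))
  expect_equal(id@values, ft@values)
  expect_error(applyChinMask(ft, matrix(TRUE, 50, 35)), "30%")
})

test_that("flattening is a length-61251 bijection with F8 last", {
  x <- noisyCube()
  ft <- computeTstmsFeatures(x$cube)
  v <- flattenFeatures(ft)
  expect_length(v, 61251)
  expect_equal(v[61251], hr(ft))
  back <- unflattenFeatures(v)
  expect_equal(back@values, ft@values)
  expect_equal(back@f8, ft@f8)
  # index map layout: 8750 entries per spatiotemporal feature, F8 last
  map <- featureIndexMap()
  expect_equal(nrow(map), 61251)
  expect_equal(sum(map$feature == "F4"), 8750)
  expect_equal(map$feature[61251], "F8")
  # spot-check the mapping against the array
  i <- map[map$feature == "F3" & map$pulse == 2 & map$row == 27 &
             map$col == 18, "index"]
  expect_equal(v[i], ft@values[3, 2, 27, 18])
})

test_that("features are nonnegative wherever defined from valid pairs", {
  x <- noisyCube()
  ft <- computeTstmsFeatures(x$cube)
  for (f in c("F2", "F3", "F4", "F5", "F6", "F7")) {
    expect_true(all(featureArray(ft, f) >= 0))
  }
})

test_that("class templates concentrate feature differences on their support", {
  # two subjects' worth of A (cheek-boosted) and N trials
  tpl <- defaultClassTemplates()
  p <- subjectProfile("S1", heartRateHz = 1.3, phaseMapSeed = 5L)
  fA <- computeTstmsFeatures(preprocessRecording(
    renderRecording(p, tpl$A, defaultOptics(), seed = 31L,
                    ampJitterSd = 0)))
  fN <- computeTstmsFeatures(preprocessRecording(
    renderRecording(p, tpl$N, defaultOptics(), seed = 32L,
                    ampJitterSd = 0)))
  d <- abs(featureArray(fA, "F4") - featureArray(fN, "F4"))
  dmap <- apply(d, c(2, 3), mean)
  reg <- defaultRois()
  support <- reg$left_cheek | reg$right_cheek
  face <- faceMaskDefault()
  expect_gt(mean(dmap[support]), 5 * mean(dmap[!faceMaskDilated()] + 1e-9))
  expect_gt(mean(dmap[support]), 2 * mean(dmap[face & !support]))
})
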