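# Synthetic multispectral simulator: forward-model contracts, geometry,
# cohort bookkeeping, determinism.

test_that("zero modulation with zero noise gives temporally constant pixels", {
  p <- subjectProfile("S1", heartRateHz = 1.2, phaseMapSeed = 1L)
  tpl <- defaultClassTemplates(strength = 0, dzBase = 0)$N
  rec <- renderRecording(p, tpl, oracleOptics(), seed = 1L,
                         ampJitterSd = 0)
  g <- channelFrames(rec, "G")
  expect_lt(max(apply(g[, seq(10, 90, 20), seq(10, 60, 10)], c(2, 3), sd)),
            1e-9)
})

test_that("rendered extremes follow the Beer-Lambert closed forms", {
  rec <- oracleRecording()
  p <- 27L
  q <- 18L # interior face pixel on the analysis grid
  cube <- preprocessRecording(rec)
  al <- c(R = 0.3, G = 0.8, B = 0.9, NIR = 0.45)
  base <- c(R = 160, G = 120, B = 90, NIR = 130)
  dz <- 0.15
  for (ch in c("R", "G", "B", "NIR")) {
    s <- cubeData(cube)[match(ch, c("R", "G", "B", "NIR", "LWIR")), , p, q]
    expect_equal(max(s), base[[ch]] * exp(-al[[ch]]), tolerance = 1e-9)
    expect_equal(log(max(s) / min(s)), al[[ch]] * dz, tolerance = 1e-9)
    expect_equal(max(s) - min(s),
                 base[[ch]] * exp(-al[[ch]]) * (1 - exp(-al[[ch]] * dz)),
                 tolerance = 1e-9)
  }
})

test_that("quantized rendering matches closed forms within one gray level", {
  p <- subjectProfile("S1", heartRateHz = 1.25, phaseMapSeed = 42L)
  opt <- new("OpticsModel", alpha = c(R = 0.3, G = 0.8, B = 0.9,
                                      NIR = 0.45),
             z0 = 1, specularRs = 0,
             noiseSd = c(R = 0, G = 0, B = 0, NIR = 0, LWIR = 0),
             quantize = TRUE)
  rec <- renderRecording(p, defaultClassTemplates(strength = 0)$N, opt,
                         seed = 3L, phaseAmplitude = 0, ampJitterSd = 0)
  s <- channelFrames(rec, "G")[, 100, 70]
  expect_lt(abs(max(s) - 120 * exp(-0.8)), 1)
  expect_lt(abs((max(s) - min(s)) -
                  120 * exp(-0.8) * (1 - exp(-0.8 * 0.15))), 1)
})

test_that("green face-pixel spectrum peaks at the true heart rate", {
  rec <- oracleRecording(hr = 1.25)
  s <- channelFrames(rec, "G")[, 100, 70]
  # brute-force DFT oracle
  mags <- vapply(1:59, function(k) {
    Mod(sum((s - mean(s)) * exp(-2i * pi * k * (0:119) / 120)))
  }, numeric(1))
  expect_equal(30 * which.max(mags) / 120, 1.25, tolerance = 0.25)
})

test_that("thermal channel separates face and background at 30 C", {
  x <- noisyCube()
  lw <- channelFrames(x$rec, "LWIR")[1, , ]
  # native (100 x 70) coordinates mapped onto the 50 x 35 grid geometry;
  # a 2-pixel guard ring absorbs the interpolation boundary
  gr <- matrix((seq_len(100) - 0.5) / 2 + 0.25, 100, 70)
  gc <- matrix((seq_len(70) - 0.5) / 2 + 0.25, 100, 70, byrow = TRUE)
  interior <- ((gr - 27) / 15)^2 + ((gc - 18) / 8)^2 <= 1
  exterior <- ((gr - 27) / 21)^2 + ((gc - 18) / 13)^2 > 1
  expect_true(all(lw[interior] > 30))
  expect_true(all(lw[exterior] < 30))
})

test_that("out-of-band heart rates are rejected at render time", {
  p <- subjectProfile("S1", heartRateHz = 0.9, phaseMapSeed = 1L)
  tpl <- defaultClassTemplates()$S
  tpl@hrOffsetHz <- 3.2 # pushes 0.9 + 3.2 beyond the 4 Hz band edge
  expect_error(renderRecording(p, tpl, defaultOptics(), seed = 1L),
               "outside")
})

test_that("cohorts are counted, shared per subject, and deterministic", {
  co <- makeCohort(3, classes = c("A", "N"), trialsPerClass = 4, seed = 5L)
  m <- cohortManifest(co)
  expect_equal(nrow(m), 24)
  expect_equal(length(unique(m$subjectId)), 3)
  # subject-level parameters shared across that subject's trials
  expect_equal(length(unique(m$trueHr[m$classLabel == "N"])), 3)
  co2 <- makeCohort(3, classes = c("A", "N"), trialsPerClass = 4, seed = 5L)
  expect_identical(m, cohortManifest(co2))
  expect_identical(renderTrial(co, 2)@channels, renderTrial(co2, 2)@channels)
})

test_that("per-class counts reproduce the study's 130 trials per subject", {
  counts <- c(S = 27, N = 30, D = 26, F = 22, A = 25)
  co <- makeCohort(2, classes = names(counts), trialsPerClass = counts,
                   seed = 2L)
  m <- cohortManifest(co)
  expect_equal(unname(table(m$subjectId)), rep(130L, 2),
               ignore_attr = TRUE)
})

test_that("degenerate cohort requests are rejected", {
  expect_error(makeCohort(1, trialsPerClass = 2), "at least 2")
  expect_error(makeCohort(3, classes = c("A", "N"),
                          trialsPerClass = c(A = 0, N = 0)), "zero")
})

test_that("neutral template carries the smallest modulation energy", {
  tpl <- defaultClassTemplates()
  en <- vapply(tpl, function(t) sum(t@dzMap^2), numeric(1))
  expect_true(all(en["N"] < en[setdiff(names(en), "N")]))
  # class modulation vanishes off the face
  face <- faceMaskDefault()
  for (t in tpl) expect_true(all(t@dzMap[!face] == 0))
})

test_that("optics model enforces the hemoglobin absorption ordering", {
  expect_error(new("OpticsModel",
                   alpha = c(R = 0.9, G = 0.8, B = 0.3, NIR = 0.45),
                   z0 = 1, specularRs = 0,
                   noiseSd = c(R = 0, G = 0, B = 0, NIR = 0, LWIR = 0),
                   quantize = FALSE),
               "alpha_B")
})
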