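# Shared fixtures. Expensive simulated cohorts are built once per test run
# and memoized; everything is generated in code from fixed seeds.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, maker) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- maker()
  .fixtures[[key]]
}

# exact-oracle optics: no specular term, no noise, no quantization
oracleOptics <- function() {
  new("OpticsModel", alpha = c(R = 0.3, G = 0.8, B = 0.9, NIR = 0.45),
      z0 = 1, specularRs = 0,
      noiseSd = c(R = 0, G = 0, B = 0, NIR = 0, LWIR = 0), quantize = FALSE)
}

# one noiseless, unquantized, in-phase recording with uniform face dz
oracleRecording <- function(hr = 1.25) {
  fixture(paste0("oracle-", hr), function() {
    p <- subjectProfile("S1", heartRateHz = hr, phaseMapSeed = 42L)
    renderRecording(p, defaultClassTemplates(strength = 0)$N,
                    oracleOptics(), seed = 3L, phaseAmplitude = 0,
                    ampJitterSd = 0)
  })
}

# a typical noisy recording + its cube (default optics, amusement template)
noisyCube <- function() {
  fixture("noisy-cube", function() {
    p <- subjectProfile("S1", heartRateHz = 1.25, phaseMapSeed = 42L)
    rec <- renderRecording(p, defaultClassTemplates()$A, defaultOptics(),
                           seed = 7L)
    list(rec = rec, cube = preprocessRecording(rec), trueHr = 1.25)
  })
}

# the end-to-end study cohort: 10 subjects x 5 classes x 6 trials, strong
# disjoint class templates, default (moderate) sensor noise; built on
# demand and not memoized -- at 300 x 61,251 it is the single largest
# object a test run holds and is released as soon as its test finishes
strongCohortFeatures <- function() {
  co <- makeCohort(10, trialsPerClass = 6, seed = 101L)
  cohortFeatureMatrix(co)
}

# small feature matrix with a known informative pixel region, built directly
# (no rendering): class B trials carry extra signal on given flat indices
syntheticFeatureMatrix <- function(n = 40, informative, effect = 3,
                                   nSubjects = 4, seed = 9L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- matrix(rnorm(n * 61251, 0, 1), n, 61251)
  lab <- rep(c("A", "N"), length.out = n)
  x[lab == "A", informative] <- x[lab == "A", informative] + effect
  # subjects in blocks, so each subject sees both classes
  subj <- rep(sprintf("S%02d", seq_len(nSubjects)),
              each = ceiling(n / nSubjects))[seq_len(n)]
  meta <- data.frame(
    subjectId = subj, classLabel = lab, gender = "F",
    stringsAsFactors = FALSE
  )
  list(x = x, meta = meta)
}
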