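## Synthetic multispectral face-video simulator.
##
## The forward model is the package's own Beer-Lambert skin-optics model:
## each reflective-channel face pixel emits
##   I(x, y, t) = R_S + A(x, y) * exp(-alpha * z(x, y, t)) + noise,
##   z(x, y, t) = z0 + dz(x, y) * (1 + sin(2 pi f t + phi(x, y))) / 2,
## so the optical path length is modulated at the heart rate f between z0
## and z0 + dz. The thermal channel carries a slow temperature drift and no
## pulsatile term. Class identity enters only through the class template:
## where dz is boosted, how the skin temperature drifts, and an optional
## heart-rate offset.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Elliptical face mask on the analysis grid
#'
#' The simulated face is an ellipse covering most of the 50 x 35 grid; the
#' chin occupies the bottom rows so chin-mask handling is exercisable.
#'
#' @return 50 x 35 logical matrix.
#' @export
faceMaskDefault <- function() {
  r <- matrix(seq_len(GRID_ROWS), GRID_ROWS, GRID_COLS)
  c <- matrix(seq_len(GRID_COLS), GRID_ROWS, GRID_COLS, byrow = TRUE)
  ((r - 27) / 18)^2 + ((c - 18) / 10)^2 <= 1
}

#' Dilated face mask covering the downsampling smear
#'
#' Pixels outside the face ellipse but within the spatial support of the
#' interpolation kernels (renderer upsampling plus the two-stage
#' downsampling, about 7 grid pixels) receive a small share of face signal.
#' This dilated mask separates genuinely signal-free background from the
#' mixed boundary ring when assessing segmentation against ground truth.
#'
#' @param radius dilation radius in grid pixels.
#' @return 50 x 35 logical matrix.
#' @export
faceMaskDilated <- function(radius = 7) {
  r <- matrix(seq_len(GRID_ROWS), GRID_ROWS, GRID_COLS)
  c <- matrix(seq_len(GRID_COLS), GRID_ROWS, GRID_COLS, byrow = TRUE)
  ((r - 27) / (18 + radius))^2 + ((c - 18) / (10 + radius))^2 <= 1
}

# Named facial regions used by the default class templates; they coincide
# with the default regions of interest of the importance module.
.faceRegions <- function() {
  r <- matrix(seq_len(GRID_ROWS), GRID_ROWS, GRID_COLS)
  c <- matrix(seq_len(GRID_COLS), GRID_ROWS, GRID_COLS, byrow = TRUE)
  ell <- function(r0, c0, ra, ca) ((r - r0) / ra)^2 + ((c - c0) / ca)^2 <= 1
  # all regions keep a >= 2 px margin from the face boundary so that the
  # downsampling halo of a modulated region falls on face pixels that carry
  # baseline pulsatile signal in every class
  face <- faceMaskDefault()
  list(
    forehead    = face & r >= 14 & r <= 19 & c >= 13 & c <= 23,
    left_eye    = face & r >= 21 & r <= 24 & c >= 11 & c <= 16,
    right_eye   = face & r >= 21 & r <= 24 & c >= 20 & c <= 25,
    left_cheek  = face & ell(30, 13.5, 4.5, 3),
    right_cheek = face & ell(30, 22.5, 4.5, 3),
    mouth       = face & ell(38, 18, 2.5, 4.5)
  )
}

#' Default per-class modulation templates
#'
#' Each emotion class modulates a distinct facial region on top of a
#' face-wide baseline pulsatile path-length modulation: amusement boosts the
#' cheeks, disgust the forehead, fear the mouth, and sexual arousal the eye
#' region plus an additive heart-rate offset; neutral adds nothing (smallest
#' total modulation energy). Temperature drift rates follow the same
#' regions. The paper-scale data give no quantitative per-emotion effect
#' sizes, so the boost magnitudes are free simulator parameters exposed via
#' \code{strength}.
#'
#' @param strength multiplier on the class-specific boosts; \code{0} yields
#'   templates that differ in label only (a negative control).
#' @param dzBase face-wide baseline modulation amplitude, depth units.
#' @param dzBoost class-region modulation boost at \code{strength = 1}.
#' @return Named list of \code{\linkS4class{ClassTemplate}} over
#'   \code{A, D, F, S, N}.
#' @export
defaultClassTemplates <- function(strength = 1, dzBase = 0.15,
                                  dzBoost = 0.25) {
  face <- faceMaskDefault()
  reg <- .faceRegions()
  base <- matrix(0, GRID_ROWS, GRID_COLS)
  base[face] <- dzBase
  zero <- matrix(0, GRID_ROWS, GRID_COLS)
  mk <- function(label, region, drift, hrOff) {
    dz <- base
    dr <- zero
    if (!is.null(region)) {
      dz[region] <- dz[region] + strength * dzBoost
      dr[region] <- strength * drift
    }
    new("ClassTemplate", classLabel = label, dzMap = dz, tempDriftMap = dr,
        hrOffsetHz = strength * hrOff)
  }
  list(
    A = mk("A", reg$left_cheek | reg$right_cheek, 0.02, 0),
    D = mk("D", reg$forehead, 0.02, 0),
    F = mk("F", reg$mouth, -0.02, 0),
    S = mk("S", reg$left_eye | reg$right_eye, 0.01, 0.3),
    N = mk("N", NULL, 0, 0)
  )
}

#' Default Beer-Lambert optics model
#'
#' Absorption coefficients follow hemoglobin's spectral ordering (strongest
#' at blue and green, weakest at red, intermediate in the near infrared).
#' Sensor noise is 2 gray levels for the reflective channels and 0.05 degrees
#' C for the thermal channel; reflective channels are quantized to 8-bit by
#' default, as the cameras are.
#'
#' @param noiseSd named noise SDs; partial overrides allowed.
#' @param quantize quantize reflective channels to integer gray levels.
#' @return An \code{\linkS4class{OpticsModel}}.
#' @export
defaultOptics <- function(noiseSd = NULL, quantize = TRUE) {
  sd <- c(R = 2, G = 2, B = 2, NIR = 2, LWIR = 0.05)
  if (!is.null(noiseSd)) sd[names(noiseSd)] <- noiseSd
  new("OpticsModel",
      alpha = c(R = 0.3, G = 0.8, B = 0.9, NIR = 0.45),
      z0 = 1, specularRs = 10, noiseSd = sd, quantize = quantize)
}

#' Default native sensor resolutions
#'
#' Modeled after a setup whose RGB camera out-resolves the NIR and thermal
#' cameras; every dimension is at least twice the analysis grid so the
#' two-stage downsampling is a genuine reduction.
#'
#' @return Named list of \code{c(H, W)} per channel.
#' @export
defaultNatives <- function() {
  list(R = c(200L, 140L), G = c(200L, 140L), B = c(200L, 140L),
       NIR = c(100L, 70L), LWIR = c(100L, 70L))
}

#' Construct a subject profile
#'
#' @param subjectId identifier.
#' @param gender \code{"F"} or \code{"M"}.
#' @param heartRateHz resting heart rate, strictly inside (0.75, 4) Hz.
#' @param skinBase named baseline diffuse amplitudes (gray levels) for
#'   \code{R, G, B, NIR}.
#' @param baseTempC baseline skin temperature, above 30 C.
#' @param phaseMapSeed seed of the subject's pulse-phase field.
#' @return A \code{\linkS4class{SubjectProfile}}.
#' @export
subjectProfile <- function(subjectId, gender = "F", heartRateHz = 1.2,
                           skinBase = c(R = 160, G = 120, B = 90, NIR = 130),
                           baseTempC = 34.5, phaseMapSeed = 1L) {
  new("SubjectProfile", subjectId = as.character(subjectId),
      gender = gender, heartRateHz = heartRateHz, skinBase = skinBase,
      baseTempC = baseTempC, phaseMapSeed = as.integer(phaseMapSeed))
}

# smooth low-amplitude spatial phase field (<= maxPhase radians), mimicking
# pulse-transit-time variation across the face without breaking per-pixel
# peak detection
.phaseField <- function(seed, maxPhase = 0.3) {
  .withSeed(seed, {
    th <- runif(2, 0, 2 * pi)
    r <- matrix(seq_len(GRID_ROWS) / GRID_ROWS, GRID_ROWS, GRID_COLS)
    c <- matrix(seq_len(GRID_COLS) / GRID_COLS, GRID_ROWS, GRID_COLS,
                byrow = TRUE)
    maxPhase * sin(2 * pi * r + th[1]) * cos(2 * pi * c + th[2])
  })
}

#' Render one synthetic multispectral recording
#'
#' Applies the Beer-Lambert forward model on the 50 x 35 template grid,
#' upsamples each frame to the requested native resolution (bicubic), adds
#' sensor noise and optionally quantizes. The thermal channel renders the
#' face above 30 C on a cooler background with the template's drift rates.
#'
#' @param profile a \code{\linkS4class{SubjectProfile}}.
#' @param template a \code{\linkS4class{ClassTemplate}}.
#' @param optics an \code{\linkS4class{OpticsModel}}.
#' @param durationS duration in seconds; \code{durationS * fs} must be at
#'   least 120 frames.
#' @param fs frame rate, Hz.
#' @param natives named list of native \code{c(H, W)} per channel; each
#'   dimension must be at least twice the analysis grid.
#' @param seed integer; identical seeds give identical recordings.
#' @param bgVis,bgTempC background gray level / temperature.
#' @param phaseAmplitude amplitude (radians) of the subject's spatial
#'   pulse-phase field; 0 makes every pixel pulse in phase, which lets the
#'   sampled extremes hit the analytic ones exactly (exact-oracle mode).
#' @param ampJitterSd log-scale SD of a per-trial multiplicative factor on
#'   the modulation amplitudes (vasomotor tone varies between trials); 0
#'   disables it (exact-oracle mode).
#' @return A \code{\linkS4class{MultispectralRecording}} whose \code{meta}
#'   holds the true heart rate and the grid face mask.
#' @export
renderRecording <- function(profile, template, optics, durationS = 4,
                            fs = 30, natives = defaultNatives(), seed = 1L,
                            bgVis = 40, bgTempC = 22, phaseAmplitude = 0.3,
                            ampJitterSd = 0.2) {
  f <- profile@heartRateHz + template@hrOffsetHz
  if (f <= 0.75 || f >= 4) {
    stop("effective heart rate ", f,
         " Hz outside (0.75, 4): the analysis band would reject it")
  }
  T <- as.integer(round(durationS * fs))
  if (T < N_FRAMES) stop("durationS * fs must give at least 120 frames")
  for (ch in CHANNELS) {
    if (any(natives[[ch]] < 2L * c(GRID_ROWS, GRID_COLS))) {
      stop("native resolution of ", ch,
           " must be at least twice the 50 x 35 analysis grid")
    }
  }
  face <- faceMaskDefault()
  faceIdx <- which(as.vector(face))
  phi <- .phaseField(profile@phaseMapSeed, phaseAmplitude)
  tt <- (seq_len(T) - 1L) / fs
  dzF <- template@dzMap[face]
  phiF <- phi[face]

  .withSeed(seed, {
    channels <- vector("list", length(CHANNELS))
    names(channels) <- CHANNELS
    if (ampJitterSd > 0) {
      dzF <- dzF * exp(rnorm(1, 0, ampJitterSd))
    }
    # T x nf modulation: (1 + sin(2 pi f t + phi)) / 2 in [0, 1]
    mod <- (1 + sin(outer(2 * pi * f * tt, phiF, `+`))) / 2
    for (ch in VIS_CHANNELS) {
      al <- optics@alpha[[ch]]
      amp <- profile@skinBase[[ch]]
      z <- optics@z0 + sweep(mod, 2L, dzF, `*`)
      ifacet <- optics@specularRs + amp * exp(-al * z) # T x n_face_px
      grid <- matrix(bgVis, T, GRID_ROWS * GRID_COLS)
      grid[, faceIdx] <- ifacet
      dim(grid) <- c(T, GRID_ROWS, GRID_COLS)
      channels[[ch]] <- .renderNative(grid, natives[[ch]],
                                      optics@noiseSd[[ch]],
                                      quantize = optics@quantize)
    }
    drift <- template@tempDriftMap[face]
    lw <- matrix(bgTempC, T, GRID_ROWS * GRID_COLS)
    lw[, faceIdx] <- profile@baseTempC + outer(tt, drift)
    dim(lw) <- c(T, GRID_ROWS, GRID_COLS)
    channels[["LWIR"]] <- .renderNative(lw, natives[["LWIR"]],
                                        optics@noiseSd[["LWIR"]],
                                        quantize = FALSE)
    new("MultispectralRecording", channels = channels, fs = fs,
        subjectId = profile@subjectId, classLabel = template@classLabel,
        gender = profile@gender,
        meta = list(trueHr = f, faceMask = face, seed = as.integer(seed)))
  })
}

# upsample a (T, 50, 35) grid stack to native (H, W), add noise, quantize
.renderNative <- function(grid, native, noiseSd, quantize) {
  out <- .lincombFrames(grid, .bicubicW(GRID_ROWS, native[1]),
                        .bicubicW(GRID_COLS, native[2]))
  d <- dim(out)
  out <- .noise_quantize_cpp(out, noiseSd, quantize)
  dim(out) <- d
  out
}

#' Simulate a cohort of subjects and trials
#'
#' Subject-level parameters (heart rate, skin baseline, temperature, phase
#' field) are drawn once per subject and shared across that subject's
#' trials. The cohort object stores only the manifest and parameters;
#' \code{\link{renderTrial}} materializes any trial's frames on demand,
#' reproducibly from the cohort seed.
#'
#' @param nSubjects number of subjects (at least 2).
#' @param classes class labels to include.
#' @param trialsPerClass single count or named per-class counts.
#' @param seed cohort seed.
#' @param templates,optics,natives simulator components (defaults:
#'   \code{\link{defaultClassTemplates}}, \code{\link{defaultOptics}},
#'   \code{\link{defaultNatives}}).
#' @param fs,durationS frame rate and duration.
#' @param hrRange range the subjects' resting heart rates are drawn from.
#' @param ... extra arguments stored and forwarded to
#'   \code{\link{renderRecording}} at render time (e.g.
#'   \code{ampJitterSd = 0} for exact-oracle cohorts).
#' @return A \code{\linkS4class{SimulatedCohort}}.
#' @export
makeCohort <- function(nSubjects, classes = CLASS_LEVELS, trialsPerClass = 4,
                       seed = 1L, templates = defaultClassTemplates(),
                       optics = defaultOptics(), natives = defaultNatives(),
                       fs = 30, durationS = 4, hrRange = c(0.9, 1.9), ...) {
  if (nSubjects < 2) stop("need at least 2 subjects")
  classes <- match.arg(classes, CLASS_LEVELS, several.ok = TRUE)
  if (length(trialsPerClass) == 1L && is.null(names(trialsPerClass))) {
    trialsPerClass <- setNames(rep(trialsPerClass, length(classes)), classes)
  }
  trialsPerClass <- trialsPerClass[classes]
  if (any(is.na(trialsPerClass)) || all(trialsPerClass == 0)) {
    stop("trialsPerClass must cover every class and not be all zero")
  }
  .withSeed(seed, {
    profiles <- lapply(seq_len(nSubjects), function(i) {
      subjectProfile(
        subjectId = sprintf("S%03d", i),
        gender = c("F", "M")[(i - 1L) %% 2L + 1L],
        heartRateHz = runif(1, hrRange[1], hrRange[2]),
        skinBase = c(R = runif(1, 140, 180), G = runif(1, 100, 140),
                     B = runif(1, 70, 110), NIR = runif(1, 110, 150)),
        baseTempC = runif(1, 33, 36),
        phaseMapSeed = sample.int(.Machine$integer.max - 1L, 1L)
      )
    })
    names(profiles) <- vapply(profiles, function(p) p@subjectId,
                              character(1))
    rows <- do.call(rbind, lapply(profiles, function(p) {
      do.call(rbind, lapply(classes, function(cl) {
        n <- trialsPerClass[[cl]]
        if (n == 0) return(NULL)
        data.frame(subjectId = p@subjectId, classLabel = cl,
                   gender = p@gender,
                   trueHr = p@heartRateHz + templates[[cl]]@hrOffsetHz,
                   stringsAsFactors = FALSE)[rep(1L, n), ]
      }))
    }))
    rownames(rows) <- NULL
    rows$trial <- seq_len(nrow(rows))
    rows$seed <- sample.int(.Machine$integer.max - 1L, nrow(rows))
    rows <- rows[, c("trial", "subjectId", "classLabel", "gender", "trueHr",
                     "seed")]
    new("SimulatedCohort", manifest = rows, profiles = profiles,
        templates = templates, optics = optics, fs = fs,
        durationS = durationS, natives = natives,
        renderArgs = list(...), seed = as.integer(seed))
  })
}

#' Materialize one cohort trial
#'
#' @param cohort a \code{\linkS4class{SimulatedCohort}}.
#' @param i trial index into the manifest.
#' @return A \code{\linkS4class{MultispectralRecording}}.
#' @export
renderTrial <- function(cohort, i) {
  row <- cohort@manifest[i, ]
  do.call(renderRecording, c(
    list(cohort@profiles[[row$subjectId]],
         cohort@templates[[row$classLabel]], cohort@optics,
         durationS = cohort@durationS, fs = cohort@fs,
         natives = cohort@natives, seed = row$seed),
    cohort@renderArgs
  ))
}

#' Materialize every recording of a cohort
#'
#' Convenience for small cohorts; large cohorts should be streamed trial by
#' trial with \code{\link{renderTrial}}.
#'
#' @param cohort a \code{\linkS4class{SimulatedCohort}}.
#' @return List of \code{\linkS4class{MultispectralRecording}}.
#' @export
cohortRecordings <- function(cohort) {
  lapply(seq_len(nTrials(cohort)), function(i) renderTrial(cohort, i))
}
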