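## Central S4 containers. All spatial grids are 50 x 35 (rows = face height,
## cols = face width, origin top-left); the pulse-frame axis has length 5.

#' SubjectProfile: per-subject simulation ground truth
#'
#' Describes one simulated subject: identity, gender, resting heart rate,
#' per-channel baseline skin intensity (the diffuse amplitude reaching the
#' camera), baseline skin temperature and the seed of the subject's spatial
#' pulse-phase field.
#'
#' @slot subjectId character identifier.
#' @slot gender \code{"F"} or \code{"M"}.
#' @slot heartRateHz resting heart rate; must lie strictly inside the
#'   analysis band (0.75, 4) Hz.
#' @slot skinBase named numeric, baseline gray level per channel
#'   (\code{R, G, B, NIR}).
#' @slot baseTempC baseline facial skin temperature, degrees C; must exceed
#'   30 so that thermal face segmentation by the 30-degree rule succeeds.
#' @slot phaseMapSeed integer seed of the subject's pulse-phase field.
#' @export
setClass("SubjectProfile", representation(
  subjectId = "character", gender = "character", heartRateHz = "numeric",
  skinBase = "numeric", baseTempC = "numeric", phaseMapSeed = "integer"
), validity = function(object) {
  msg <- NULL
  if (!(object@heartRateHz > 0.75 && object@heartRateHz < 4)) {
    msg <- c(msg, "heartRateHz must lie strictly inside (0.75, 4) Hz")
  }
  if (object@baseTempC <= 30) {
    msg <- c(msg, "baseTempC must exceed 30 C")
  }
  if (!all(VIS_CHANNELS %in% names(object@skinBase))) {
    msg <- c(msg, "skinBase needs entries R, G, B, NIR")
  }
  if (!object@gender %in% c("F", "M")) {
    msg <- c(msg, "gender must be 'F' or 'M'")
  }
  if (is.null(msg)) TRUE else msg
})

#' ClassTemplate: spatial modulation template of one stimulus class
#'
#' Holds what makes a stimulus class physiologically distinct in the
#' simulator: a 50 x 35 map of additional optical path-length modulation
#' amplitudes (arbitrary depth units; zero outside the face), a map of slow
#' skin-temperature drift rates, and an additive heart-rate offset.
#'
#' @slot classLabel one of \code{A, D, F, S, N}.
#' @slot dzMap 50 x 35 nonnegative path-length modulation amplitudes.
#' @slot tempDriftMap 50 x 35 temperature drift rates, degrees C per second.
#' @slot hrOffsetHz additive heart-rate shift, Hz.
#' @export
setClass("ClassTemplate", representation(
  classLabel = "character", dzMap = "matrix", tempDriftMap = "matrix",
  hrOffsetHz = "numeric"
), validity = function(object) {
  msg <- NULL
  if (!identical(dim(object@dzMap), c(GRID_ROWS, GRID_COLS))) {
    msg <- c(msg, "dzMap must be 50 x 35")
  }
  if (!identical(dim(object@tempDriftMap), c(GRID_ROWS, GRID_COLS))) {
    msg <- c(msg, "tempDriftMap must be 50 x 35")
  }
  if (any(object@dzMap < 0)) msg <- c(msg, "dzMap must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' OpticsModel: Beer-Lambert forward model of the simulated skin
#'
#' Light reaching the camera from a skin pixel is modeled as a constant
#' specular term plus a diffuse term attenuated exponentially along the
#' optical path: \eqn{I = R_S + A \exp(-\alpha z)}. Pulsation modulates the
#' path length \eqn{z}, which is what the pulsatile features recover.
#'
#' @slot alpha named numeric, absorption coefficient per depth unit for
#'   \code{R, G, B, NIR}. Hemoglobin absorption peaks at the blue and green
#'   wavelengths, so \code{alpha["B"] >= alpha["G"] > alpha["R"]} is
#'   enforced.
#' @slot z0 baseline optical path depth (depth units).
#' @slot specularRs constant specular reflection term (gray levels).
#' @slot noiseSd named numeric, sensor noise SD per channel (gray levels for
#'   the reflective channels, degrees C for LWIR).
#' @slot quantize logical; quantize reflective channels to 8-bit gray levels.
#' @export
setClass("OpticsModel", representation(
  alpha = "numeric", z0 = "numeric", specularRs = "numeric",
  noiseSd = "numeric", quantize = "logical"
), validity = function(object) {
  msg <- NULL
  a <- object@alpha
  if (!all(VIS_CHANNELS %in% names(a))) {
    msg <- c(msg, "alpha needs entries R, G, B, NIR")
  } else if (!(a["B"] >= a["G"] && a["G"] > a["R"])) {
    msg <- c(msg, "need alpha_B >= alpha_G > alpha_R (hemoglobin absorption)")
  }
  if (!all(CHANNELS %in% names(object@noiseSd))) {
    msg <- c(msg, "noiseSd needs entries for all five channels")
  }
  if (is.null(msg)) TRUE else msg
})

#' MultispectralRecording: one trial's synchronized frame stacks
#'
#' @slot channels named list of \code{T x H x W} arrays for
#'   \code{R, G, B, NIR} (gray level) and \code{LWIR} (degrees C). Native
#'   resolutions may differ between channels.
#' @slot fs frame rate, Hz, shared by all channels.
#' @slot subjectId,classLabel,gender trial metadata.
#' @slot meta list of auxiliary ground truth (simulator only): true heart
#'   rate, face mask on the analysis grid, per-channel face bounding boxes.
#' @export
setClass("MultispectralRecording", representation(
  channels = "list", fs = "numeric", subjectId = "character",
  classLabel = "character", gender = "character", meta = "list"
), validity = function(object) {
  msg <- NULL
  if (!all(CHANNELS %in% names(object@channels))) {
    msg <- c(msg, "channels must contain R, G, B, NIR, LWIR")
  }
  if (!all(vapply(object@channels, function(x) length(dim(x)) == 3L,
                  logical(1)))) {
    msg <- c(msg, "every channel must be a T x H x W array")
  }
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (is.null(msg)) TRUE else msg
})

#' DownsampledCube: all five channels on the common analysis grid
#'
#' @slot data numeric array \code{(channel = 5, T, 50, 35)} with channel
#'   order \code{R, G, B, NIR, LWIR}.
#' @slot fs frame rate, Hz.
#' @export
setClass("DownsampledCube", representation(
  data = "array", fs = "numeric"
), validity = function(object) {
  d <- dim(object@data)
  msg <- NULL
  if (length(d) != 4L || d[1] != 5L || d[3] != GRID_ROWS ||
      d[4] != GRID_COLS) {
    msg <- c(msg, "data must have shape (5, T, 50, 35)")
  }
  if (!all(is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (is.null(msg)) TRUE else msg
})

#' FrequencyMap: per-pixel dominant frequencies and the coherent-pulse mask
#'
#' @slot freqs 50 x 35 matrix of dominant frequencies, Hz.
#' @slot power 50 x 35 matrix of the spectral magnitude at the dominant
#'   frequency (arbitrary units).
#' @slot mask 50 x 35 logical matrix; masked-in pixels carry a coherent
#'   pulsatile signal and their frequencies lie in the analysis band.
#' @export
setClass("FrequencyMap", representation(
  freqs = "matrix", power = "matrix", mask = "matrix"
), validity = function(object) {
  msg <- NULL
  if (!identical(dim(object@freqs), c(GRID_ROWS, GRID_COLS)) ||
      !identical(dim(object@mask), c(GRID_ROWS, GRID_COLS))) {
    msg <- c(msg, "freqs and mask must be 50 x 35")
  }
  if (length(msg) == 0) {
    inband <- object@freqs[object@mask]
    inband <- inband[inband > 0]
    if (length(inband) && (min(inband) < 0.75 || max(inband) > 4)) {
      msg <- c(msg, "masked-in nonzero frequencies must lie in [0.75, 4] Hz")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' PulseFrameStack: aligned per-pulse peak and trough images
#'
#' For each reflective channel, \code{Imax[p, , ]} and \code{Imin[p, , ]}
#' hold the pixel gray level at the p-th detected pulse peak and its
#' following trough. Pixels with fewer than 5 detected pulses are
#' zero-padded.
#'
#' @slot imax,imin named lists over \code{R, G, B, NIR} of
#'   \code{(5, 50, 35)} arrays.
#' @slot npairs named list of 50 x 35 matrices counting the detected
#'   peak-trough pairs per pixel (before truncation to 5).
#' @export
setClass("PulseFrameStack", representation(
  imax = "list", imin = "list", npairs = "list"
), validity = function(object) {
  msg <- NULL
  for (ch in VIS_CHANNELS) {
    a <- object@imax[[ch]]
    b <- object@imin[[ch]]
    if (is.null(a) || is.null(b) ||
        !identical(dim(a), c(N_PULSE, GRID_ROWS, GRID_COLS)) ||
        !identical(dim(b), c(N_PULSE, GRID_ROWS, GRID_COLS))) {
      msg <- c(msg, sprintf("channel %s must hold (5, 50, 35) arrays", ch))
      next
    }
    live <- a > 0 & b > 0
    if (any(a[live] < b[live])) {
      msg <- c(msg, sprintf("Imax < Imin at non-padded entries of %s", ch))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' TSTMSFeatures: the eight transdermal spatiotemporal multispectral features
#'
#' F1 is the low-passed LWIR temperature track; F2-F4 and F7 are the
#' pulsatile amplitudes (Imax - Imin) of R, G, B and NIR; F5 is the B/R
#' pulsatile-amplitude ratio; F6 the baseline-adjusted absolute absorption
#' difference between R and B; F8 the green-channel estimated heart rate.
#'
#' @slot values numeric array \code{(7, 5, 50, 35)} holding F1..F7 on the
#'   (feature, pulse frame, row, col) axes.
#' @slot f8 scalar estimated heart rate, Hz.
#' @slot chinMask 50 x 35 logical; \code{TRUE} pixels were zeroed in F1-F7
#'   to remove the chin head mount.
#' @export
setClass("TSTMSFeatures", representation(
  values = "array", f8 = "numeric", chinMask = "matrix"
), validity = function(object) {
  msg <- NULL
  if (!identical(dim(object@values), c(7L, N_PULSE, GRID_ROWS, GRID_COLS))) {
    msg <- c(msg, "values must have shape (7, 5, 50, 35)")
  }
  if (length(object@f8) != 1L) msg <- c(msg, "f8 must be a scalar")
  if (is.null(msg)) TRUE else msg
})

#' ImportanceTensor: per-parameter classifier importance, in percent
#'
#' @slot values nonnegative array \code{(7, 5, 50, 35)} over (feature, pulse
#'   frame, row, col).
#' @slot f8Value importance of the scalar heart-rate feature F8.
#' @details All entries plus \code{f8Value} sum to 100.
#' @export
setClass("ImportanceTensor", representation(
  values = "array", f8Value = "numeric"
), validity = function(object) {
  msg <- NULL
  if (!identical(dim(object@values), c(7L, N_PULSE, GRID_ROWS, GRID_COLS))) {
    msg <- c(msg, "values must have shape (7, 5, 50, 35)")
  }
  if (any(object@values < 0)) msg <- c(msg, "importances must be nonnegative")
  tot <- sum(object@values) + object@f8Value
  if (abs(tot - 100) > 1e-6) {
    msg <- c(msg, "entries plus f8Value must sum to 100")
  }
  if (is.null(msg)) TRUE else msg
})

#' OvoModel: one-vs-one ensemble of binary gradient-boosted classifiers
#'
#' @slot models list of \code{k (k - 1) / 2} fitted binary xgboost boosters,
#'   named \code{"X|Y"} for the class pair (X, Y).
#' @slot classLevels character vector of the k class labels.
#' @slot params list of training hyperparameters.
#' @slot seed integer training seed.
#' @export
setClass("OvoModel", representation(
  models = "list", classLevels = "character", params = "list",
  seed = "integer"
))

#' MetricsReport: classification metrics under leave-one-subject-out CV
#'
#' @slot aucPerClass named numeric, fold-averaged one-vs-rest ROC AUC.
#' @slot balancedAccPerClass named numeric, fold-averaged balanced accuracy
#'   of the final decisions.
#' @slot subsetAccuracy overall exact-match accuracy.
#' @slot confusion 5 x 5 row-normalized (percent) elementwise median of the
#'   per-fold confusion matrices.
#' @slot folds data.frame with one row per scored trial (subject, truth,
#'   prediction, class probabilities).
#' @slot seed integer evaluation seed (undersampling and training).
#' @export
setClass("MetricsReport", representation(
  aucPerClass = "numeric", balancedAccPerClass = "numeric",
  subsetAccuracy = "numeric", confusion = "matrix", folds = "data.frame",
  seed = "integer"
))

#' SimulatedCohort: manifest plus deterministic per-trial render recipe
#'
#' Frame stacks are large, so a cohort stores only the per-subject profiles,
#' the class templates, the optics model and a manifest of trials with
#' per-trial seeds; \code{\link{renderTrial}} materializes any trial on
#' demand, byte-identically for a fixed cohort seed.
#'
#' @slot manifest data.frame: trial, subjectId, classLabel, gender, trueHr,
#'   seed.
#' @slot profiles named list of \code{\linkS4class{SubjectProfile}}.
#' @slot templates named list of \code{\linkS4class{ClassTemplate}}.
#' @slot optics an \code{\linkS4class{OpticsModel}}.
#' @slot fs frame rate, Hz. @slot durationS trial duration, seconds.
#' @slot natives named list of per-channel native \code{c(H, W)}.
#' @slot renderArgs list of extra arguments forwarded to
#'   \code{\link{renderRecording}} (e.g. \code{ampJitterSd}).
#' @slot seed cohort seed.
#' @export
setClass("SimulatedCohort", representation(
  manifest = "data.frame", profiles = "list", templates = "list",
  optics = "OpticsModel", fs = "numeric", durationS = "numeric",
  natives = "list", renderArgs = "list", seed = "integer"
))
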