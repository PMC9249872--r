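#' @name tstms-accessors
#' @title Accessors for the core containers
#' @description Slot accessors; user code should use these rather than
#'   \code{@}.
#' @param x an object.
#' @param ... unused.
NULL

#' @rdname tstms-accessors
#' @export
setGeneric("cubeData", function(x, ...) standardGeneric("cubeData"))
#' @rdname tstms-accessors
#' @export
setMethod("cubeData", "DownsampledCube", function(x, ...) x@data)

#' @rdname tstms-accessors
#' @export
setGeneric("frameRate", function(x, ...) standardGeneric("frameRate"))
#' @rdname tstms-accessors
#' @export
setMethod("frameRate", "DownsampledCube", function(x, ...) x@fs)
#' @rdname tstms-accessors
#' @export
setMethod("frameRate", "MultispectralRecording", function(x, ...) x@fs)

#' @rdname tstms-accessors
#' @param channel channel name (\code{"R"}, \code{"G"}, \code{"B"},
#'   \code{"NIR"}, \code{"LWIR"}).
#' @export
setGeneric("channelFrames", function(x, channel, ...) {
  standardGeneric("channelFrames")
})
#' @rdname tstms-accessors
#' @export
setMethod("channelFrames", "MultispectralRecording", function(x, channel,
                                                              ...) {
  ch <- match.arg(channel, CHANNELS)
  x@channels[[ch]]
})

#' @rdname tstms-accessors
#' @export
setGeneric("subjectId", function(x, ...) standardGeneric("subjectId"))
#' @rdname tstms-accessors
#' @export
setMethod("subjectId", "MultispectralRecording", function(x, ...) {
  x@subjectId
})

#' @rdname tstms-accessors
#' @export
setGeneric("trialClass", function(x, ...) standardGeneric("trialClass"))
#' @rdname tstms-accessors
#' @export
setMethod("trialClass", "MultispectralRecording", function(x, ...) {
  x@classLabel
})

#' @rdname tstms-accessors
#' @export
setGeneric("domFreqs", function(x, ...) standardGeneric("domFreqs"))
#' @rdname tstms-accessors
#' @export
setMethod("domFreqs", "FrequencyMap", function(x, ...) x@freqs)

#' @rdname tstms-accessors
#' @export
setGeneric("freqMask", function(x, ...) standardGeneric("freqMask"))
#' @rdname tstms-accessors
#' @export
setMethod("freqMask", "FrequencyMap", function(x, ...) x@mask)

#' @rdname tstms-accessors
#' @param feature feature name \code{"F1"}..\code{"F7"}.
#' @export
setGeneric("featureArray", function(x, feature, ...) {
  standardGeneric("featureArray")
})
#' @rdname tstms-accessors
#' @export
setMethod("featureArray", "TSTMSFeatures", function(x, feature, ...) {
  i <- match(feature, paste0("F", 1:7))
  if (is.na(i)) stop("feature must be one of F1..F7 (F8 is a scalar: hr())")
  x@values[i, , , ]
})

#' @rdname tstms-accessors
#' @export
setGeneric("hr", function(x, ...) standardGeneric("hr"))
#' @rdname tstms-accessors
#' @export
setMethod("hr", "TSTMSFeatures", function(x, ...) x@f8)

#' @rdname tstms-accessors
#' @export
setGeneric("cohortManifest", function(x, ...) {
  standardGeneric("cohortManifest")
})
#' @rdname tstms-accessors
#' @export
setMethod("cohortManifest", "SimulatedCohort", function(x, ...) x@manifest)

#' @rdname tstms-accessors
#' @export
setGeneric("nTrials", function(x, ...) standardGeneric("nTrials"))
#' @rdname tstms-accessors
#' @export
setMethod("nTrials", "SimulatedCohort", function(x, ...) nrow(x@manifest))

setMethod("show", "MultispectralRecording", function(object) {
  d <- vapply(object@channels, function(x) paste(dim(x), collapse = "x"),
              character(1))
  cat("MultispectralRecording |", object@subjectId, "| class",
      object@classLabel, "| gender", object@gender, "|", object@fs, "fps\n")
  cat("  channels:", paste(sprintf("%s[%s]", names(d), d), collapse = " "),
      "\n")
})

setMethod("show", "DownsampledCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("DownsampledCube | %d channels x %d frames x %dx%d @ %g fps\n",
              d[1], d[2], d[3], d[4], object@fs))
})

setMethod("show", "FrequencyMap", function(object) {
  nz <- object@freqs[object@mask]
  nz <- nz[nz > 0]
  cat(sprintf("FrequencyMap | %d masked-in pixels", sum(object@mask)))
  if (length(nz)) cat(sprintf(" | median %.3g Hz", stats::median(nz)))
  cat("\n")
})

setMethod("show", "TSTMSFeatures", function(object) {
  cat(sprintf(
    "TSTMSFeatures | F1-F7 (7 x 5 x 50 x 35) + F8 = %.3g Hz | %d chin px\n",
    object@f8, sum(object@chinMask)))
})

setMethod("show", "ImportanceTensor", function(object) {
  perFeat <- apply(object@values, 1, sum)
  cat("ImportanceTensor (percent)\n  F1..F7:",
      paste(sprintf("%.2f", perFeat), collapse = " "),
      sprintf("| F8: %.2f\n", object@f8Value))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport | LOOCV over", length(unique(object@folds$subjectId)),
      "subjects\n")
  cat("  macro ROC AUC:", sprintf("%.3f", mean(object@aucPerClass)),
      "| subset accuracy:", sprintf("%.3f", object@subsetAccuracy), "\n")
})

setMethod("show", "SimulatedCohort", function(object) {
  m <- object@manifest
  cat(sprintf("SimulatedCohort | %d subjects, %d trials, classes: %s\n",
              length(object@profiles), nrow(m),
              paste(sort(unique(m$classLabel)), collapse = ",")))
})
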