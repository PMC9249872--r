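## Preprocessing: temporal slicing, face localization, and the two-stage
## spatial downsampling that puts every channel on the common 50 x 35 grid.

#' Slice a recording to a fixed number of frames
#'
#' Keeps only the initial \code{nFrames} frames of every channel (4 s at 30
#' fps), so all trials have identical length. A trial whose channels are too
#' short is excluded with an informative error, mirroring the exclusion of
#' recordings just under 4 s.
#'
#' @param rec a \code{\linkS4class{MultispectralRecording}}.
#' @param nFrames frames to keep.
#' @return The sliced recording.
#' @export
sliceToLength <- function(rec, nFrames = N_FRAMES) {
  short <- vapply(rec@channels, function(x) dim(x)[1] < nFrames, logical(1))
  if (any(short)) {
    stop("trial excluded: channel(s) ",
         paste(names(rec@channels)[short], collapse = ", "),
         " shorter than ", nFrames, " frames")
  }
  rec@channels <- lapply(rec@channels, function(x) {
    x[seq_len(nFrames), , , drop = FALSE]
  })
  rec
}

#' Locate the face in a reflective-channel frame stack
#'
#' When an explicit bounding box is given, the detector is bypassed and the
#' crop is returned directly (the route used for synthetic data, whose face
#' position is known). Otherwise the pluggable \code{detector} is called on
#' the first frame and must return a list of candidate boxes
#' \code{c(row0, col0, row1, col1)}; the largest is kept. The default
#' detector thresholds the first frame (Otsu) and takes the bounding box of
#' the foreground, a stand-in for a pretrained face cascade.
#'
#' @param frames \code{T x H x W} array.
#' @param bbox optional \code{c(row0, col0, row1, col1)} (inclusive).
#' @param detector function(frame) -> list of candidate boxes.
#' @return Cropped \code{T x h x w} array.
#' @export
faceRegionVis <- function(frames, bbox = NULL, detector = thresholdDetector) {
  if (is.null(bbox)) {
    cands <- detector(frames[1, , ])
    if (length(cands) == 0) {
      stop("trial excluded: no face found and no bounding box supplied")
    }
    areas <- vapply(cands, function(b) {
      (b[3] - b[1] + 1) * (b[4] - b[2] + 1)
    }, numeric(1))
    bbox <- cands[[which.max(areas)]]
  }
  frames[, bbox[1]:bbox[3], bbox[2]:bbox[4], drop = FALSE]
}

#' Threshold-based face-candidate detector
#'
#' Otsu-binarizes a frame and returns the bounding box of the foreground
#' (brighter) region, if any.
#'
#' @param frame numeric matrix.
#' @return List of candidate boxes \code{c(row0, col0, row1, col1)}.
#' @export
thresholdDetector <- function(frame) {
  thr <- tryCatch(otsuThreshold(frame), error = function(e) NULL)
  if (is.null(thr)) return(list())
  fg <- which(frame > thr, arr.ind = TRUE)
  if (nrow(fg) == 0) return(list())
  list(c(min(fg[, 1]), min(fg[, 2]), max(fg[, 1]), max(fg[, 2])))
}

#' Segment the face in the thermal channel
#'
#' Otsu-thresholds each frame of the calibrated (degrees C) thermal stack
#' and suppresses the background, then zeroes every pixel below 30 C. Fails
#' if no pixel survives.
#'
#' @param frames \code{T x H x W} array in degrees C.
#' @return Masked stack of identical shape; background pixels are 0.
#' @export
faceRegionLwir <- function(frames) {
  thr <- tryCatch(otsuThreshold(frames[1, , ]), error = function(e) Inf)
  out <- frames
  out[out < max(thr, 30)] <- 0
  if (!any(out > 0)) {
    stop("trial excluded: no thermal foreground above 30 C")
  }
  out
}

#' Two-stage spatial downsampling to the analysis grid
#'
#' Stage 1 averages non-overlapping pooling blocks (10 x 10 for R, G, B;
#' 5 x 5 for NIR and LWIR), slicing off rows/columns that do not fill a
#' block; stage 2 resizes the pooled frame to 50 x 35 by bicubic
#' interpolation. Applied frame by frame.
#'
#' @param frames \code{T x H x W} array.
#' @param poolBlock \code{c(h, w)} pooling block.
#' @return \code{T x 50 x 35} array.
#' @export
downsampleTwoStage <- function(frames, poolBlock) {
  d <- dim(frames)
  pr <- .poolMatrix(d[2], poolBlock[1])
  pc <- .poolMatrix(d[3], poolBlock[2])
  # both stages are linear, so they compose into one operator per axis
  mr <- .bicubicW(nrow(pr), GRID_ROWS) %*% pr
  mc <- .bicubicW(nrow(pc), GRID_COLS) %*% pc
  .lincombFrames(frames, mr, mc)
}

#' Preprocess a recording into a DownsampledCube
#'
#' Runs the full preprocessing chain: temporal slicing, per-channel face
#' localization (reflective channels cropped, thermal channel masked), and
#' two-stage downsampling of every channel to the common grid. Channels are
#' registered only through this shared resolution.
#'
#' @param rec a \code{\linkS4class{MultispectralRecording}}.
#' @param nFrames frames to keep.
#' @param bboxes optional named list of per-channel bounding boxes; for
#'   simulated recordings the face fills the frame and no crop is needed.
#' @param poolBlocks named list of pooling blocks per channel.
#' @param lwirMask apply the thermal 30 C background suppression.
#' @return A \code{\linkS4class{DownsampledCube}}.
#' @export
preprocessRecording <- function(rec, nFrames = N_FRAMES, bboxes = NULL,
                                poolBlocks = list(
                                  R = c(10L, 10L), G = c(10L, 10L),
                                  B = c(10L, 10L), NIR = c(5L, 5L),
                                  LWIR = c(5L, 5L)
                                ),
                                lwirMask = TRUE) {
  rec <- sliceToLength(rec, nFrames)
  data <- array(0, dim = c(5L, nFrames, GRID_ROWS, GRID_COLS))
  for (i in seq_along(CHANNELS)) {
    ch <- CHANNELS[i]
    frames <- rec@channels[[ch]]
    if (ch == "LWIR") {
      if (lwirMask) frames <- faceRegionLwir(frames)
    } else if (!is.null(bboxes) && !is.null(bboxes[[ch]])) {
      frames <- faceRegionVis(frames, bbox = bboxes[[ch]])
    }
    data[i, , , ] <- downsampleTwoStage(frames, poolBlocks[[ch]])
  }
  new("DownsampledCube", data = data, fs = rec@fs)
}
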