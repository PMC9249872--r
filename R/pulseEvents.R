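## Per-pixel pulse peaks and troughs, the aligned pulse-frame stacks they
## form, and the slow thermal track (feature F1).
##
## Detection runs on each pixel's min-max-normalized band-passed series, so
## the prominence thresholds (0.4 for G and NIR, 0.2 for R and B) act on a
## [0, 1] scale; the stored intensities come from the band-limited series
## with the pixel's temporal mean restored, so ln(Imax / Imin) is
## well-defined while amplitude information is preserved.

#' Default prominence thresholds per channel
#'
#' Reflects the differing noise characteristics of the channels: 0.4 for the
#' green and NIR channels, 0.2 for red and blue.
#'
#' @return Named numeric vector.
#' @export
defaultProminence <- function() {
  c(R = 0.2, G = 0.4, B = 0.2, NIR = 0.4)
}

#' Minimum peak separation in frames
#'
#' \code{ceiling(0.75 * fs / hr)}: three quarters of one cardiac cycle, so
#' two detections cannot fall within the same beat.
#'
#' @param fs frame rate, Hz.
#' @param hr heart rate, Hz.
#' @return Integer frame count.
#' @export
minPeakDistance <- function(fs, hr) {
  if (hr <= 0) stop("heart rate must be positive")
  as.integer(ceiling(0.75 * fs / hr))
}

#' Find pulse peaks and troughs of one temporal signal
#'
#' Peaks are local maxima of the min-max-normalized band-passed signal with
#' at least \code{minPeakDistance(fs, hr)} frames separation and the given
#' topographic prominence; troughs are peaks of the negated signal under the
#' same thresholds.
#'
#' @param x band-passed temporal series.
#' @param fs frame rate, Hz.
#' @param hr heart rate driving the separation threshold, Hz.
#' @param prominence minimal prominence on the normalized [0, 1] scale.
#' @return List with \code{peakTimes}, \code{peakValues},
#'   \code{troughTimes}, \code{troughValues} (times are 1-based frame
#'   indices; values are read from \code{x}).
#' @export
findPeaksTroughs <- function(x, fs, hr, prominence = 0.4) {
  dist <- minPeakDistance(fs, hr)
  rng <- range(x)
  if (!(rng[2] > rng[1])) {
    return(list(peakTimes = integer(0), peakValues = numeric(0),
                troughTimes = integer(0), troughValues = numeric(0)))
  }
  v <- (x - rng[1]) / (rng[2] - rng[1])
  pk <- .find_peaks_cpp(v, dist, prominence)
  tr <- .find_peaks_cpp(1 - v, dist, prominence)
  list(peakTimes = pk, peakValues = x[pk],
       troughTimes = tr, troughValues = x[tr])
}

#' Build the aligned pulse-frame stacks
#'
#' For every reflective-channel pixel, band-passes the temporal series,
#' detects peaks and troughs, pairs each peak with the nearest following
#' trough (a trailing unmatched peak is dropped), and stores the intensities
#' of the first 5 pairs at pulse indices 1..5. Pixels with fewer pairs are
#' zero-padded; pixels with more are truncated, fixing the
#' 5 x 50 x 35-per-feature dimensionality.
#'
#' @param cube a \code{\linkS4class{DownsampledCube}}.
#' @param hr estimated heart rate (F8), Hz.
#' @param prominence named per-channel prominence thresholds.
#' @param nPulseFrames pulse frames kept per pixel.
#' @param lo,hi,order band-pass parameters.
#' @return A \code{\linkS4class{PulseFrameStack}}.
#' @export
buildPulseStack <- function(cube, hr, prominence = defaultProminence(),
                            nPulseFrames = N_PULSE, lo = 0.75, hi = 4,
                            order = 6L) {
  if (hr <= 0) stop("heart rate must be positive")
  dist <- minPeakDistance(cube@fs, hr)
  T <- dim(cube@data)[2]
  imax <- list()
  imin <- list()
  npairs <- list()
  for (i in seq_along(VIS_CHANNELS)) {
    ch <- VIS_CHANNELS[i]
    x <- matrix(cube@data[i, , , ], T, GRID_ROWS * GRID_COLS)
    dc <- colMeans(x)
    bp <- bandpassFilter(x, cube@fs, lo, hi, order)
    res <- .pulse_stack_cpp(bp, dc, dist, prominence[[ch]],
                            as.integer(nPulseFrames))
    imax[[ch]] <- array(res$imax, dim = c(nPulseFrames, GRID_ROWS,
                                          GRID_COLS))
    imin[[ch]] <- array(res$imin, dim = c(nPulseFrames, GRID_ROWS,
                                          GRID_COLS))
    npairs[[ch]] <- matrix(res$npairs, GRID_ROWS, GRID_COLS)
  }
  new("PulseFrameStack", imax = imax, imin = imin, npairs = npairs)
}

#' Slow thermal track (feature F1)
#'
#' Low-passes each thermal pixel at 0.75 Hz (6th-order Butterworth, zero
#' phase) and resamples the result at 1.5 Hz -- every \code{fs / 1.5} frames
#' -- keeping slow temperature changes while suppressing sensor noise. The
#' first 5 samples form F1's pulse-frame axis.
#'
#' @param lwirCube \code{T x 50 x 35} array in degrees C.
#' @param fs frame rate, Hz.
#' @param cutoff low-pass cutoff, Hz.
#' @param sampleHz resampling rate, Hz.
#' @return \code{(5, 50, 35)} array.
#' @export
lwirTrack <- function(lwirCube, fs, cutoff = 0.75, sampleHz = 1.5) {
  T <- dim(lwirCube)[1]
  x <- matrix(lwirCube, T, GRID_ROWS * GRID_COLS)
  lp <- lowpassFilter(x, fs, cutoff)
  step <- fs / sampleHz
  idx <- round(1 + step * (seq_len(N_PULSE) - 1L))
  if (max(idx) > T) stop("stack too short for ", N_PULSE, " thermal samples")
  array(lp[idx, ], dim = c(N_PULSE, GRID_ROWS, GRID_COLS))
}
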