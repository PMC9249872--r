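## Heart-rate estimation (feature F8) from the green channel: band-pass each
## pixel's temporal signal, take the per-pixel dominant FFT frequency, clean
## the resulting 2D frequency map (blur, Otsu, morphological opening), and
## report the median of the masked non-zero frequencies.

#' Per-pixel dominant frequency map
#'
#' Band-passes each pixel's temporal series (unless already filtered), FFTs
#' it, keeps the positive frequencies only, and records the frequency of the
#' maximum magnitude. All-zero series yield frequency 0 (masked out later).
#' The frequency resolution is \code{fs / T} (0.25 Hz at 30 fps, 120
#' frames).
#'
#' @param greenCube \code{T x 50 x 35} array (green channel).
#' @param fs sampling rate, Hz.
#' @param bandpass band-pass before the FFT; set \code{FALSE} if
#'   \code{greenCube} is already filtered.
#' @param lo,hi,order band-pass parameters.
#' @return A \code{\linkS4class{FrequencyMap}} with an all-\code{FALSE} mask
#'   (see \code{\link{refineMask}}).
#' @export
dominantFrequencyMap <- function(greenCube, fs, bandpass = TRUE, lo = 0.75,
                                 hi = 4, order = 6L) {
  T <- dim(greenCube)[1]
  x <- matrix(greenCube, T, GRID_ROWS * GRID_COLS)
  if (bandpass) x <- bandpassFilter(x, fs, lo, hi, order)
  spec <- Mod(mvfft(x))
  pos <- 2:(T %/% 2 + 1) # positive frequencies, DC excluded
  freqs <- fs * (pos - 1) / T
  idx <- apply(spec[pos, , drop = FALSE], 2, which.max)
  f <- freqs[idx]
  pw <- spec[pos, , drop = FALSE][cbind(idx, seq_along(idx))]
  silent <- colSums(abs(x)) == 0 # silent pixels carry no frequency
  f[silent] <- 0
  pw[silent] <- 0
  new("FrequencyMap", freqs = matrix(f, GRID_ROWS, GRID_COLS),
      power = matrix(pw, GRID_ROWS, GRID_COLS),
      mask = matrix(FALSE, GRID_ROWS, GRID_COLS))
}

#' Refine a frequency map into a coherent-pulse mask
#'
#' Blurs the dominant-frequency map with a uniform 5 x 5 kernel (replicated
#' edges), binarizes it with Otsu adaptive thresholding, and applies a 5 x 5
#' morphological opening (erosion then dilation) to remove isolated pixels.
#' The mask multiplies the original frequency map, so masked-out pixels read
#' zero.
#'
#' When the map carries the spectral magnitude at each pixel's dominant
#' frequency (the usual case), the blurring and binarization run on that
#' magnitude: skin pixels concentrate energy at the heart rate while
#' background pixels spread theirs, so Otsu's upper class is the pulsatile
#' region for any heart rate in the band. Given a bare matrix of
#' frequencies instead, the binarization falls back to keeping the
#' \emph{coherent} class -- the side of the threshold with the smaller
#' within-class variance -- since skin pixels share one dominant frequency
#' while background argmax frequencies scatter across the band.
#'
#' @param fm a \code{\linkS4class{FrequencyMap}} (or a 50 x 35 matrix of
#'   frequencies).
#' @param lo,hi analysis band; masked-in pixels whose dominant frequency
#'   falls outside it are dropped from the mask.
#' @return The map with its mask set; frequencies outside the mask are
#'   zeroed.
#' @export
refineMask <- function(fm, lo = 0.75, hi = 4) {
  isMap <- is(fm, "FrequencyMap")
  freqs <- if (isMap) fm@freqs else fm
  power <- if (isMap && length(fm@power)) fm@power else NULL
  if (!all(is.finite(freqs))) stop("frequency map must be finite")
  basis <- if (is.null(power)) freqs else power
  blurred <- .meanFilter5(basis)
  thr <- tryCatch(otsuThreshold(blurred), error = function(e) {
    stop("no coherent pulsatile region: frequency map is uniform")
  })
  high <- blurred > thr
  if (is.null(power)) { # frequencies only: keep the coherent class
    vHigh <- stats::var(blurred[high])
    vLow <- stats::var(blurred[!high])
    if (!isTRUE(vHigh <= vLow) && any(!high)) high <- !high
  }
  mask <- .opening5(high)
  mask <- mask & freqs >= lo & freqs <= hi
  if (!any(mask)) stop("no coherent pulsatile region")
  new("FrequencyMap", freqs = freqs * mask,
      power = if (is.null(power)) matrix(0, GRID_ROWS, GRID_COLS) else
        power * mask,
      mask = mask)
}

#' Estimate the heart rate from a masked frequency map
#'
#' F8 is the median of all masked-in, non-zero dominant frequencies -- the
#' most common frequency over the coherent pulsatile region. For an even
#' count the median is the mean of the two central values.
#'
#' @param fm a \code{\linkS4class{FrequencyMap}} with a non-empty mask.
#' @return Estimated heart rate, Hz.
#' @export
estimateHr <- function(fm) {
  v <- fm@freqs[fm@mask]
  v <- v[v > 0]
  if (length(v) == 0) stop("mask holds no non-zero frequencies")
  stats::median(v)
}

#' Green-channel heart rate of a downsampled cube
#'
#' Convenience wrapper running \code{\link{dominantFrequencyMap}},
#' \code{\link{refineMask}} and \code{\link{estimateHr}} on the green
#' channel.
#'
#' @param cube a \code{\linkS4class{DownsampledCube}}.
#' @param lo,hi,order band-pass parameters.
#' @return List with \code{hr} (Hz) and the refined \code{map}.
#' @export
estimateHrCube <- function(cube, lo = 0.75, hi = 4, order = 6L) {
  fm <- dominantFrequencyMap(cube@data[2L, , , ], cube@fs, lo = lo, hi = hi,
                             order = order)
  fm <- refineMask(fm)
  list(hr = estimateHr(fm), map = fm)
}
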