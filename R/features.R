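## Assembly of the eight TSTMS features from the pulse-frame stacks, the
## thermal track and the estimated heart rate, plus the flattening to the
## 61,251-value classifier input. Every division and logarithm is
## zero-guarded: padded or degenerate entries yield 0, the unique "no
## signal" code already used by the zero padding.

#' Pulsatile amplitude I_AC
#'
#' Elementwise \code{Imax - Imin}; zero-padded entries yield 0.
#'
#' @param imax,imin aligned \code{(5, 50, 35)} stacks.
#' @return I_AC stack.
#' @export
pulsatileAmplitude <- function(imax, imin) {
  out <- imax - imin
  out[imax == 0 | imin == 0] <- 0
  out
}

#' Absorption ratio I_R
#'
#' Elementwise \code{ln(Imax / Imin)}, a Beer-Lambert absorption measure
#' that cancels the static tissue contribution; zero-padded or
#' zero-denominator entries yield 0.
#'
#' @param imax,imin aligned \code{(5, 50, 35)} stacks.
#' @return I_R stack.
#' @export
absorptionRatio <- function(imax, imin) {
  out <- imax
  out[] <- 0
  ok <- imin > 0 & imax > 0
  out[ok] <- log(imax[ok] / imin[ok])
  out
}

#' Cross-wavelength pulsatile-amplitude ratio (feature F5)
#'
#' Elementwise \code{I_AC^B / I_AC^R}; zero denominators yield 0.
#'
#' @param iacB,iacR pulsatile-amplitude stacks of the blue and red channels.
#' @return F5 stack.
#' @export
amplitudeDissimilarity <- function(iacB, iacR) {
  out <- iacB
  out[] <- 0
  ok <- iacR != 0
  out[ok] <- iacB[ok] / iacR[ok]
  out
}

#' Baseline-adjusted absorption difference (feature F6)
#'
#' Elementwise \code{|(I_R^R - I_R^B) / (Imax^R - Imax^B)|}; zero
#' denominators, or entries where either channel is padded, yield 0.
#'
#' @param irR,irB absorption-ratio stacks of red and blue.
#' @param imaxR,imaxB peak-intensity stacks of red and blue.
#' @return F6 stack (nonnegative).
#' @export
absorptionDifference <- function(irR, irB, imaxR, imaxB) {
  out <- irR
  out[] <- 0
  ok <- (imaxR != imaxB) & imaxR > 0 & imaxB > 0
  out[ok] <- abs((irR[ok] - irB[ok]) / (imaxR[ok] - imaxB[ok]))
  out
}

#' Default chin mask
#'
#' The bottom rows of the grid, where a chin head mount would sit.
#'
#' @param nRows number of bottom rows masked (default 6).
#' @return 50 x 35 logical matrix.
#' @export
defaultChinMask <- function(nRows = 6L) {
  m <- matrix(FALSE, GRID_ROWS, GRID_COLS)
  if (nRows > 0) m[(GRID_ROWS - nRows + 1L):GRID_ROWS, ] <- TRUE
  m
}

#' Zero features over the chin mask
#'
#' Zeroes F1-F7 on the masked pixels while keeping the vector length (and
#' hence the 8750-per-feature dimensionality) unchanged.
#'
#' @param features a \code{\linkS4class{TSTMSFeatures}}.
#' @param mask 50 x 35 logical matrix; masks covering more than 30 percent
#'   of the grid are rejected as suspicious.
#' @return The masked features.
#' @export
applyChinMask <- function(features, mask = defaultChinMask()) {
  if (mean(mask) > 0.3) {
    stop("chin mask covers more than 30% of the grid")
  }
  v <- features@values
  dim(v) <- c(7L * N_PULSE, GRID_ROWS * GRID_COLS)
  v[, as.vector(mask)] <- 0
  dim(v) <- c(7L, N_PULSE, GRID_ROWS, GRID_COLS)
  features@values <- v
  features@chinMask <- mask | features@chinMask
  features
}

#' Assemble the TSTMS features of one trial
#'
#' Orchestrates the full per-trial feature chain on a downsampled cube:
#' green-channel heart-rate estimation (F8), per-channel pulse-frame stacks,
#' the pulsatile amplitudes (F2 = red, F3 = green, F4 = blue, F7 = NIR), the
#' B/R amplitude ratio (F5), the baseline-adjusted R-B absorption difference
#' (F6), the slow thermal track (F1), and the chin mask.
#'
#' @param cube a \code{\linkS4class{DownsampledCube}}.
#' @param chinMask logical 50 x 35, or \code{NULL} to skip masking.
#' @param prominence named per-channel prominence thresholds.
#' @param lo,hi,order band-pass parameters.
#' @return A \code{\linkS4class{TSTMSFeatures}}.
#' @export
computeTstmsFeatures <- function(cube, chinMask = defaultChinMask(),
                                 prominence = defaultProminence(),
                                 lo = 0.75, hi = 4, order = 6L) {
  est <- estimateHrCube(cube, lo = lo, hi = hi, order = order)
  stack <- buildPulseStack(cube, est$hr, prominence = prominence, lo = lo,
                           hi = hi, order = order)
  f1 <- lwirTrack(cube@data[5L, , , ], cube@fs)
  iac <- lapply(VIS_CHANNELS, function(ch) {
    pulsatileAmplitude(stack@imax[[ch]], stack@imin[[ch]])
  })
  names(iac) <- VIS_CHANNELS
  irR <- absorptionRatio(stack@imax[["R"]], stack@imin[["R"]])
  irB <- absorptionRatio(stack@imax[["B"]], stack@imin[["B"]])
  values <- array(0, dim = c(7L, N_PULSE, GRID_ROWS, GRID_COLS))
  values[1, , , ] <- f1
  values[2, , , ] <- iac$R
  values[3, , , ] <- iac$G
  values[4, , , ] <- iac$B
  values[5, , , ] <- amplitudeDissimilarity(iac$B, iac$R)
  values[6, , , ] <- absorptionDifference(irR, irB, stack@imax[["R"]],
                                          stack@imax[["B"]])
  values[7, , , ] <- iac$NIR
  out <- new("TSTMSFeatures", values = values, f8 = est$hr,
             chinMask = matrix(FALSE, GRID_ROWS, GRID_COLS))
  if (!is.null(chinMask)) out <- applyChinMask(out, chinMask)
  out
}

#' Flatten features to the classifier input vector
#'
#' F1..F7 are laid out consecutively, each in (pulse, row, col) raster
#' order, followed by the scalar F8; total length 61,251. The mapping is
#' invertible (\code{\link{unflattenFeatures}}) and described by
#' \code{\link{featureIndexMap}}.
#'
#' @param features a \code{\linkS4class{TSTMSFeatures}}.
#' @return Numeric vector of length 61,251.
#' @export
flattenFeatures <- function(features) {
  c(aperm(features@values, c(2, 3, 4, 1)), features@f8)
}

#' Invert \code{\link{flattenFeatures}}
#'
#' @param v numeric vector of length 61,251.
#' @param chinMask optional chin mask to record on the result.
#' @return A \code{\linkS4class{TSTMSFeatures}}.
#' @export
unflattenFeatures <- function(v, chinMask = matrix(FALSE, GRID_ROWS,
                                                   GRID_COLS)) {
  if (length(v) != N_FLAT) stop("expected a length-", N_FLAT, " vector")
  a <- array(v[seq_len(N_FLAT - 1L)],
             dim = c(N_PULSE, GRID_ROWS, GRID_COLS, 7L))
  new("TSTMSFeatures", values = aperm(a, c(4, 1, 2, 3)), f8 = v[N_FLAT],
      chinMask = chinMask)
}

#' Index map of the flattened feature vector
#'
#' @return data.frame with columns \code{index} (1-based), \code{feature},
#'   \code{pulse}, \code{row}, \code{col}; the last row is F8.
#' @export
featureIndexMap <- function() {
  grid <- expand.grid(pulse = seq_len(N_PULSE), row = seq_len(GRID_ROWS),
                      col = seq_len(GRID_COLS))
  per <- do.call(rbind, lapply(1:7, function(f) {
    data.frame(feature = paste0("F", f), grid)
  }))
  out <- rbind(per, data.frame(feature = "F8", pulse = NA_integer_,
                               row = NA_integer_, col = NA_integer_))
  out$index <- seq_len(nrow(out))
  out[, c("index", "feature", "pulse", "row", "col")]
}

#' Feature matrix of a simulated cohort
#'
#' Streams through the cohort trial by trial: render, preprocess, extract,
#' flatten. Frames are discarded after each trial, so memory stays bounded.
#'
#' @param cohort a \code{\linkS4class{SimulatedCohort}}.
#' @param verbose print progress every 25 trials.
#' @param ... passed to \code{\link{computeTstmsFeatures}}.
#' @return List with \code{x} (trials x 61,251 matrix) and \code{meta}
#'   (manifest data.frame).
#' @export
cohortFeatureMatrix <- function(cohort, verbose = FALSE, ...) {
  n <- nTrials(cohort)
  x <- matrix(0, n, N_FLAT)
  for (i in seq_len(n)) {
    rec <- renderTrial(cohort, i)
    cube <- preprocessRecording(rec)
    x[i, ] <- flattenFeatures(computeTstmsFeatures(cube, ...))
    if (i %% 10L == 0L) {
      rm(rec, cube)
      gc(FALSE) # rendering churns ~300 MB per trial; keep the heap low
    }
    if (verbose && i %% 25L == 0L) {
      message("  trial ", i, " / ", n)
    }
  }
  list(x = x, meta = cohort@manifest)
}
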