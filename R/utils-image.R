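## Spatial resampling primitives shared by the simulator and preprocessing.

# Keys cubic-convolution kernel (a = -0.5, Catmull-Rom): interpolates, sums
# to one for any sampling phase, and reproduces linear ramps exactly.
.cubicKernel <- function(s) {
  s <- abs(s)
  ifelse(s <= 1, 1.5 * s^3 - 2.5 * s^2 + 1,
    ifelse(s < 2, -0.5 * s^3 + 2.5 * s^2 - 4 * s + 2, 0)
  )
}

#' Bicubic resampling weight matrix
#'
#' One-dimensional cubic-convolution weights mapping \code{nIn} samples to
#' \code{nOut} samples under pixel-center alignment, with edge clamping.
#' Applying the row and column matrices on either side of an image performs
#' separable bicubic interpolation.
#'
#' @param nIn,nOut input and output lengths.
#' @return \code{nOut x nIn} weight matrix whose rows sum to 1.
#' @keywords internal
bicubicWeights <- function(nIn, nOut) {
  w <- matrix(0, nOut, nIn)
  scale <- nIn / nOut
  for (i in seq_len(nOut)) {
    src <- (i - 0.5) * scale + 0.5 # 1-based source coordinate
    base <- floor(src)
    for (k in -1:2) {
      j <- base + k
      wt <- .cubicKernel(src - j)
      jc <- min(max(j, 1L), nIn) # clamp: edge samples absorb outside taps
      w[i, jc] <- w[i, jc] + wt
    }
  }
  w
}

.bicubic_cache <- new.env(parent = emptyenv())

.bicubicW <- function(nIn, nOut) {
  key <- paste(nIn, nOut)
  hit <- .bicubic_cache[[key]]
  if (is.null(hit)) {
    hit <- .bicubic_cache[[key]] <- bicubicWeights(nIn, nOut)
  }
  hit
}

#' Bicubic image resize
#'
#' @param img numeric matrix.
#' @param outDim target \code{c(rows, cols)}.
#' @return Resized matrix.
#' @export
resizeBicubic <- function(img, outDim) {
  wr <- .bicubicW(nrow(img), outDim[1])
  wc <- .bicubicW(ncol(img), outDim[2])
  wr %*% img %*% t(wc)
}

# Apply per-frame separable linear operators over a (T, H, W) stack in one
# batch: out[t, , ] = mr %*% x[t, , ] %*% t(mc). The frame loop is replaced
# by two large matrix products.
.lincombFrames <- function(x, mr, mc) {
  d <- dim(x)
  T <- d[1]
  # rows: (H, T*W) -> (h, T*W)
  y <- mr %*% matrix(aperm(x, c(2, 1, 3)), d[2], T * d[3])
  h <- nrow(mr)
  dim(y) <- c(h * T, d[3]) # W is the trailing dim: reshape, no copy needed
  z <- y %*% t(mc)
  dim(z) <- c(h, T, nrow(mc))
  aperm(z, c(2, 1, 3))
}

# pooling matrix: block mean over non-overlapping blocks, slicing to fit
.poolMatrix <- function(n, block) {
  nOut <- n %/% block
  if (nOut < 1) stop("image smaller than one pooling block")
  p <- matrix(0, nOut, n)
  p[cbind(rep(seq_len(nOut), each = block), seq_len(nOut * block))] <-
    1 / block
  p
}

#' Non-overlapping block-mean pooling
#'
#' Averages non-overlapping \code{block[1] x block[2]} pixel blocks. Rows and
#' columns that do not fill a complete block are sliced off first.
#'
#' @param img numeric matrix.
#' @param block \code{c(height, width)} of the pooling block.
#' @return Pooled matrix of dimension \code{floor(dim(img) / block)}.
#' @export
blockMean <- function(img, block) {
  pr <- .poolMatrix(nrow(img), block[1])
  pc <- .poolMatrix(ncol(img), block[2])
  pr %*% img[seq_len(ncol(pr)), seq_len(ncol(pc)), drop = FALSE] %*% t(pc)
}

# Uniform 5x5 mean filter with replicated edges.
.meanFilter5 <- function(img) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (dr in -2:2) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    for (dc in -2:2) {
      ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      out <- out + img[ri, ci]
    }
  }
  out / 25
}

#' Otsu threshold of a numeric matrix
#'
#' Rescales the values to \code{[0, 1]}, applies \code{\link[EBImage]{otsu}},
#' and maps the threshold back to the original scale.
#'
#' @param x numeric matrix.
#' @return Threshold on the scale of \code{x}; values strictly above it form
#'   the foreground.
#' @export
otsuThreshold <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!(rng[2] > rng[1])) {
    stop("degenerate input: all values identical, no threshold exists")
  }
  norm <- (x - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  rng[1] + thr * (rng[2] - rng[1])
}

# 5x5 box morphological opening (erosion then dilation) of a logical matrix
.opening5 <- function(mask) {
  img <- EBImage::Image(mask * 1)
  kern <- EBImage::makeBrush(5L, shape = "box")
  EBImage::imageData(EBImage::opening(img, kern)) > 0.5
}
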