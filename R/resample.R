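# Separable bicubic resampling built from explicit 1-d weight matrices.
# out = W_rows %*% img %*% t(W_cols); weights use the Keys cubic kernel
# (a = -0.5) with the kernel stretched by the inverse scale when shrinking
# (antialiasing), the convention of MATLAB's imresize and of the SRCNN
# lineage of super-resolution work. Boundaries are handled by clamping
# source indices (replicate padding), so each row of weights sums to 1 and
# constant images are reproduced exactly.

#' Keys cubic interpolation kernel
#'
#' @param x distances in source pixels
#' @param a kernel parameter; -0.5 is the standard bicubic choice
#' @return kernel values
#' @keywords internal
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  k <- numeric(length(x))
  i1 <- x <= 1
  i2 <- x > 1 & x < 2
  k[i1] <- (a + 2) * x[i1]^3 - (a + 3) * x[i1]^2 + 1
  k[i2] <- a * x[i2]^3 - 5 * a * x[i2]^2 + 8 * a * x[i2] - 4 * a
  k
}

#' 1-d resampling weight matrix
#'
#' Dense `out_len x in_len` matrix mapping a length-`in_len` signal to
#' `out_len` samples under pixel-center alignment. When `out_len < in_len`
#' and `antialias` is `TRUE` the kernel support is widened by the inverse
#' scale so downsampling low-passes the signal.
#'
#' @param in_len,out_len source and target lengths
#' @param antialias widen the kernel when shrinking
#' @return numeric matrix with unit row sums
#' @keywords internal
resample_weights <- function(in_len, out_len, antialias = TRUE) {
  scale <- out_len / in_len
  kscale <- if (antialias && scale < 1) scale else 1
  support <- 2 / kscale
  W <- matrix(0, out_len, in_len)
  for (i in seq_len(out_len)) {
    # center of output pixel i (1-based) in source coordinates
    u <- (i - 0.5) / scale + 0.5
    lo <- floor(u - support)
    hi <- ceiling(u + support)
    idx <- lo:hi
    w <- cubic_kernel((u - idx) * kscale) * kscale
    keep <- w != 0
    idx <- pmin(pmax(idx[keep], 1L), in_len)  # replicate boundary
    w <- w[keep]
    for (j in seq_along(idx)) W[i, idx[j]] <- W[i, idx[j]] + w[j]
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

#' Bicubic image resize
#'
#' @param img numeric matrix
#' @param out_dim integer vector `c(rows, cols)` of the target grid
#' @param antialias low-pass when shrinking (ignored when enlarging)
#' @return resized matrix
#' @export
#' @examples
#' x <- matrix(runif(64), 8, 8)
#' y <- resize_bicubic(x, c(16, 16))
resize_bicubic <- function(img, out_dim, antialias = TRUE) {
  stopifnot(is.matrix(img), length(out_dim) == 2)
  Wr <- resample_weights(nrow(img), out_dim[1], antialias)
  Wc <- resample_weights(ncol(img), out_dim[2], antialias)
  Wr %*% img %*% t(Wc)
}

#' Gaussian blur with replicate boundary handling
#'
#' Separable discrete gaussian, truncated at `ceiling(3.5 * sigma)` taps per
#' side and renormalized, so constant images are preserved exactly.
#'
#' @param img numeric matrix
#' @param sigma standard deviation in pixels (> 0)
#' @return blurred matrix, same size
#' @export
blur_gaussian <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  Br <- gaussian_weights(nrow(img), sigma)
  Bc <- gaussian_weights(ncol(img), sigma)
  Br %*% img %*% t(Bc)
}

gaussian_weights <- function(len, sigma) {
  r <- ceiling(3.5 * sigma)
  taps <- (-r):r
  k <- exp(-taps^2 / (2 * sigma^2))
  k <- k / sum(k)
  W <- matrix(0, len, len)
  for (i in seq_len(len)) {
    idx <- pmin(pmax(i + taps, 1L), len)
    for (j in seq_along(idx)) W[i, idx[j]] <- W[i, idx[j]] + k[j]
  }
  W
}

#' Sampled, normalized 2-d gaussian kernel
#'
#' @param sigma standard deviation in pixels
#' @param radius taps per side; default `ceiling(3.5 * sigma)`
#' @return `(2*radius+1)` square matrix summing to 1
#' @export
gaussian_kernel2d <- function(sigma, radius = ceiling(3.5 * sigma)) {
  taps <- (-radius):radius
  k1 <- exp(-taps^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

# Resize a 3-d array along each axis in turn (used for the phantom bias
# field). Antialiasing is irrelevant here: always enlarging.
resize3d <- function(arr, out_dim) {
  d <- dim(arr)
  W1 <- resample_weights(d[1], out_dim[1], antialias = FALSE)
  W2 <- resample_weights(d[2], out_dim[2], antialias = FALSE)
  W3 <- resample_weights(d[3], out_dim[3], antialias = FALSE)
  # axis 1
  m <- W1 %*% matrix(arr, d[1], d[2] * d[3])
  arr <- array(m, c(out_dim[1], d[2], d[3]))
  # axis 2
  arr <- aperm(arr, c(2, 1, 3))
  m <- W2 %*% matrix(arr, d[2], out_dim[1] * d[3])
  arr <- aperm(array(m, c(out_dim[2], out_dim[1], d[3])), c(2, 1, 3))
  # axis 3
  arr <- aperm(arr, c(3, 1, 2))
  m <- W3 %*% matrix(arr, d[3], out_dim[1] * out_dim[2])
  aperm(array(m, c(out_dim[3], out_dim[1], out_dim[2])), c(2, 3, 1))
}
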