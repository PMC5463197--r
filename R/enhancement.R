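#' Read a grayscale image
#'
#' Reads an 8-bit PNG or TIFF into a numeric matrix with intensities in
#' \[0, 1\] (multi-channel files are averaged to one channel).
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix in \[0, 1\].
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  clip01(img)
}

#' Write a grayscale image
#'
#' Quantizes intensities to 8 bits (round(255 v)) and writes PNG or TIFF.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param path output path ending in .png, .tif or .tiff.
#' @export
writeGrayImage <- function(img, path) {
  assertGrayImage(img)
  q <- round(img * 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(q, path),
    tif = ,
    tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Estimate the mass radius of an ROI
#'
#' Thresholds the crop at the level maximizing between-class variance, takes
#' the largest connected bright component of pixel area A, and returns
#' r = sqrt(A / pi), clipped to \[2, side/2 - 1\].
#'
#' @param roi an [ROIPatch-class] or a square image matrix.
#' @return radius in pixels.
#' @export
estimateRadius <- function(roi) {
  img <- if (is(roi, "ROIPatch")) roi@pixels else roi
  assertGrayImage(img)
  if (max(img) - min(img) < 1e-12)
    stop("no mass candidate: constant image")
  thr <- otsuThreshold(img)
  comp <- largestComponent(img > thr)
  if (is.null(comp) || !any(comp))
    stop("no mass candidate: empty foreground")
  r <- sqrt(sum(comp) / pi)
  side <- min(dim(img))
  min(max(r, 2), side / 2 - 1)
}

#' Suppress tissue neighbouring the ROI
#'
#' Multiplies the crop by a radial amplitude that is 1 inside the estimated
#' mass radius and decays as exp((r^2 - d^2) / (2 sigma^2)) outside it, where
#' d is the pixel's distance to the ROI centre. By default sigma is the
#' difference between the crop side length and the radius, the setting that
#' gives the cleanest downstream segmentation.
#'
#' @param roi an [ROIPatch-class].
#' @param sigma suppression width in pixels; default `side - radiusR`.
#' @return image matrix in \[0, 1\].
#' @export
suppressNeighborTissue <- function(roi, sigma = NULL) {
  stopifnot(is(roi, "ROIPatch"))
  if (is.null(sigma)) sigma <- roi@side - roi@radiusR
  if (sigma <= 0) stop("sigma must be positive")
  amp <- suppressionAmplitude(roi@side, roi@radiusR, sigma)
  clip01(amp * roi@pixels)
}

# Radial amplitude field of the neighbour-tissue suppression for a square
# crop: 1 on the closed disk of radius r, Gaussian-tapered beyond it.
suppressionAmplitude <- function(side, r, sigma) {
  ctr <- floor(side / 2) + 1
  off <- seq_len(side) - ctr
  d2 <- outer(off^2, off^2, "+")
  amp <- matrix(1, side, side)
  out <- d2 > r^2
  amp[out] <- exp((r^2 - d2[out]) / (2 * sigma^2))
  amp
}

#' Flatten an uneven ROI background
#'
#' Fits a plane a + b x + c y to the intensities by ordinary least squares,
#' subtracts it, and linearly rescales the residual to span the original
#' \[min, max\] intensity range. Removes slow background trends (chest wall,
#' skin line, dense gland) while keeping the high-frequency mass structure.
#'
#' @param roi an [ROIPatch-class] or an image matrix.
#' @return image matrix in \[0, 1\].
#' @export
correctBackground <- function(roi) {
  img <- if (is(roi, "ROIPatch")) roi@pixels else roi
  assertGrayImage(img)
  h <- nrow(img); w <- ncol(img)
  x <- rep(seq_len(h), times = w)
  y <- rep(seq_len(w), each = h)
  X <- cbind(1, x, y)
  coef <- qr.coef(qr(X), as.vector(img))
  resid <- as.vector(img) - X %*% coef
  lo <- min(img); hi <- max(img)
  rng <- max(resid) - min(resid)
  if (rng < 1e-12) {
    out <- matrix((lo + hi) / 2, h, w)
  } else {
    out <- matrix(lo + (resid - min(resid)) / rng * (hi - lo), h, w)
  }
  clip01(out)
}

#' Gamma (power-law) intensity transform
#'
#' Pointwise G = c X^r. Exponents above 1 spread the high-gray range where
#' both the suspected mass and adhering background tissue live, separating
#' their distributions before segmentation.
#'
#' @param img image matrix in \[0, 1\].
#' @param c gain, > 0.
#' @param r_exp exponent, > 0; default 1.5.
#' @return image matrix in \[0, 1\].
#' @export
gammaTransform <- function(img, c = 1, r_exp = 1.5) {
  assertGrayImage(img)
  if (c <= 0 || r_exp <= 0) stop("gamma parameters c and r must be positive")
  clip01(c * img^r_exp)
}

#' Isotropic Gaussian kernel
#'
#' 2-D kernel exp(-(x^2 + y^2) / (2 sigma^2)), truncated at +-ceil(3 sigma)
#' and renormalized to sum exactly 1.
#'
#' @param sigma standard deviation in pixels, > 0.
#' @return square numeric matrix summing to 1.
#' @export
gaussianKernel <- function(sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  h <- ceiling(3 * sigma)
  off <- -h:h
  k1 <- exp(-off^2 / (2 * sigma^2))
  k2 <- outer(k1, k1)
  k2 / sum(k2)
}

#' Gaussian smoothing
#'
#' Convolves with the truncated, renormalized isotropic Gaussian kernel using
#' symmetric (reflect) boundary handling; computed separably.
#'
#' @param img image matrix in \[0, 1\].
#' @param sigma kernel standard deviation in pixels.
#' @return image matrix in \[0, 1\].
#' @export
gaussianSmooth <- function(img, sigma) {
  assertGrayImage(img)
  if (sigma <= 0) stop("sigma must be positive")
  h <- ceiling(3 * sigma)
  k1 <- exp(-(-h:h)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  out <- convolveReflect(img, k1, h, margin = 1)
  out <- convolveReflect(out, k1, h, margin = 2)
  clip01(out)
}

# 1-D convolution along rows (margin 1) or columns (margin 2) with
# symmetric-reflect padding.
convolveReflect <- function(img, k1, h, margin) {
  n <- dim(img)[margin]
  idx <- c(rev(seq_len(min(h, n))), seq_len(n),
           rev(seq_len(n))[seq_len(min(h, n))])
  if (h > n) stop("kernel larger than image; reduce sigma")
  pad <- if (margin == 1) img[idx, , drop = FALSE] else img[, idx, drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (o in seq_along(k1)) {
    sl <- (o - 1) + seq_len(n)
    out <- out + k1[o] *
      (if (margin == 1) pad[sl, , drop = FALSE] else pad[, sl, drop = FALSE])
  }
  out
}

#' Segment the mass in an enhanced ROI
#'
#' Global threshold maximizing between-class variance, keep the largest
#' connected bright component, fill interior holes. Stands in for a full
#' mass segmentation; the result has exactly one foreground component.
#'
#' @param img enhanced image matrix in \[0, 1\].
#' @return logical mask matrix.
#' @export
segmentROI <- function(img) {
  assertGrayImage(img)
  if (max(img) - min(img) < 1e-12) stop("no mass: constant image")
  thr <- otsuThreshold(img)
  comp <- largestComponent(img > thr)
  if (is.null(comp)) stop("no mass: empty foreground")
  fillHoles(comp)
}

#' Full ROI enhancement chain
#'
#' Neighbour-tissue suppression, background correction, gamma transform and
#' Gaussian smoothing, in that order.
#'
#' @param roi an [ROIPatch-class].
#' @param suppressSigma suppression width; default `side - radiusR`.
#' @param gammaC,gammaR gamma-transform gain and exponent.
#' @param smoothSigma Gaussian smoothing width in pixels.
#' @return enhanced image matrix in \[0, 1\].
#' @export
enhanceROI <- function(roi, suppressSigma = NULL, gammaC = 1,
                       gammaR = 1.5, smoothSigma = 1) {
  out <- suppressNeighborTissue(roi, suppressSigma)
  out <- correctBackground(out)
  out <- gammaTransform(out, gammaC, gammaR)
  gaussianSmooth(out, smoothSigma)
}
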