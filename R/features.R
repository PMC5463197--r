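#' Resize so the longest side does not exceed a maximum
#'
#' Bilinear resize preserving aspect ratio when max(h, w) exceeds
#' `maxSide`; smaller images pass through unchanged.
#'
#' @param img image matrix in \[0, 1\].
#' @param maxSide maximum allowed side length in pixels; default 1000.
#' @return image matrix in \[0, 1\].
#' @export
resizeMaxSide <- function(img, maxSide = 1000) {
  assertGrayImage(img)
  if (maxSide < 8) stop("maxSide must be at least 8")
  h <- nrow(img); w <- ncol(img)
  m <- max(h, w)
  if (m <= maxSide) return(img)
  scale <- maxSide / m
  bilinearResize(img, round(h * scale), round(w * scale))
}

# Bilinear interpolation onto a newH x newW grid (pixel-centre mapping).
bilinearResize <- function(img, newH, newW) {
  h <- nrow(img); w <- ncol(img)
  rs <- (seq_len(newH) - 0.5) * h / newH + 0.5
  cs <- (seq_len(newW) - 0.5) * w / newW + 0.5
  r0 <- pmin(pmax(floor(rs), 1), h); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(pmax(floor(cs), 1), w); c1 <- pmin(c0 + 1, w)
  fr <- pmin(pmax(rs - r0, 0), 1); fc <- pmin(pmax(cs - c0, 0), 1)
  a <- img[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
       img[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
       img[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
       img[r1, c1, drop = FALSE] * outer(fr, fc)
  clip01(a)
}

#' Dense gradient-orientation descriptors
#'
#' Samples a regular grid and describes each point by a 4 x 4-cell,
#' 8-orientation gradient-magnitude histogram (128 dimensions, the SIFT
#' layout), L2-normalized; all-zero windows stay zero vectors. Deterministic
#' for a fixed input.
#'
#' @param img image matrix in \[0, 1\].
#' @param gridStep grid spacing in pixels; default 8, minimum 4.
#' @return list with `positions` (n x 2 matrix of row/col) and `vectors`
#'   (n x 128 matrix); n = 0 when the image is smaller than one 16 x 16
#'   descriptor window.
#' @export
extractDescriptors <- function(img, gridStep = 8) {
  assertGrayImage(img)
  if (gridStep < 4) stop("gridStep must be at least 4")
  h <- nrow(img); w <- ncol(img)
  win <- 16L
  if (h < win || w < win)
    return(list(positions = matrix(0, 0, 2), vectors = matrix(0, 0, 128)))

  gridAxis <- function(n) {
    m <- floor((n - win) / gridStep) + 1L
    span <- (m - 1L) * gridStep
    start <- floor((n - win - span) / 2) + 1L  # top-left row of first window
    start + (0:(m - 1L)) * gridStep
  }
  tlr <- gridAxis(h); tlc <- gridAxis(w)

  # gradients by central differences, edges replicated
  gx <- img[, c(2:w, w), drop = FALSE] - img[, c(1, 1:(w - 1)), drop = FALSE]
  gy <- img[c(2:h, h), , drop = FALSE] - img[c(1, 1:(h - 1)), , drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  bin <- pmin(floor(ang / (pi / 4)), 7) + 1L

  # per-orientation summed-area tables for O(1) cell sums
  sat <- lapply(1:8, function(b) {
    m <- mag * (bin == b)
    apply(apply(m, 2, cumsum), 1, cumsum)  # transposed SAT: sat[c, r]
  })
  cellSum <- function(b, r0, r1, c0, c1) {
    S <- sat[[b]]  # indexed [col, row]
    s <- S[cbind(c1, r1)]
    if (any(r0 > 1)) s <- s - ifelse(r0 > 1, S[cbind(c1, pmax(r0 - 1, 1))], 0)
    if (any(c0 > 1)) s <- s - ifelse(c0 > 1, S[cbind(pmax(c0 - 1, 1), r1)], 0)
    s + ifelse(r0 > 1 & c0 > 1,
               S[cbind(pmax(c0 - 1, 1), pmax(r0 - 1, 1))], 0)
  }

  grid <- expand.grid(r = tlr, c = tlc)
  n <- nrow(grid)
  vec <- matrix(0, n, 128)
  col <- 0L
  for (cr in 0:3) for (cc in 0:3) {
    r0 <- grid$r + cr * 4L; r1 <- r0 + 3L
    c0 <- grid$c + cc * 4L; c1 <- c0 + 3L
    for (b in 1:8) {
      col <- col + 1L
      vec[, col] <- cellSum(b, r0, r1, c0, c1)
    }
  }
  nrm <- sqrt(rowSums(vec^2))
  nz <- nrm > 0
  vec[nz, ] <- vec[nz, , drop = FALSE] / nrm[nz]
  list(positions = cbind(row = grid$r + win / 2 - 1L,
                         col = grid$c + win / 2 - 1L),
       vectors = vec)
}

#' Build a visual-word codebook by k-means
#'
#' k-means++ initialisation followed by Lloyd iterations, both driven by the
#' given seed, so the codebook is fully deterministic. Assignment ties go to
#' the lowest word index.
#'
#' @param descriptors matrix with one descriptor per row (or the list
#'   returned by [extractDescriptors()]).
#' @param M vocabulary size; default 200.
#' @param seed RNG seed.
#' @param maxIter Lloyd iteration cap.
#' @return A [Codebook-class].
#' @export
buildCodebook <- function(descriptors, M = 200, seed = 1L, maxIter = 50L) {
  X <- if (is.list(descriptors) && !is.data.frame(descriptors))
    descriptors$vectors else descriptors
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  if (n < M) stop("need at least M = ", M, " descriptors, got ", n)
  centers <- withSeed(seed, kmeansppInit(X, M))
  fit <- lloydKmeans(X, centers, maxIter)
  new("Codebook", words = fit$centers)
}

# k-means++ seeding; when all remaining distances are zero (duplicated
# points) the next centre is the first not-yet-chosen distinct row.
kmeansppInit <- function(X, M) {
  n <- nrow(X)
  idx <- integer(M)
  idx[1] <- sample.int(n, 1)
  d2 <- colSums((t(X) - X[idx[1], ])^2)
  for (j in 2:M) {
    tot <- sum(d2)
    if (tot <= 0) stop("fewer than M distinct descriptors")
    idx[j] <- sample.int(n, 1, prob = d2 / tot)
    d2 <- pmin(d2, colSums((t(X) - X[idx[j], ])^2))
  }
  X[idx, , drop = FALSE]
}

# Lloyd iterations with lowest-index tie-breaking; empty clusters are
# re-seeded with the point farthest from its centre.
lloydKmeans <- function(X, centers, maxIter) {
  n <- nrow(X); M <- nrow(centers)
  xs <- rowSums(X^2)
  for (it in seq_len(maxIter)) {
    d2 <- outer(xs, rowSums(centers^2), "+") - 2 * X %*% t(centers)
    assign <- max.col(-d2, ties.method = "first")
    newC <- centers
    for (j in seq_len(M)) {
      members <- assign == j
      if (any(members)) {
        newC[j, ] <- colMeans(X[members, , drop = FALSE])
      } else {
        worst <- which.max(d2[cbind(seq_len(n), assign)])
        newC[j, ] <- X[worst, ]
        assign[worst] <- j
      }
    }
    if (max(abs(newC - centers)) < 1e-10) { centers <- newC; break }
    centers <- newC
  }
  d2 <- outer(xs, rowSums(centers^2), "+") - 2 * X %*% t(centers)
  assign <- max.col(-d2, ties.method = "first")
  list(centers = centers, cluster = assign,
       withinss = sum(pmax(d2[cbind(seq_len(n), assign)], 0)))
}

#' Concentric-circle zoning of an image
#'
#' Divides half the image diagonal into `nLayers` equal portions; zone 1 is
#' the closed central disk of the first radius and zone k the annulus between
#' consecutive radii, so the zones partition all pixels.
#'
#' @param shape integer vector (height, width).
#' @param nLayers number of zones, >= 1.
#' @return A [ConcentricPartition-class].
#' @export
assignZones <- function(shape, nLayers) {
  nLayers <- as.integer(nLayers)
  if (nLayers < 1L) stop("nLayers must be >= 1")
  h <- shape[1]; w <- shape[2]
  half <- sqrt(h^2 + w^2) / 2
  new("ConcentricPartition", nLayers = nLayers,
      radii = (1:nLayers) * half / nLayers,
      center = c((h + 1) / 2, (w + 1) / 2), dim = as.integer(c(h, w)))
}

#' Zone membership of pixel positions
#'
#' @param part a [ConcentricPartition-class].
#' @param positions n x 2 matrix of (row, col) coordinates.
#' @return integer vector of zone indices in 1..nLayers.
#' @export
zoneOf <- function(part, positions) {
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 2)
  d <- sqrt((positions[, 1] - part@center[1])^2 +
            (positions[, 2] - part@center[2])^2)
  z <- findInterval(d, part@radii, left.open = TRUE) + 1L
  pmin(z, part@nLayers)  # corner rounding: clamp to outermost annulus
}

#' Zoned bag-of-words histograms
#'
#' Assigns every descriptor to its nearest visual word (ties to the lowest
#' index) and counts it once in the whole-image histogram and once in the
#' histogram of the concentric zone containing its position.
#'
#' @param desc descriptor list from [extractDescriptors()].
#' @param cb a [Codebook-class].
#' @param part a [ConcentricPartition-class].
#' @param weights per-block weights (whole image first); default all 1.
#' @return A [ZonedBoW-class].
#' @export
zonedBoW <- function(desc, cb, part, weights = NULL) {
  M <- nrow(cb@words)
  N <- part@nLayers
  if (is.null(weights)) weights <- rep(1, N + 1)
  if (nrow(desc$vectors) == 0) {
    return(new("ZonedBoW", histWhole = numeric(M),
               histZones = matrix(0, N, M), weights = weights))
  }
  if (ncol(desc$vectors) != ncol(cb@words))
    stop("descriptor dimension does not match codebook")
  X <- desc$vectors
  d2 <- outer(rowSums(X^2), rowSums(cb@words^2), "+") - 2 * X %*% t(cb@words)
  word <- max.col(-d2, ties.method = "first")
  zone <- zoneOf(part, desc$positions)
  hw <- tabulate(word, nbins = M)
  hz <- matrix(0, N, M)
  for (z in seq_len(N)) {
    sel <- zone == z
    if (any(sel)) hz[z, ] <- tabulate(word[sel], nbins = M)
  }
  new("ZonedBoW", histWhole = as.numeric(hw), histZones = hz,
      weights = weights)
}

#' Combine zoned histograms into one feature vector
#'
#' Weighted concatenation of the whole-image histogram and the per-zone
#' histograms, giving a vector of length M (N + 1): with a 200-word
#' vocabulary and 4 concentric layers, 1000 dimensions.
#'
#' @param z a [ZonedBoW-class].
#' @return numeric vector of length M * (nLayers + 1).
#' @export
combineFeatures <- function(z) {
  blocks <- rbind(z@histWhole, z@histZones)
  as.numeric(t(blocks * z@weights))
}
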