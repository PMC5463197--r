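test_that("radius estimation inverts the disk area formula and clips", {
  img <- diskImage(64, r = 20)
  r <- estimateRadius(img)
  expect_gte(r, 19)
  expect_lte(r, 21)

  expect_error(estimateRadius(matrix(0.5, 32, 32)), "no mass")

  # nearly full-bright: foreground covers almost everything -> clipped
  bright <- matrix(1, 32, 32)
  bright[1, 1:4] <- 0
  expect_equal(estimateRadius(bright), 32 / 2 - 1)
})

test_that("neighbour suppression is exact inside the radius and Gaussian outside", {
  side <- 64
  img <- matrix(0.8, side, side)
  roi <- ROIPatch(img, radiusR = 10)
  ctr <- floor(side / 2) + 1

  out <- suppressNeighborTissue(roi, sigma = 20)
  # centre pixel and a pixel at exact distance r (offsets 6, 8) unchanged
  expect_equal(out[ctr, ctr], 0.8)
  expect_equal(out[ctr + 6, ctr + 8], 0.8)
  # offset (12, 16): d^2 = 400 -> amplitude exp((100 - 400) / 800)
  expect_equal(out[ctr + 12, ctr + 16], 0.8 * exp(-0.375), tolerance = 1e-12)

  # amplitude field via an all-ones image: R in (0, 1], 1 iff d <= r,
  # non-increasing in distance
  ones <- ROIPatch(matrix(1, side, side), radiusR = 10)
  amp <- suppressNeighborTissue(ones, sigma = 20)
  off <- seq_len(side) - ctr
  d2 <- outer(off^2, off^2, "+")
  expect_true(all(amp > 0 & amp <= 1))
  expect_true(all(amp[d2 <= 100] == 1))
  ord <- order(d2)
  expect_true(all(diff(amp[ord]) <= 1e-12))

  # default sigma is side - r
  expect_equal(suppressNeighborTissue(roi),
               suppressNeighborTissue(roi, sigma = side - 10))
  expect_error(suppressNeighborTissue(roi, sigma = 0), "positive")
})

test_that("background correction removes planes and keeps bump locations", {
  h <- 32; w <- 32
  x <- matrix(seq_len(h), h, w)
  y <- matrix(seq_len(w), h, w, byrow = TRUE)
  plane <- 0.2 + 0.001 * x + 0.002 * y
  out <- correctBackground(plane)
  expect_lt(diff(range(out)), 1e-9)

  # plane + centred bump: argmax location survives the correction
  ctr <- (h + 1) / 2
  bump <- 0.3 * exp(-((x - ctr)^2 + (y - ctr)^2) / 50)
  out2 <- correctBackground(pmin(pmax(plane + bump, 0), 1))
  expect_equal(arrayInd(which.max(out2), c(h, w)),
               arrayInd(which.max(bump), c(h, w)))

  cst <- matrix(0.4, h, w)
  expect_equal(correctBackground(cst), cst)
})

test_that("gamma transform is a monotone power law", {
  img <- matrix(runif(64 * 64), 64)
  expect_equal(gammaTransform(img, 1, 1), img)
  expect_equal(gammaTransform(matrix(0.5, 8, 8), 1, 2)[1, 1], 0.25)
  # r > 1 compresses low grays pointwise
  expect_true(all(gammaTransform(img, 1, 2) <= img + 1e-15))
  # order preservation
  v <- sort(runif(100))
  g <- as.numeric(gammaTransform(matrix(v, 10, 10), 1, 1.5))
  expect_true(all(diff(g[order(v)]) >= -1e-15))
  expect_error(gammaTransform(img, 0, 1.5), "positive")
  expect_error(gammaTransform(img, 1, -1), "positive")
})

test_that("Gaussian smoothing preserves constants, mass and never raises variance", {
  k <- gaussianKernel(2.5)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(dim(k), c(2 * ceiling(7.5) + 1, 2 * ceiling(7.5) + 1))

  cst <- matrix(0.5, 32, 32)
  expect_equal(gaussianSmooth(cst, 2), cst, tolerance = 1e-12)

  # impulse response equals the kernel
  side <- 41
  imp <- matrix(0, side, side)
  imp[21, 21] <- 1
  sm <- gaussianSmooth(imp, 1.5)
  h <- ceiling(4.5)
  expect_equal(sm[21 + (-h:h), 21 + (-h:h)], gaussianKernel(1.5),
               tolerance = 1e-12)

  ph <- makePhantom("benign", phantomParams(seed = 3))$image
  expect_lte(var(as.numeric(gaussianSmooth(ph, 2))), var(as.numeric(ph)))
})

test_that("segmentation recovers the disk and is idempotent", {
  img <- diskImage(64, r = 20)
  mask <- segmentROI(img)
  expect_lt(abs(sum(mask) - pi * 400) / (pi * 400), 0.1)
  expect_error(segmentROI(matrix(0.02, 32, 32)), "no mass")
  expect_equal(segmentROI(mask * 1), mask)
})

test_that("enhancement operators keep intensities in [0, 1]", {
  ph <- makePhantom("malignant", phantomParams(seed = 5))
  roi <- ROIPatch(ph$image)
  for (out in list(suppressNeighborTissue(roi), correctBackground(roi),
                   gammaTransform(ph$image), gaussianSmooth(ph$image, 2),
                   enhanceROI(roi))) {
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("segmentation agrees with an independent image-analysis toolkit", {
  skip_if_not_installed("EBImage")
  ph <- makePhantom("benign", phantomParams(speckleSigma = 0.05, seed = 13))
  mask <- segmentROI(ph$image)
  thr <- EBImage::otsu(EBImage::Image(ph$image), range = c(0, 1))
  ref <- EBImage::fillHull(EBImage::bwlabel(ph$image > thr))
  refMask <- as.matrix(ref) > 0
  dice <- 2 * sum(mask & refMask) / (sum(mask) + sum(refMask))
  expect_gte(dice, 0.95)
})
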