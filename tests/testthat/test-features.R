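test_that("resize caps the longest side and preserves aspect ratio", {
  big <- matrix(runif(200 * 100), 200, 100)
  out <- resizeMaxSide(big, 100)
  expect_equal(dim(out), c(100, 50))
  small <- matrix(runif(80 * 60), 80, 60)
  expect_identical(resizeMaxSide(small, 100), small)
  expect_equal(dim(resizeMaxSide(matrix(0.5, 150, 90), 100)), c(100, 60))
})

test_that("dense descriptors are deterministic, normalized, counted by the grid", {
  img <- makePhantom("benign", phantomParams(seed = 2))$image[1:64, 1:64]
  d1 <- extractDescriptors(img, 8)
  d2 <- extractDescriptors(img, 8)
  expect_identical(d1, d2)
  # grid count: floor((64 - 16) / 8) + 1 = 7 positions per axis
  expect_equal(nrow(d1$vectors), 49)
  expect_equal(ncol(d1$vectors), 128)
  nrm <- sqrt(rowSums(d1$vectors^2))
  expect_true(all(abs(nrm[nrm > 0] - 1) < 1e-9))

  cst <- matrix(0.7, 64, 64)
  expect_true(all(extractDescriptors(cst, 8)$vectors == 0))

  tiny <- matrix(runif(100), 10, 10)
  expect_equal(nrow(extractDescriptors(tiny, 8)$vectors), 0)
})

test_that("codebook construction is seeded k-means with exact recovery of repeats", {
  pts <- matrix(rnorm(5 * 4), 5, 4)
  X <- pts[rep(1:5, each = 20), ]
  cb <- buildCodebook(X, 5, seed = 3)
  # centroids are exactly the distinct points
  ord <- order(codewords(cb)[, 1])
  expect_equal(codewords(cb)[ord, ], pts[order(pts[, 1]), ],
               tolerance = 1e-12, ignore_attr = TRUE)

  Y <- matrix(rnorm(300 * 6), 300)
  expect_identical(codewords(buildCodebook(Y, 10, seed = 9)),
                   codewords(buildCodebook(Y, 10, seed = 9)))
  expect_error(buildCodebook(Y[1:5, ], 10), "at least M")

  # fitted distortion beats a random assignment of the same points
  cb2 <- buildCodebook(Y, 10, seed = 1)
  dist2 <- function(A, B)
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2 <- dist2(Y, codewords(cb2))
  fitted <- sum(d2[cbind(1:300, max.col(-d2, ties.method = "first"))])
  rnd <- withr::with_seed(4, sum(d2[cbind(1:300, sample(10, 300, TRUE))]))
  expect_lt(fitted, rnd)
})

test_that("concentric zones partition every pixel for many shapes and layer counts", {
  part <- assignZones(c(100, 100), 4)
  expect_equal(zoneRadii(part), (1:4) * sqrt(2e4) / 2 / 4)
  pts <- rbind(c(50.5, 50.5), c(1, 1), c(50.5, 50.5 + 30))
  expect_equal(zoneOf(part, pts), c(1L, 4L, 2L))

  p1 <- assignZones(c(40, 60), 1)
  grid <- as.matrix(expand.grid(1:40, 1:60))
  expect_true(all(zoneOf(p1, grid) == 1L))

  for (shape in list(c(32, 32), c(50, 30), c(41, 67), c(8, 120), c(99, 98))) {
    grid <- as.matrix(expand.grid(seq_len(shape[1]), seq_len(shape[2])))
    for (n in c(1:4, 8, 16)) {
      z <- zoneOf(assignZones(shape, n), grid)
      expect_true(all(z >= 1L & z <= n))
      expect_equal(length(z), prod(shape))  # each pixel in exactly one zone
    }
  }
})

test_that("zoned bag of words counts each descriptor once per level", {
  words <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  cb <- new("Codebook", words = words)
  part <- assignZones(c(100, 100), 3)

  # single descriptor nearest word 3, sitting in zone 2
  desc <- list(positions = matrix(c(50.5, 50.5 + 25), 1),
               vectors = matrix(c(0.1, 0.9), 1))
  z <- zonedBoW(desc, cb, part)
  expect_equal(z@histWhole, c(0, 0, 1, 0))
  expect_equal(z@histZones[2, ], c(0, 0, 1, 0))
  expect_equal(sum(z@histZones), 1)

  # exact tie between words 1 and 4 -> lowest index wins
  tie <- list(positions = matrix(c(50.5, 50.5), 1),
              vectors = matrix(c(0.5, 0.5), 1))
  zt <- zonedBoW(tie, cb, part)
  expect_equal(which(zt@histWhole == 1), 1L)

  # zone histograms always sum to the whole-image histogram
  img <- makePhantom("malignant", phantomParams(seed = 7))$image
  d <- extractDescriptors(img, 8)
  cb2 <- buildCodebook(d$vectors, 8, seed = 2)
  z2 <- zonedBoW(d, cb2, assignZones(dim(img), 4))
  expect_equal(colSums(z2@histZones), z2@histWhole)
  expect_equal(sum(z2@histWhole), nrow(d$vectors))
})

test_that("combined features are the weighted concatenation of all blocks", {
  z <- new("ZonedBoW", histWhole = c(2, 1, 0),
           histZones = rbind(c(1, 1, 0), c(1, 0, 0)),
           weights = rep(1, 3))
  expect_equal(combineFeatures(z), c(2, 1, 0, 1, 1, 0, 1, 0, 0))

  # whole-image only (no zones) -> length M
  z0 <- new("ZonedBoW", histWhole = c(2, 1, 0),
            histZones = matrix(0, 0, 3), weights = 1)
  expect_equal(combineFeatures(z0), c(2, 1, 0))

  # M = 200, N = 4 -> 1000 dimensions
  zz <- new("ZonedBoW", histWhole = rep(1, 200),
            histZones = matrix(1 / 4, 4, 200), weights = rep(1, 5))
  expect_length(combineFeatures(zz), 1000)

  # weights scale their own block
  zw <- new("ZonedBoW", histWhole = c(2, 1, 0),
            histZones = rbind(c(1, 1, 0), c(1, 0, 0)),
            weights = c(1, 2, 3))
  expect_equal(combineFeatures(zw), c(2, 1, 0, 2, 2, 0, 3, 0, 0))
})
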