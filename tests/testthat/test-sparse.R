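test_that("coordinate descent matches the orthonormal closed form", {
  D <- new("Dictionary", atoms = diag(2))
  expect_equal(sparseCode(c(1.0, 0.1), D, 0.4), c(0.8, 0))

  # random orthonormal dictionaries: soft threshold at gamma / 2
  set.seed(20)
  for (i in 1:10) {
    Q <- qr.Q(qr(matrix(rnorm(36), 6)))
    x <- rnorm(6)
    gamma <- runif(1, 0.1, 1)
    ref <- Q %*% (sign(crossprod(Q, x)) *
                    pmax(abs(crossprod(Q, x)) - gamma / 2, 0))
    a <- sparseCode(x, Q, gamma)
    expect_equal(as.numeric(Q %*% a), as.numeric(ref), tolerance = 1e-8)
  }

  # unregularised limit: alpha -> D^{-1} x
  set.seed(21)
  Dm <- matrix(rnorm(16), 4)
  Dm <- sweep(Dm, 2, sqrt(colSums(Dm^2)), "/")
  x <- rnorm(4)
  expect_equal(sparseCode(x, Dm, 1e-10), as.numeric(solve(Dm, x)),
               tolerance = 1e-5)

  expect_error(sparseCode(c(1, NA), D, 0.1), "non-finite")
  expect_error(sparseCode(c(1, 1, 1), D, 0.1), "dimension")
})

test_that("lasso solutions satisfy the KKT conditions", {
  set.seed(22)
  for (i in 1:10) {
    D <- matrix(rnorm(40), 5, 8)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    x <- rnorm(5)
    gamma <- 0.3
    a <- sparseCode(x, D, gamma)
    g <- 2 * crossprod(D, x - D %*% a)
    on <- abs(a) > 0
    expect_true(all(abs(g[!on]) <= gamma + 1e-6))
    if (any(on))
      expect_equal(as.numeric(g[on]), gamma * sign(a[on]), tolerance = 1e-6)
  }
})

test_that("lasso matches an exhaustive small-support oracle", {
  set.seed(23)
  worst <- 0
  for (i in 1:50) {
    s <- sample(4:6, 1)
    k <- s + sample(0:2, 1)
    D <- matrix(rnorm(k * s), k, s)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    sup <- sample(s, 2)
    x <- D[, sup] %*% runif(2, 0.5, 1.5) + rnorm(k, sd = 0.05)
    gamma <- 0.5
    a <- sparseCode(x, D, gamma)
    gap <- abs(lassoObjective(D, x, a, gamma) -
                 lassoOracleObjective(D, x, gamma))
    worst <- max(worst, gap)
  }
  expect_lte(worst, 1e-6)
})

test_that("K-SVD decreases its objective and recovers a planted dictionary", {
  set.seed(24)
  X <- matrix(rnorm(12 * 60), 12, 60)
  fit <- ksvdLearn(X, 10, 0.2, iters = 15, seed = 4)
  obj <- attr(fit, "objective")
  expect_true(all(diff(obj) <= 1e-9))
  expect_equal(sqrt(colSums(atoms(fit)^2)), rep(1, 10), tolerance = 1e-9)

  # planted recovery: noiseless single-atom columns
  k <- 16; s <- 12; m <- 20 * s
  set.seed(25)
  Dt <- matrix(rnorm(k * s), k)
  Dt <- sweep(Dt, 2, sqrt(colSums(Dt^2)), "/")
  Xp <- Dt[, sample(s, m, TRUE)] * rep(runif(m, 0.5, 1.5), each = k)
  rec <- ksvdLearn(Xp, s, 1e-4, iters = 30, seed = 5)
  codes <- sparseCode(Xp, rec, 1e-4)
  err <- mean(sqrt(colSums((Xp - atoms(rec) %*% codes)^2)))
  expect_lte(err, 1e-3)

  expect_identical(atoms(ksvdLearn(X, 10, 0.2, iters = 5, seed = 4)),
                   atoms(ksvdLearn(X, 10, 0.2, iters = 5, seed = 4)))
  expect_error(ksvdLearn(X[, 1:5], 10, 0.2), "at least s")
})

test_that("pooling collapses codes per atom and ignores instance order", {
  codes <- cbind(c(1, -2), c(3, 0))
  expect_equal(as.numeric(poolBag(codes, "avg")), c(2, 1))
  expect_equal(as.numeric(poolBag(codes, "max")), c(3, 2))
  single <- matrix(c(-1.5, 2), 2, 1)
  expect_equal(as.numeric(poolBag(single, "avg")), c(1.5, 2))
  expect_equal(as.numeric(poolBag(single, "max")), c(1.5, 2))
  perm <- codes[, 2:1]
  expect_equal(poolBag(perm, "avg"), poolBag(codes, "avg"))
  expect_equal(poolBag(perm, "max"), poolBag(codes, "max"))
})

test_that("bag embedding is the pooled code of each bag's instances", {
  set.seed(26)
  D <- ksvdLearn(matrix(rnorm(6 * 40), 6, 40), 10, 0.2, iters = 5, seed = 1)
  bags <- lapply(1:3, function(i)
    Bag(matrix(rnorm(4 * 6), 4, 6), i %% 2, paste0("b", i)))
  emb <- embedBags(bags, D, 0.2, "avg")
  expect_equal(dim(emb$features), c(3, 10))
  expect_equal(emb$labels, c(1L, 0L, 1L))
  expect_true(all(emb$features >= 0))

  # recomposition: row 2 equals pool of independently computed codes
  codes <- sparseCode(t(instances(bags[[2]])), D, 0.2)
  expect_equal(emb$features[2, ], as.numeric(poolBag(codes, "avg")),
               ignore_attr = TRUE)

  # duplicated bag duplicates its row
  emb2 <- embedBags(c(bags, bags[1]), D, 0.2, "avg")
  expect_equal(emb2$features[4, ], emb$features[1, ], ignore_attr = TRUE)

  badBag <- Bag(matrix(rnorm(8), 2, 4), 0)
  expect_error(embedBags(list(badBag), D, 0.2), "dimension")
})

test_that("OMP coding reconstructs with the requested sparsity", {
  set.seed(27)
  D <- matrix(rnorm(8 * 12), 8, 12)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  x <- D[, 3] * 2 - D[, 7] * 1.5
  a <- ompCode(x, D, 2)
  expect_lte(sum(a != 0), 2)
  expect_equal(as.numeric(D %*% a), as.numeric(x), tolerance = 1e-8)
})

test_that("coordinate descent agrees with an independent lasso solver", {
  skip_if_not_installed("glmnet")
  set.seed(28)
  k <- 12; s <- 8
  D <- matrix(rnorm(k * s), k, s)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  x <- rnorm(k)
  gamma <- 0.4
  a <- sparseCode(x, D, gamma)
  # glmnet solves (1/2n)||y - Xb||^2 + lambda ||b||_1
  fit <- glmnet::glmnet(D, x, alpha = 1, lambda = gamma / (2 * k),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
  b <- as.numeric(fit$beta)
  expect_lte(lassoObjective(D, x, a, gamma),
             lassoObjective(D, x, b, gamma) + 1e-8)
  expect_equal(a, b, tolerance = 1e-4)
})
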