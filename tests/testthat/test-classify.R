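toyBlobs <- function(seed = 4, n = 20, sep = 2, sd = 0.5) {
  withr::with_seed(seed, list(
    X = rbind(matrix(rnorm(2 * n, -sep, sd), n, 2),
              matrix(rnorm(2 * n, sep, sd), n, 2)),
    y = rep(0:1, each = n)))
}

test_that("RVM separates toys, stays sparse, and outputs probabilities", {
  toy <- toyBlobs()
  m <- rvmTrain(toy$X, toy$y)
  pr <- rvmPredict(m, toy$X)
  expect_equal(mean(pr$label == toy$y), 1)
  expect_lt(nrow(m@relevanceVectors), nrow(toy$X))
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))

  # midpoint of the symmetric blobs is maximally uncertain
  mid <- rvmPredict(m, matrix(0, 1, 2))$prob
  expect_lt(abs(mid - 0.5), 0.1)

  # a point at a positive relevance vector deep in its blob
  deep <- rvmPredict(m, matrix(c(2, 2), 1))$prob
  expect_gt(deep, 0.9)

  # XOR needs the nonlinear kernel
  xor <- withr::with_seed(5, {
    X <- matrix(runif(400, -1, 1), 200)
    list(X = X, y = as.integer(X[, 1] * X[, 2] > 0))
  })
  mx <- rvmTrain(xor$X, xor$y, kernelWidth = 0.5)
  expect_gte(mean(rvmPredict(mx, xor$X)$label == xor$y), 0.95)

  expect_error(rvmTrain(toy$X, rep(1, 40)), "single class")
  expect_error(rvmPredict(m, matrix(0, 1, 3)), "dimension")
})

test_that("confusion metrics follow their defining ratios", {
  m <- confusionMetrics(list(TP = 50, FN = 0, TN = 50, FP = 0))
  expect_equal(unlist(m), c(SE = 100, SP = 100, ACC = 100))

  m2 <- confusionMetrics(list(TP = 45, FN = 15, TN = 68, FP = 16))
  expect_equal(m2$SE, 75)
  expect_equal(m2$SP, 80.95, tolerance = 1e-4)
  expect_equal(m2$ACC, 78.47, tolerance = 1e-4)

  # swapping the class labels swaps SE and SP
  m3 <- confusionMetrics(list(TP = 68, FN = 16, TN = 45, FP = 15))
  expect_equal(m3$SE, m2$SP)
  expect_equal(m3$SP, m2$SE)

  # counts from labels
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(cc), c(TP = 1, FN = 1, TN = 1, FP = 1))

  expect_true(is.na(confusionMetrics(list(TP = 0, FN = 0, TN = 3,
                                          FP = 1))$SE))
})

test_that("ROC/AUC equals the rank statistic and behaves under reversal", {
  r <- rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(auc(r), 1)

  set.seed(6)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # many ties
    lb <- sample(0:1, n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    a <- auc(rocAUC(sc, lb))
    # Mann-Whitney with rank-averaged ties
    rk <- rank(sc)
    n1 <- sum(lb == 1); n0 <- sum(lb == 0)
    u <- (sum(rk[lb == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    expect_equal(a, u, tolerance = 1e-9)
    expect_equal(auc(rocAUC(-sc, lb)), 1 - a, tolerance = 1e-9)
  }

  set.seed(7)
  big <- auc(rocAUC(runif(4000), rep(0:1, 2000)))
  expect_lt(abs(big - 0.5), 0.05)

  expect_error(rocAUC(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("majority vote breaks ties toward malignant", {
  expect_equal(voteLabels(cbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))),
               c(1L, 1L, 0L))
  expect_equal(voteLabels(cbind(c(1, 0), c(0, 1))), c(1L, 1L))  # ties
  expect_equal(voteLabels(matrix(c(0.2 >= 0.5, 0.4 >= 0.5, 0.9 >= 0.5) * 1,
                                 1)), 0L)
})

test_that("a one-member ensemble replays the standalone pipeline exactly", {
  bags <- makeFeatureBags(10, J = 4, k = 6, rho = 0.5, delta = 4, seed = 31)
  ens <- trainEnsemble(bags, sizes = 8, gamma = 0.2, seed = 9,
                       ksvdIters = 5)
  out <- ensemblePredict(ens, bags)

  # replay the member by hand with the same derived seed
  memberSeed <- withr::with_seed(9, sample.int(.Machine$integer.max - 1L,
                                               1))
  X <- t(do.call(rbind, lapply(bags, instances)))
  D <- ksvdLearn(X, 8, 0.2, iters = 5, seed = memberSeed)
  emb <- embedBags(bags, D, 0.2, "avg")
  mdl <- rvmTrain(emb$features, emb$labels)
  pr <- rvmPredict(mdl, emb$features)
  expect_equal(out$scores, pr$prob)
  expect_equal(out$labels, pr$label)

  # determinism of the ensemble as a whole
  ens2 <- trainEnsemble(bags, sizes = 8, gamma = 0.2, seed = 9,
                        ksvdIters = 5)
  expect_equal(ensemblePredict(ens2, bags)$scores, out$scores)

  # mean posterior combination
  expect_equal(mean(c(0.2, 0.4, 0.9)), 0.5)
  multi <- trainEnsemble(bags, sizes = c(6, 8), gamma = 0.2, seed = 9,
                         ksvdIters = 5)
  om <- ensemblePredict(multi, bags)
  expect_equal(om$scores, rowMeans(om$memberProbs))

  expect_error(trainEnsemble(bags, sizes = c(8, 8)), "distinct")
  expect_error(trainEnsemble(bags, sizes = 500), "exceeds")
})

test_that("cross-validation is stratified, seeded, and leak-free", {
  bags <- makeFeatureBags(6, J = 3, k = 5, rho = 0.5, delta = 5, seed = 41)

  # leave-one-out style: k = n per class runs and predicts every bag
  cv <- kfoldCV(bags, sizes = 6, gamma = 0.2, k = 6, seed = 3,
                ksvdIters = 4)
  expect_equal(nrow(cv$perRepeat), 1)
  expect_length(cv$pred, 12)

  cv2 <- kfoldCV(bags, sizes = 6, gamma = 0.2, k = 6, seed = 3,
                 ksvdIters = 4)
  expect_identical(cv$perRepeat, cv2$perRepeat)

  # no leakage: with a fixed train split, flipping the held-out labels and
  # re-running leaves the learned dictionaries bit-identical
  tr <- bags[c(1:4, 7:10)]
  te <- bags[c(5, 6, 11, 12)]
  m1 <- trainEnsemble(tr, sizes = 6, gamma = 0.2, seed = 77, ksvdIters = 4)
  p1 <- ensemblePredict(m1, te)
  teFlip <- lapply(te, function(b) Bag(instances(b), 1L - bagLabel(b),
                                       b@bagId))
  m2 <- trainEnsemble(tr, sizes = 6, gamma = 0.2, seed = 77, ksvdIters = 4)
  p2 <- ensemblePredict(m2, teFlip)
  expect_identical(atoms(m1@members[[1]]$dictionary),
                   atoms(m2@members[[1]]$dictionary))
  expect_identical(p1$scores, p2$scores)  # scores ignore held-out labels
})
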