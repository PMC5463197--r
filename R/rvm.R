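sigmoid <- function(z) 1 / (1 + exp(-z))

rbfKernel <- function(X, Y, width) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  exp(-pmax(d2, 0) / (2 * width^2))
}

# Median pairwise Euclidean distance, the usual RBF width heuristic.
medianHeuristic <- function(X) {
  d <- as.numeric(stats::dist(X))
  d <- d[d > 0]
  if (!length(d)) return(1)
  stats::median(d)
}

#' Train a relevance vector machine classifier
#'
#' Sparse-Bayesian kernel logistic regression: an RBF kernel expansion with
#' independent zero-mean Gaussian priors on the weights whose per-weight
#' precisions are re-estimated by evidence maximisation under a Laplace
#' approximation of the posterior. Weights whose precision diverges beyond
#' 1e6 are pruned; the surviving training rows are the relevance vectors.
#'
#' @param X feature matrix, one sample per row.
#' @param y labels in \{0, 1\}; both classes must be present.
#' @param kernelWidth RBF width; default median pairwise distance.
#' @param maxIter cap on precision re-estimation cycles; default 300.
#' @return An [RVMModel-class].
#' @export
rvmTrain <- function(X, y, kernelWidth = NULL, maxIter = 300L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (any(table(y) < 2)) stop("need at least 2 samples per class")
  n <- nrow(X)
  if (is.null(kernelWidth)) kernelWidth <- medianHeuristic(X)

  Phi <- cbind(rbfKernel(X, X, kernelWidth), 1)  # bias column last
  p <- ncol(Phi)
  active <- seq_len(p)
  alpha <- rep(1, p)
  w <- numeric(p)
  alphaMax <- 1e6

  for (it in seq_len(maxIter)) {
    Pa <- Phi[, active, drop = FALSE]
    aa <- alpha[active]
    wa <- w[active]

    # Laplace / IRLS for the posterior mode given the precisions
    for (inner in seq_len(50)) {
      eta <- as.numeric(Pa %*% wa)
      mu <- sigmoid(eta)
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      g <- crossprod(Pa, y - mu) - aa * wa
      if (max(abs(g)) < 1e-6) break
      B <- pmax(mu * (1 - mu), 1e-10)
      H <- crossprod(Pa * B, Pa)
      diag(H) <- diag(H) + aa
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) { diag(H) <- diag(H) + 1e-8; step <- solve(H, g) }
      objOld <- sum(y * log(mu) + (1 - y) * log(1 - mu)) -
        0.5 * sum(aa * wa^2)
      lam <- 1
      repeat {
        wNew <- wa + lam * as.numeric(step)
        muN <- pmin(pmax(sigmoid(as.numeric(Pa %*% wNew)), 1e-12), 1 - 1e-12)
        objNew <- sum(y * log(muN) + (1 - y) * log(1 - muN)) -
          0.5 * sum(aa * wNew^2)
        if (objNew >= objOld - 1e-12 || lam < 1e-4) break
        lam <- lam / 2
      }
      wa <- wNew
    }

    mu <- pmin(pmax(sigmoid(as.numeric(Pa %*% wa)), 1e-12), 1 - 1e-12)
    B <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Pa * B, Pa)
    diag(H) <- diag(H) + aa
    Sigma <- tryCatch(chol2inv(chol(H)), error = function(e) solve(H))
    gam <- 1 - aa * diag(Sigma)
    gam <- pmin(pmax(gam, 1e-12), 1)
    aNew <- gam / pmax(wa^2, 1e-20)
    aNew <- pmin(aNew, 1e12)

    delta <- max(abs(log(aNew) - log(aa)))
    alpha[active] <- aNew
    w[active] <- wa
    keep <- aNew < alphaMax
    if (!any(keep)) keep[which.max(abs(wa))] <- TRUE
    active <- active[keep]
    w[setdiff(seq_len(p), active)] <- 0
    if (delta < 1e-3) break
  }

  hasBias <- p %in% active
  rvIdx <- setdiff(active, p)
  new("RVMModel",
      relevanceVectors = X[rvIdx, , drop = FALSE],
      weights = w[rvIdx],
      bias = if (hasBias) w[p] else 0,
      hasBias = hasBias,
      kernelWidth = kernelWidth,
      alphaPrior = alpha[active],
      rvIndex = as.integer(rvIdx))
}

#' Predict malignancy probabilities with an RVM
#'
#' Sigmoid of the RBF kernel expansion over the relevance vectors; the
#' predicted label is 1 (malignant) when the probability is at least 0.5.
#'
#' @param model an [RVMModel-class].
#' @param X rows to classify.
#' @return list with `prob` and `label`.
#' @export
rvmPredict <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (nrow(model@relevanceVectors) > 0 &&
      ncol(X) != ncol(model@relevanceVectors))
    stop("feature dimension does not match the trained model")
  eta <- rep(model@bias, nrow(X))
  if (nrow(model@relevanceVectors) > 0) {
    K <- rbfKernel(X, model@relevanceVectors, model@kernelWidth)
    eta <- eta + as.numeric(K %*% model@weights)
  }
  prob <- sigmoid(eta)
  list(prob = prob, label = as.integer(prob >= 0.5))
}
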