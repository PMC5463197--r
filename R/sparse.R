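#' l1 sparse coding against a dictionary
#'
#' Solves min_a ||x - D a||_2^2 + gamma ||a||_1 by cyclic coordinate descent
#' (soft threshold at gamma / 2), converged when the largest coefficient
#' change in a sweep falls below `tol` or after `maxSweeps` sweeps.
#'
#' @param x instance vector of length k, or a k x m matrix coded column-wise.
#' @param D a [Dictionary-class] (or k x s atom matrix).
#' @param gamma l1 regularisation weight, > 0.
#' @param tol convergence tolerance on coefficient changes; default 1e-8.
#' @param maxSweeps sweep cap; default 10000.
#' @return length-s code vector, or s x m code matrix for matrix input.
#' @export
sparseCode <- function(x, D, gamma, tol = 1e-8, maxSweeps = 10000L) {
  A <- if (is(D, "Dictionary")) D@atoms else D
  if (gamma <= 0) stop("gamma must be positive")
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, ncol = 1) else x
  if (!all(is.finite(X))) stop("non-finite input")
  if (nrow(X) != nrow(A)) stop("instance dimension does not match dictionary")
  codes <- .cd_lasso(A, X, gamma, tol, as.integer(maxSweeps))
  if (vec) as.numeric(codes) else codes
}

#' Orthogonal matching pursuit coding (l0 alternative)
#'
#' Greedy support selection up to `Tmax` atoms with least-squares refits;
#' provided for comparison with the l1 coder.
#'
#' @param x instance vector.
#' @param D a [Dictionary-class] or atom matrix.
#' @param Tmax sparsity level (number of atoms).
#' @return length-s code vector.
#' @export
ompCode <- function(x, D, Tmax) {
  A <- if (is(D, "Dictionary")) D@atoms else D
  s <- ncol(A)
  a <- numeric(s)
  support <- integer(0)
  r <- x
  for (t in seq_len(min(Tmax, s))) {
    corr <- abs(crossprod(A, r))
    corr[support] <- -Inf
    j <- which.max(corr)
    support <- c(support, j)
    coef <- qr.coef(qr(A[, support, drop = FALSE]), x)
    coef[is.na(coef)] <- 0
    r <- x - A[, support, drop = FALSE] %*% coef
    if (sum(r^2) < 1e-20) break
  }
  a[support] <- coef
  a
}

sparseObjective <- function(X, A, codes, gamma) {
  sum((X - A %*% codes)^2) + gamma * sum(abs(codes))
}

#' K-SVD dictionary learning with an l1 coding step
#'
#' Alternates (a) sparse coding of every data column with the current
#' dictionary and (b) sequential atom updates: for each atom, the rank-1 SVD
#' of the residual restricted to the columns using that atom proposes a new
#' atom and coefficients, accepted only when it lowers the penalised
#' objective (so the recorded objective never increases). Unused atoms are
#' replaced by the worst-reconstructed data column, renormalized. Atoms keep
#' unit norm throughout.
#'
#' @param X k x m data matrix (instances as columns).
#' @param s dictionary size; m >= s required.
#' @param gamma l1 weight for the coding step.
#' @param iters alternation count; default 30.
#' @param seed RNG seed (atom initialisation from random data columns).
#' @return A [Dictionary-class]; the per-iteration objective trace is
#'   attached as attribute `"objective"`.
#' @export
ksvdLearn <- function(X, s, gamma, iters = 30L, seed = 1L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  k <- nrow(X); m <- ncol(X)
  if (m < s) stop("need at least s = ", s, " data columns, got ", m)
  # diverse initialisation: seeded first column, then farthest-point
  # selection by angular distance, so near-duplicate columns are avoided
  nrmX <- sqrt(colSums(X^2))
  usable <- which(nrmX > 1e-12)
  if (length(usable) < s) stop("not enough non-zero data columns")
  U <- sweep(X[, usable, drop = FALSE], 2, nrmX[usable], "/")
  pick <- integer(s)
  pick[1] <- withSeed(seed, sample.int(length(usable), 1))
  minCoh <- abs(crossprod(U, U[, pick[1]]))
  for (j in seq_len(s - 1) + 1) {
    pick[j] <- which.min(minCoh)
    minCoh <- pmax(minCoh, abs(crossprod(U, U[, pick[j]])))
  }
  A <- U[, pick, drop = FALSE]

  obj <- numeric(iters)
  codes <- NULL
  for (it in seq_len(iters)) {
    # warm-started coding: every coordinate update is a descent step, so
    # the penalised objective cannot increase between iterations
    codes <- .cd_lasso(A, X, gamma, 1e-8, 10000L, codes)
    for (j in seq_len(s)) {
      using <- which(abs(codes[j, ]) > 0)
      if (!length(using)) {
        # replace a dead atom by the worst-reconstructed column
        err <- colSums((X - A %*% codes)^2)
        w <- which.max(err)
        cand <- X[, w]
        if (sum(cand^2) > 1e-12) A[, j] <- cand / sqrt(sum(cand^2))
        next
      }
      E <- X[, using, drop = FALSE] - A %*% codes[, using, drop = FALSE] +
        A[, j] %o% codes[j, using]
      sv <- svd(E, nu = 1, nv = 1)
      u <- sv$u[, 1]; v <- sv$d[1] * sv$v[, 1]
      if (sum(u) < 0) { u <- -u; v <- -v }
      oldObj <- sum((E - A[, j] %o% codes[j, using])^2) +
        gamma * sum(abs(codes[j, using]))
      newObj <- sum((E - u %o% v)^2) + gamma * sum(abs(v))
      if (newObj <= oldObj + 1e-12) {
        A[, j] <- u
        codes[j, using] <- v
      }
    }
    obj[it] <- sparseObjective(X, A, codes, gamma)
  }
  out <- new("Dictionary", atoms = A)
  attr(out, "objective") <- obj
  out
}

#' Pool a bag's instance codes into one bag feature
#'
#' Collapses the s x J matrix of instance codes to an s-vector of pooled
#' absolute coefficients: per-atom mean ("avg", the default) or maximum
#' ("max").
#'
#' @param codes s x J code matrix (columns are instances of one bag).
#' @param mode "avg" or "max".
#' @return non-negative numeric vector of length s with attribute
#'   `"pooling"`.
#' @export
poolBag <- function(codes, mode = c("avg", "max")) {
  mode <- match.arg(mode)
  if (!is.matrix(codes)) codes <- matrix(codes, ncol = 1)
  b <- if (mode == "avg") rowMeans(abs(codes)) else
    apply(abs(codes), 1, max)
  attr(b, "pooling") <- mode
  b
}

#' Embed bags as fixed-length sparse-code features
#'
#' Sparse-codes every instance of every bag against the dictionary and pools
#' the absolute coefficients per bag, converting the multi-instance problem
#' into a single-instance one: each bag becomes an s-dimensional row.
#'
#' @param bags list of [Bag-class] objects.
#' @param D a [Dictionary-class].
#' @param gamma l1 weight.
#' @param mode pooling mode, "avg" or "max".
#' @return list with `features` (bags x s matrix, rows in bag order) and
#'   `labels`.
#' @export
embedBags <- function(bags, D, gamma, mode = c("avg", "max")) {
  mode <- match.arg(mode)
  A <- D@atoms
  k <- nrow(A)
  feat <- t(vapply(bags, function(b) {
    ins <- instances(b)
    if (ncol(ins) != k) stop("instance dimension does not match dictionary")
    codes <- sparseCode(t(ins), D, gamma)
    as.numeric(poolBag(codes, mode))
  }, numeric(ncol(A))))
  rownames(feat) <- vapply(bags, function(b) b@bagId, character(1))
  list(features = feat, labels = vapply(bags, bagLabel, integer(1)))
}
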