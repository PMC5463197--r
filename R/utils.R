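#' @useDynLib sparseMIL, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif sd var
#' @importFrom utils modifyList head tail
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Images are plain numeric matrices with intensities in [0, 1].
assertGrayImage <- function(img, minSide = 8L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix")
  if (nrow(img) < minSide || ncol(img) < minSide)
    stop("image must be at least ", minSide, " pixels on each side")
  if (!all(is.finite(img)))
    stop("image contains non-finite values")
  if (min(img) < 0 || max(img) > 1)
    stop("image intensities must lie in [0, 1]")
  invisible(img)
}

# Otsu's rule: the global threshold maximizing between-class variance
# over a 256-bin histogram; ties resolved toward the lower threshold.
otsuThreshold <- function(img) {
  nb <- 256L
  bin <- pmin(floor(img * nb), nb - 1L)
  h <- tabulate(as.integer(bin) + 1L, nbins = nb)
  p <- h / sum(h)
  levels <- (seq_len(nb) - 0.5) / nb
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  muT <- mu[nb]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, nb)
  bc[valid] <- (muT * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  if (!any(is.finite(bc)))
    stop("cannot threshold a constant image")
  t <- which.max(bc)
  t / nb
}

# 8-connected component labelling by iterative flood fill.
labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      q <- stack
      stack <- integer(0)
      r <- ((q - 1L) %% h) + 1L
      cc <- ((q - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc2 <- cc + dc
        ok <- rr >= 1L & rr <= h & cc2 >= 1L & cc2 <= w
        if (!any(ok)) next
        nb <- (cc2[ok] - 1L) * h + rr[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- cur
          stack <- c(stack, nb)
        }
      }
      stack <- unique(stack)
    }
  }
  lab
}

largestComponent <- function(mask) {
  lab <- labelComponents(mask)
  if (max(lab) == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# Fill interior holes: background components not touching the image border.
fillHoles <- function(mask) {
  bg <- labelComponents(!mask)
  if (max(bg) == 0L) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  border <- unique(c(bg[1, ], bg[h, ], bg[, 1], bg[, w]))
  border <- border[border > 0L]
  hole <- bg > 0L & !(bg %in% border)
  mask | hole
}

# FNV-1a-style hash of a deparsed R object; used to fingerprint
# configurations. Multiplication is split so intermediates stay exact
# in double precision.
fnvHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  m <- 2^31
  mulmod <- function(a, b) {
    a1 <- a %/% 65536; a0 <- a %% 65536
    (((a1 * b) %% m * 65536) %% m + (a0 * b) %% m) %% m
  }
  hash <- 2166136261 %% m
  for (b in bytes) {
    hash <- bitwXor(as.integer(hash), as.integer(b))
    hash <- mulmod(hash, 16777619)
  }
  sprintf("%08x", as.integer(hash))
}
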