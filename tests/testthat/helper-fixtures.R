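# Shared fixtures, all generated in code.

# Disk phantom: filled disk of radius r on a dark background.
diskImage <- function(side = 64, r = 20, bg = 0.1, fg = 0.9) {
  ctr <- (side + 1) / 2
  rr <- matrix(seq_len(side), side, side) - ctr
  cc <- matrix(seq_len(side), side, side, byrow = TRUE) - ctr
  img <- matrix(bg, side, side)
  img[rr^2 + cc^2 <= r^2] <- fg
  img
}

# The Breast Cancer Wisconsin (Original) file in the UCI comma-separated
# dialect, reconstructed from MASS::biopsy (same 699 records; '?' marks the
# missing bare-nuclei values, class coded 2 = benign / 4 = malignant).
wbcdFile <- function() {
  path <- file.path(tempdir(), "breast-cancer-wisconsin.data")
  if (file.exists(path)) return(path)
  e <- new.env()
  utils::data("biopsy", package = "MASS", envir = e)
  b <- e$biopsy
  vals <- as.matrix(b[, 2:10])
  attrStr <- apply(vals, 1, function(v)
    paste(ifelse(is.na(v), "?", v), collapse = ","))
  cls <- ifelse(b$class == "malignant", 4L, 2L)
  writeLines(paste(b$ID, attrStr, cls, sep = ","), path)
  path
}

# Exhaustive lasso oracle for tiny problems: enumerate all supports up to
# size `maxSupport` and all sign patterns; for a fixed support S and sign
# vector sgn the minimiser of ||x - D_S a||^2 + gamma ||a||_1 solves
# 2 D_S'D_S a = 2 D_S'x - gamma * sgn; candidates with inconsistent signs
# are discarded. Returns the best objective found.
lassoOracleObjective <- function(D, x, gamma, maxSupport = ncol(D)) {
  s <- ncol(D)
  best <- sum(x^2)  # empty support
  for (size in seq_len(maxSupport)) {
    for (S in utils::combn(s, size, simplify = FALSE)) {
      Ds <- D[, S, drop = FALSE]
      G <- crossprod(Ds)
      b <- crossprod(Ds, x)
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), size)))
      for (i in seq_len(nrow(signs))) {
        sgn <- signs[i, ]
        a <- tryCatch(solve(G, b - gamma * sgn / 2),
                      error = function(e) NULL)
        if (is.null(a) || any(sign(a) * sgn < 0)) next
        obj <- sum((x - Ds %*% a)^2) + gamma * sum(abs(a))
        if (obj < best) best <- obj
      }
    }
  }
  best
}

lassoObjective <- function(D, x, a, gamma) {
  sum((x - D %*% a)^2) + gamma * sum(abs(a))
}
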