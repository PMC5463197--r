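#' Phantom generation parameters
#'
#' Defaults describe the simulated study conditions: a 128-pixel square ROI,
#' a lesion-background intensity gap of 0.45, multiplicative speckle at
#' scale 0.12, nine spicules on malignant masses, and a mild background
#' plane gradient.
#'
#' @param imageSide ROI side length in pixels.
#' @param contrast lesion-background intensity gap in (0, 1).
#' @param speckleSigma multiplicative speckle scale (0 disables).
#' @param nSpicules spicule count for malignant masses, >= 3.
#' @param backgroundSlope background plane gradient per pixel.
#' @param shadow add a vertical attenuation band.
#' @param seed RNG seed.
#' @return named list of parameters.
#' @export
phantomParams <- function(imageSide = 128L, contrast = 0.45,
                          speckleSigma = 0.12, nSpicules = 9L,
                          backgroundSlope = 0.0015, shadow = FALSE,
                          seed = 1L) {
  if (contrast <= 0 || contrast >= 1) stop("contrast must lie in (0, 1)")
  if (nSpicules < 3) stop("malignant masses need at least 3 spicules")
  if (imageSide < 32) stop("imageSide must be at least 32")
  list(imageSide = as.integer(imageSide), contrast = contrast,
       speckleSigma = speckleSigma, nSpicules = as.integer(nSpicules),
       backgroundSlope = backgroundSlope, shadow = isTRUE(shadow),
       seed = as.integer(seed))
}

#' Generate one synthetic mass phantom
#'
#' Benign masses are filled ellipses (axis ratio 0.7-1) with smoothed
#' margins and homogeneous intensity; malignant masses are star polygons
#' with `nSpicules` random-length spikes and heterogeneous intensity. The
#' background is a plane with optional vertical shadow band; speckle is
#' multiplicative Rayleigh-derived noise,
#' pixel <- pixel (1 + sigma (Rayleigh(1) - mean)). The mass is brighter
#' than its background, matching the bright-centre assumption of the radius
#' estimator and segmenter. A pure function of (label, params).
#'
#' @param label "benign"/0 or "malignant"/1.
#' @param params list from [phantomParams()].
#' @return list with `image` (matrix in \[0, 1\]), `mask` (logical ground
#'   truth) and `label` (0/1).
#' @export
makePhantom <- function(label, params = phantomParams()) {
  lab <- if (is.character(label))
    match.arg(label, c("benign", "malignant")) == "malignant"
  else as.integer(label) == 1L
  n <- params$imageSide
  withSeed(params$seed, {
    ctr <- (n + 1) / 2
    rr <- matrix(seq_len(n), n, n) - ctr
    cc <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
    bg <- 0.25 + params$backgroundSlope * (cc + 0.5 * rr + 1.5 * ctr)
    r0 <- 0.22 * n
    if (!lab) {
      q <- runif(1, 0.7, 1)
      phi <- runif(1, 0, pi)
      u <- cos(phi) * cc + sin(phi) * rr
      v <- -sin(phi) * cc + cos(phi) * rr
      mask <- (u / r0)^2 + (v / (q * r0))^2 <= 1
      lesion <- params$contrast * gaussianSmooth(clip01(mask * 1), 1)
    } else {
      nsp <- params$nSpicules
      phase <- runif(1, 0, 2 * pi)
      lens <- runif(nsp, 0.25, 0.6)
      theta <- atan2(rr, cc) %% (2 * pi)
      spike <- matrix(0, n, n)
      halfw <- pi / nsp
      for (j in seq_len(nsp)) {
        aj <- (2 * pi * (j - 1) / nsp + phase) %% (2 * pi)
        dd <- abs(theta - aj)
        dd <- pmin(dd, 2 * pi - dd)
        spike <- spike + lens[j] * pmax(0, 1 - dd / halfw)
      }
      mask <- sqrt(rr^2 + cc^2) <= r0 * (0.75 + spike)
      hetero <- gaussianSmooth(matrix(runif(n * n), n, n), 3)
      hetero <- (hetero - min(hetero)) / max(1e-12, diff(range(hetero)))
      lesion <- params$contrast * (0.7 + 0.6 * hetero) *
        gaussianSmooth(clip01(mask * 1), 1)
    }
    img <- bg + lesion
    if (params$shadow) {
      band <- seq(floor(0.40 * n), floor(0.55 * n))
      img[, band] <- img[, band] * 0.7
    }
    if (params$speckleSigma > 0) {
      ray <- sqrt(-2 * log(pmax(runif(n * n), 1e-12)))
      img <- img * (1 + params$speckleSigma * (ray - sqrt(pi / 2)))
    }
    list(image = clip01(img), mask = mask, label = as.integer(lab))
  })
}

#' Generate a labelled phantom dataset
#'
#' Per-image seeds are derived from the master seed; all images share the
#' same generation parameters so class difficulty is balanced.
#'
#' @param nBenign,nMalignant image counts, each >= 1.
#' @param params list from [phantomParams()] (its seed field is ignored).
#' @param seed master seed.
#' @return list with `images`, `masks`, `labels`.
#' @export
makePhantomDataset <- function(nBenign, nMalignant,
                               params = phantomParams(), seed = 1L) {
  stopifnot(nBenign >= 1, nMalignant >= 1)
  total <- nBenign + nMalignant
  seeds <- deriveSeeds(seed, total)
  labels <- c(rep(0L, nBenign), rep(1L, nMalignant))
  out <- lapply(seq_len(total), function(i) {
    p <- params; p$seed <- seeds[i]
    makePhantom(labels[i], p)
  })
  list(images = lapply(out, `[[`, "image"),
       masks = lapply(out, `[[`, "mask"),
       labels = labels)
}

#' Boundary compactness of a mask
#'
#' Perimeter squared over area; spiculated shapes score higher than
#' ellipses of matched area.
#'
#' @param mask logical matrix.
#' @return numeric scalar.
#' @export
maskCompactness <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[2:(h + 1), 2:(w + 1)]
  boundary <- inner & !(pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
                          pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)])
  sum(boundary)^2 / max(1, sum(mask))
}

#' Simulate feature-space bags with generalized-MIL structure
#'
#' Concept instances are drawn from N(mu+, I) and background instances from
#' N(mu0, I) with ||mu+ - mu0|| = delta, so delta is the class separation in
#' noise-SD units. Positive bags contain exactly ceiling(rho J) concept
#' instances; negative bags contain none — a fraction of concept instances,
#' not a single witness, carries the bag label.
#'
#' @param nBagsPerClass bags per class.
#' @param J instances per bag.
#' @param k instance dimension.
#' @param rho concept fraction in (0, 1\].
#' @param delta mean separation in noise-SD units, >= 0.
#' @param seed RNG seed.
#' @return list of [Bag-class]; each bag carries a `"composition"`
#'   attribute with its concept/background instance counts.
#' @export
makeFeatureBags <- function(nBagsPerClass = 50, J = 8, k = 10, rho = 0.5,
                            delta = 6, seed = 1L) {
  stopifnot(rho > 0, rho <= 1, delta >= 0, J >= 1)
  nConcept <- ceiling(rho * J)
  mu0 <- numeric(k)
  muP <- c(delta, numeric(k - 1))
  withSeed(seed, {
    bags <- vector("list", 2 * nBagsPerClass)
    for (i in seq_len(2 * nBagsPerClass)) {
      pos <- i > nBagsPerClass
      nc <- if (pos) nConcept else 0L
      ins <- rbind(
        if (nc > 0)
          matrix(rnorm(nc * k), nc, k) + matrix(muP, nc, k, byrow = TRUE),
        if (J - nc > 0)
          matrix(rnorm((J - nc) * k), J - nc, k) +
            matrix(mu0, J - nc, k, byrow = TRUE))
      b <- Bag(ins, as.integer(pos), sprintf("bag%03d", i))
      attr(b, "composition") <- c(concept = nc, background = J - nc)
      bags[[i]] <- b
    }
    bags
  })
}

wbcdAttributes <- c("clump_thickness", "uniformity_of_cell_size",
                    "uniformity_of_cell_shape", "marginal_adhesion",
                    "single_epithelial_cell_size", "bare_nuclei",
                    "bland_chromatin", "normal_nucleoli", "mitoses")

#' Load the Breast Cancer Wisconsin (Original) dataset
#'
#' Parses the UCI comma-separated dialect: sample id, nine integer cytology
#' attributes in \[1, 10\] with '?' marking a missing bare-nuclei value, and
#' a class code (2 = benign, 4 = malignant), recoded to 0/1.
#'
#' @param path path to the local data file.
#' @return data.frame with `id`, the nine attribute columns, `missing`
#'   (logical) and `class` (0 benign / 1 malignant).
#' @export
loadWBCD <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, ",", fixed = TRUE)
  parse <- function(i) {
    f <- trimws(rows[[i]])
    if (length(f) != 11L)
      stop("malformed row at line ", i, ": expected 11 fields, got ",
           length(f))
    vals <- suppressWarnings(as.integer(ifelse(f == "?", NA, f)))
    if (is.na(vals[1]) || is.na(vals[11]))
      stop("malformed row at line ", i, ": non-numeric id or class")
    attrs <- vals[2:10]
    if (any(!is.na(attrs) & (attrs < 1L | attrs > 10L)))
      stop("malformed row at line ", i, ": attribute outside [1, 10]")
    if (!vals[11] %in% c(2L, 4L))
      stop("malformed row at line ", i, ": class must be 2 or 4")
    vals
  }
  m <- t(vapply(seq_along(rows), parse, integer(11)))
  df <- as.data.frame(m[, 1:10, drop = FALSE])
  names(df) <- c("id", wbcdAttributes)
  df$missing <- is.na(df$bare_nuclei)
  df$class <- as.integer(m[, 11] == 4L)
  df
}

#' Per-attribute summary of WBCD records
#'
#' Minimum, maximum, mean and sample standard deviation for each of the
#' nine cytology attributes.
#'
#' @param records data.frame from [loadWBCD()].
#' @param dropMissing drop records with a missing bare-nuclei value first
#'   (default TRUE).
#' @return data.frame with one row per attribute (min, max, mean, sd; sd is
#'   NA with fewer than two records).
#' @export
wbcdSummary <- function(records, dropMissing = TRUE) {
  if (!nrow(records)) stop("no records")
  if (dropMissing) records <- records[!records$missing, , drop = FALSE]
  stats <- t(vapply(wbcdAttributes, function(a) {
    v <- records[[a]]
    c(min = min(v), max = max(v), mean = mean(v),
      sd = if (length(v) > 1) sd(v) else NA_real_)
  }, numeric(4)))
  data.frame(attribute = wbcdAttributes, stats, row.names = NULL)
}
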