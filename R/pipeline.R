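#' Pipeline configuration
#'
#' Validated end-to-end configuration. Defaults: 200-word vocabulary, 4
#' concentric layers, 80 topics, average pooling, 10-fold cross-validation.
#'
#' @slot nBenign,nMalignant phantom counts when simulating input.
#' @slot imageSide,contrast,speckleSigma phantom generation parameters.
#' @slot gammaC,gammaR,smoothSigma enhancement parameters.
#' @slot gridStep dense descriptor grid spacing.
#' @slot vocabM vocabulary size M.
#' @slot layersN concentric layer count N.
#' @slot topicsK topic count K.
#' @slot ldaIters Gibbs sweeps for topic fitting.
#' @slot gamma l1 sparse-coding weight.
#' @slot sizes dictionary size set.
#' @slot pooling "avg" or "max".
#' @slot folds,repeats cross-validation folds and repetitions.
#' @slot ksvdIters K-SVD alternations.
#' @slot seed master seed.
#' @slot inDir,outDir optional image input / report output directories.
#' @export
setClass("PipelineConfig",
  representation(nBenign = "integer", nMalignant = "integer",
                 imageSide = "integer", contrast = "numeric",
                 speckleSigma = "numeric", gammaC = "numeric",
                 gammaR = "numeric", smoothSigma = "numeric",
                 gridStep = "integer", vocabM = "integer",
                 layersN = "integer", topicsK = "integer",
                 ldaIters = "integer", gamma = "numeric", sizes = "numeric",
                 pooling = "character", folds = "integer",
                 repeats = "integer", ksvdIters = "integer",
                 seed = "integer", inDir = "character",
                 outDir = "character"))

configDefaults <- function() {
  list(nBenign = 20L, nMalignant = 20L, imageSide = 128L, contrast = 0.45,
       speckleSigma = 0.12, gammaC = 1, gammaR = 1.5, smoothSigma = 1,
       gridStep = 8L, vocabM = 200L, layersN = 4L, topicsK = 80L,
       ldaIters = 200L, gamma = 0.1, sizes = c(50, 100, 200),
       pooling = "avg", folds = 10L, repeats = 1L, ksvdIters = 20L,
       seed = 1L, inDir = NA_character_, outDir = NA_character_)
}

#' Validate a raw configuration document
#'
#' Fills defaults, coerces types, parses comma-separated dictionary sizes,
#' and rejects unknown keys and out-of-range values, naming the offending
#' key.
#'
#' @param raw named list (possibly empty) of configuration overrides.
#' @return A [PipelineConfig-class].
#' @export
validateConfig <- function(raw = list()) {
  def <- configDefaults()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, raw)
  if (is.character(cfg$sizes))
    cfg$sizes <- as.numeric(strsplit(cfg$sizes, ",")[[1]])
  ints <- c("nBenign", "nMalignant", "imageSide", "gridStep", "vocabM",
            "layersN", "topicsK", "ldaIters", "folds", "repeats",
            "ksvdIters", "seed")
  for (k in ints) cfg[[k]] <- as.integer(cfg[[k]])
  check <- function(ok, key, why)
    if (!ok) stop("invalid value for '", key, "': ", why)
  check(cfg$layersN >= 1L, "layersN", "need at least one layer")
  check(cfg$vocabM >= 2L, "vocabM", "vocabulary needs >= 2 words")
  check(cfg$topicsK >= 2L, "topicsK", "need >= 2 topics")
  check(cfg$folds >= 2L, "folds", "need >= 2 folds")
  check(cfg$repeats >= 1L, "repeats", "need >= 1 repeat")
  check(cfg$gamma > 0, "gamma", "regularisation weight must be positive")
  check(cfg$contrast > 0 && cfg$contrast < 1, "contrast", "must be in (0,1)")
  check(cfg$gridStep >= 4L, "gridStep", "grid step must be >= 4")
  check(all(cfg$sizes >= 2) && !any(duplicated(cfg$sizes)), "sizes",
        "dictionary sizes must be distinct and >= 2")
  check(cfg$pooling %in% c("avg", "max"), "pooling", "must be avg or max")
  do.call(new, c(list("PipelineConfig"), cfg))
}

#' Fingerprint of a configuration
#'
#' @param config a [PipelineConfig-class].
#' @return 8-hex-digit hash string.
#' @export
configHash <- function(config) {
  sl <- slotNames(config)
  fnvHash(lapply(sl[order(sl)], function(s) slot(config, s)))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig", configHash(object), ": M =", object@vocabM,
      ", N =", object@layersN, ", K =", object@topicsK,
      ", sizes =", paste(object@sizes, collapse = ","),
      ", pooling =", object@pooling, ",", object@folds, "folds\n")
})

runStage <- function(name, timings, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(result = res, timings = timings)
}

# Turn one image's zoned histograms into a bag: the whole-image document
# plus one document per concentric zone, each LDA-transformed separately.
imageDocs <- function(z) {
  rbind(z@histWhole, z@histZones)
}

#' Run the full image-classification pipeline
#'
#' Simulates (or reads) ROI images, enhances them, extracts dense
#' descriptors, and evaluates by stratified cross-validation in which the
#' codebook, topic model, dictionaries and classifiers are all fitted inside
#' each training fold only. Each image becomes a bag whose instances are the
#' topic vectors of its whole-image document and its concentric-zone
#' documents. Deterministic for a fixed configuration.
#'
#' @param config a [PipelineConfig-class] (see [validateConfig()]).
#' @return a run report: list with `configHash`, `config`, `timings`,
#'   `counts`, `metrics` (SE/SP/ACC in percent), `auc`, `roc`, and the
#'   per-image predictions.
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  timings <- list()
  hash <- configHash(config)

  if (is.na(config@inDir)) {
    st <- runStage("simulate", timings, {
      params <- phantomParams(imageSide = config@imageSide,
                              contrast = config@contrast,
                              speckleSigma = config@speckleSigma)
      makePhantomDataset(config@nBenign, config@nMalignant, params,
                         seed = config@seed)
    })
    timings <- st$timings
    images <- st$result$images
    labels <- st$result$labels
  } else {
    st <- runStage("enhance", timings, {
      if (!dir.exists(config@inDir))
        stop("input directory not found: ", config@inDir)
      files <- list.files(config@inDir, pattern = "\\.(png|tiff?)$",
                          full.names = TRUE)
      if (!length(files)) stop("no images in ", config@inDir)
      lab <- ifelse(grepl("malignant", basename(files)), 1L, 0L)
      list(images = lapply(files, readGrayImage), labels = lab)
    })
    timings <- st$timings
    images <- st$result$images
    labels <- st$result$labels
  }

  st <- runStage("enhance", timings, {
    lapply(images, function(img) {
      roi <- ROIPatch(resizeMaxSide(img))
      enhanceROI(roi, gammaC = config@gammaC, gammaR = config@gammaR,
                 smoothSigma = config@smoothSigma)
    })
  })
  timings <- st$timings
  enhanced <- st$result

  st <- runStage("features", timings, {
    lapply(enhanced, extractDescriptors, gridStep = config@gridStep)
  })
  timings <- st$timings
  descs <- st$result

  st <- runStage("evaluate", timings, {
    evaluateImageCV(enhanced, descs, labels, config)
  })
  timings <- st$timings
  ev <- st$result

  report <- list(configHash = hash,
                 config = sapply(slotNames(config), slot, object = config,
                                 simplify = FALSE),
                 timings = timings,
                 counts = ev$counts, metrics = ev$metrics, auc = ev$auc,
                 roc = ev$roc, pred = ev$pred, scores = ev$scores,
                 truth = labels)
  if (!is.na(config@outDir)) {
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      report[c("configHash", "config", "timings", "counts", "metrics",
               "auc")],
      file.path(config@outDir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Cross-validated evaluation of the image pipeline; all models are fitted
# on training folds only.
evaluateImageCV <- function(enhanced, descs, labels, config) {
  nImg <- length(enhanced)
  k <- min(config@folds, min(table(labels)))
  folds <- withSeed(config@seed, stratifiedFolds(labels, k))
  pred <- integer(nImg)
  score <- numeric(nImg)
  foldSeeds <- deriveSeeds(config@seed + 1L, k)

  for (f in seq_len(k)) {
    trainIdx <- which(folds != f)
    testIdx <- which(folds == f)
    pooled <- do.call(rbind, lapply(descs[trainIdx], `[[`, "vectors"))
    keepRows <- which(rowSums(abs(pooled)) > 0)
    if (length(keepRows) > 20000)
      keepRows <- withSeed(foldSeeds[f], sample(keepRows, 20000))
    cb <- buildCodebook(pooled[keepRows, , drop = FALSE], config@vocabM,
                        seed = foldSeeds[f])

    docsPerImage <- lapply(seq_len(nImg), function(i) {
      part <- assignZones(dim(enhanced[[i]]), config@layersN)
      imageDocs(zonedBoW(descs[[i]], cb, part))
    })
    corpus <- do.call(rbind, docsPerImage[trainIdx])
    tm <- ldaFit(corpus, K = config@topicsK, iters = config@ldaIters,
                 seed = foldSeeds[f])
    bags <- lapply(seq_len(nImg), function(i) {
      theta <- t(apply(docsPerImage[[i]], 1, function(doc)
        ldaTransform(tm, doc, iters = 100, burnin = 50,
                     seed = foldSeeds[f])))
      Bag(theta, labels[i], sprintf("img%03d", i))
    })
    model <- trainEnsemble(bags[trainIdx], config@sizes, config@gamma,
                           config@pooling, seed = foldSeeds[f],
                           ksvdIters = config@ksvdIters)
    out <- ensemblePredict(model, bags[testIdx])
    pred[testIdx] <- out$labels
    score[testIdx] <- out$scores
  }

  counts <- confusionCounts(pred, labels)
  roc <- tryCatch(rocAUC(score, labels), error = function(e) NULL)
  list(counts = counts, metrics = confusionMetrics(counts),
       auc = if (is.null(roc)) NA_real_ else auc(roc),
       roc = if (is.null(roc)) NULL else
         list(fpr = roc@fpr, tpr = roc@tpr),
       pred = pred, scores = score)
}
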