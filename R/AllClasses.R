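#' Square ROI crop around a suspected mass
#'
#' Holds a square grayscale crop together with the geometry the enhancement
#' operators need: the crop side, the ROI centre (the geometric centre of the
#' crop) and the estimated mass radius in pixels.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\], square.
#' @slot centerRow,centerCol centre pixel coordinates (1-based).
#' @slot radiusR estimated mass radius in pixels; 0 < radiusR < side/2.
#' @slot side crop side length in pixels.
#' @export
setClass("ROIPatch",
  representation(pixels = "matrix", centerRow = "numeric",
                 centerCol = "numeric", radiusR = "numeric", side = "numeric"),
  validity = function(object) {
    msg <- character(0)
    p <- object@pixels
    if (nrow(p) != ncol(p)) msg <- c(msg, "ROI crop must be square")
    if (nrow(p) < 8) msg <- c(msg, "ROI side must be at least 8 pixels")
    if (!all(is.finite(p)) || min(p) < 0 || max(p) > 1)
      msg <- c(msg, "intensities must be finite and in [0, 1]")
    if (object@radiusR <= 0 || object@radiusR >= object@side / 2)
      msg <- c(msg, "radius must satisfy 0 < r < side/2")
    ctr <- floor(object@side / 2) + 1
    if (object@centerRow != ctr || object@centerCol != ctr)
      msg <- c(msg, "centre must be the geometric centre of the crop")
    if (length(msg)) msg else TRUE
  })

#' Construct an ROIPatch
#'
#' @param pixels square numeric matrix in \[0, 1\].
#' @param radiusR mass radius in pixels; when `NULL` it is estimated with
#'   [estimateRadius()].
#' @return An [ROIPatch-class] object.
#' @export
ROIPatch <- function(pixels, radiusR = NULL) {
  assertGrayImage(pixels)
  side <- nrow(pixels)
  if (is.null(radiusR)) radiusR <- estimateRadius(pixels)
  new("ROIPatch", pixels = pixels, centerRow = floor(side / 2) + 1,
      centerCol = floor(side / 2) + 1, radiusR = radiusR, side = side)
}

#' Visual-word codebook
#'
#' k-means centroids in descriptor space; rows are words.
#'
#' @slot words numeric matrix, one centroid per row.
#' @export
setClass("Codebook", representation(words = "matrix"),
  validity = function(object) {
    if (nrow(object@words) < 2) return("a codebook needs at least 2 words")
    if (!all(is.finite(object@words))) return("non-finite centroid entries")
    TRUE
  })

#' Concentric-circle partition of an image
#'
#' The image diagonal is divided into `nLayers` equal portions; each portion
#' length is a radius around the image centre, yielding a central disk and
#' `nLayers - 1` annuli that together cover every pixel.
#'
#' @slot nLayers number of zones.
#' @slot radii strictly increasing radii in pixels; the last equals half the
#'   image diagonal.
#' @slot center image centre (row, col).
#' @slot dim image dimensions (height, width).
#' @export
setClass("ConcentricPartition",
  representation(nLayers = "integer", radii = "numeric",
                 center = "numeric", dim = "integer"),
  validity = function(object) {
    if (object@nLayers < 1L) return("need at least one layer")
    if (length(object@radii) != object@nLayers) return("radii/layer mismatch")
    if (any(diff(object@radii) <= 0)) return("radii must strictly increase")
    d <- sqrt(sum(object@dim^2)) / 2
    if (abs(object@radii[object@nLayers] - d) > 1e-9)
      return("last radius must equal half the image diagonal")
    TRUE
  })

#' Zoned bag-of-words histograms
#'
#' Word counts for the whole image (`histWhole`) and for each concentric
#' zone (`histZones`, one row per zone); the per-zone rows sum elementwise to
#' the whole-image histogram.
#'
#' @slot histWhole length-M count vector for the whole image.
#' @slot histZones nLayers x M count matrix.
#' @slot weights per-block weights, length nLayers + 1 (whole image first).
#' @export
setClass("ZonedBoW",
  representation(histWhole = "numeric", histZones = "matrix",
                 weights = "numeric"),
  validity = function(object) {
    if (nrow(object@histZones) > 0L &&
        ncol(object@histZones) != length(object@histWhole))
      return("zone histograms must match vocabulary size")
    if (length(object@weights) != nrow(object@histZones) + 1L)
      return("need one weight per block (whole image + zones)")
    if (nrow(object@histZones) > 0L &&
        max(abs(colSums(object@histZones) - object@histWhole)) > 1e-9)
      return("zone histograms must sum to the whole-image histogram")
    TRUE
  })

#' Latent Dirichlet allocation topic model
#'
#' @slot nTopics number of topics K.
#' @slot alpha symmetric Dirichlet document-topic concentration.
#' @slot beta topic-word smoothing.
#' @slot topicWord K x M matrix; rows are word distributions and sum to 1.
#' @slot docTopic training-document topic proportions (documents x K).
#' @slot loglik joint log-likelihood trace over Gibbs sweeps.
#' @export
setClass("TopicModel",
  representation(nTopics = "integer", alpha = "numeric", beta = "numeric",
                 topicWord = "matrix", docTopic = "matrix",
                 loglik = "numeric"),
  validity = function(object) {
    if (nrow(object@topicWord) != object@nTopics)
      return("topicWord must have one row per topic")
    if (max(abs(rowSums(object@topicWord) - 1)) > 1e-9)
      return("each topic's word distribution must sum to 1")
    TRUE
  })

#' Sparse-coding dictionary
#'
#' @slot atoms k x s matrix; columns are unit-norm basis vectors.
#' @export
setClass("Dictionary", representation(atoms = "matrix"),
  validity = function(object) {
    if (ncol(object@atoms) < 2) return("dictionary needs at least 2 atoms")
    nrm <- sqrt(colSums(object@atoms^2))
    if (max(abs(nrm - 1)) > 1e-6) return("atoms must have unit L2 norm")
    TRUE
  })

#' A labelled bag of instances
#'
#' @slot instances numeric matrix, one instance per row.
#' @slot label 0 (benign) or 1 (malignant).
#' @slot bagId identifier.
#' @export
setClass("Bag",
  representation(instances = "matrix", label = "integer", bagId = "character"),
  validity = function(object) {
    if (nrow(object@instances) < 1) return("a bag needs at least one instance")
    if (!object@label %in% c(0L, 1L)) return("label must be 0 or 1")
    if (!all(is.finite(object@instances))) return("non-finite instance values")
    TRUE
  })

#' Construct a Bag
#' @param instances matrix with one instance per row (or a single vector).
#' @param label 0 = benign, 1 = malignant.
#' @param bagId identifier string.
#' @return A [Bag-class] object.
#' @export
Bag <- function(instances, label, bagId = "bag") {
  if (!is.matrix(instances)) instances <- matrix(instances, nrow = 1)
  new("Bag", instances = instances, label = as.integer(label),
      bagId = as.character(bagId))
}

#' Relevance vector machine model
#'
#' Sparse-Bayesian kernel logistic classifier: an RBF kernel expansion whose
#' weights carry independent Gaussian priors with per-weight precisions
#' re-estimated by evidence maximisation; weights whose precision diverges
#' are pruned, leaving the relevance vectors.
#'
#' @slot relevanceVectors rows of the training matrix that survived pruning.
#' @slot weights coefficients for the surviving kernel columns.
#' @slot bias intercept (0 when the bias was pruned).
#' @slot hasBias whether the intercept survived pruning.
#' @slot kernelWidth RBF width.
#' @slot alphaPrior surviving per-weight precisions.
#' @slot rvIndex indices of the relevance vectors in the training set.
#' @export
setClass("RVMModel",
  representation(relevanceVectors = "matrix", weights = "numeric",
                 bias = "numeric", hasBias = "logical",
                 kernelWidth = "numeric", alphaPrior = "numeric",
                 rvIndex = "integer"))

#' Ensemble of RVM classifiers over dictionary sizes
#'
#' One (dictionary, RVM) member per dictionary size; labels are combined by
#' majority vote (ties toward malignant) and scores by the mean posterior.
#'
#' @slot members list of member fits (dictionary, model, size).
#' @slot sizes dictionary sizes, aligned with members.
#' @slot gamma l1 regularisation weight used for sparse coding.
#' @slot pooling "avg" or "max".
#' @export
setClass("EnsembleModel",
  representation(members = "list", sizes = "numeric", gamma = "numeric",
                 pooling = "character"),
  validity = function(object) {
    if (length(object@members) < 1) return("ensemble needs >= 1 member")
    if (length(object@members) != length(object@sizes))
      return("members and sizes must align")
    TRUE
  })

#' ROC curve from a threshold sweep
#'
#' @slot thresholds decision thresholds (decreasing).
#' @slot fpr,tpr operating points.
#' @slot auc area under the curve (trapezoid; equals the rank statistic).
#' @export
setClass("ROCCurve",
  representation(thresholds = "numeric", fpr = "numeric", tpr = "numeric",
                 auc = "numeric"),
  validity = function(object) {
    if (object@auc < 0 || object@auc > 1) return("AUC must lie in [0, 1]")
    if (any(diff(object@fpr) < -1e-12) || any(diff(object@tpr) < -1e-12))
      return("sorted operating points must be monotone")
    TRUE
  })

setMethod("show", "ROIPatch", function(object) {
  cat("ROIPatch:", object@side, "x", object@side,
      "crop, estimated radius", round(object@radiusR, 2), "px\n")
})
setMethod("show", "Codebook", function(object) {
  cat("Codebook:", nrow(object@words), "visual words of dimension",
      ncol(object@words), "\n")
})
setMethod("show", "ConcentricPartition", function(object) {
  cat("ConcentricPartition:", object@nLayers, "zones on a",
      paste(object@dim, collapse = "x"), "image; radii",
      paste(round(object@radii, 2), collapse = ", "), "\n")
})
setMethod("show", "TopicModel", function(object) {
  cat("TopicModel:", object@nTopics, "topics over",
      ncol(object@topicWord), "words (alpha =", object@alpha, ")\n")
})
setMethod("show", "Dictionary", function(object) {
  cat("Dictionary:", ncol(object@atoms), "unit-norm atoms of dimension",
      nrow(object@atoms), "\n")
})
setMethod("show", "Bag", function(object) {
  cat("Bag", object@bagId, ":", nrow(object@instances),
      "instances of dimension", ncol(object@instances),
      "; label =", object@label, "\n")
})
setMethod("show", "RVMModel", function(object) {
  cat("RVMModel:", length(object@weights), "relevance vectors, RBF width",
      signif(object@kernelWidth, 4), "\n")
})
setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel:", length(object@members),
      "RVM members, dictionary sizes",
      paste(object@sizes, collapse = ", "), "\n")
})
setMethod("show", "ROCCurve", function(object) {
  cat("ROCCurve:", length(object@fpr), "operating points, AUC =",
      round(object@auc, 4), "\n")
})

#' @describeIn Dictionary-class dictionary atom matrix (k x s).
#' @param object a Dictionary.
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
setMethod("atoms", "Dictionary", function(object) object@atoms)

#' @describeIn Dictionary-class number of atoms s.
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))
setMethod("nAtoms", "Dictionary", function(object) ncol(object@atoms))

#' @describeIn Codebook-class centroid matrix (M x d).
#' @param object a Codebook.
#' @export
setGeneric("codewords", function(object) standardGeneric("codewords"))
setMethod("codewords", "Codebook", function(object) object@words)

#' @describeIn Bag-class instance matrix (one row per instance).
#' @param object a Bag.
#' @export
setGeneric("instances", function(object) standardGeneric("instances"))
setMethod("instances", "Bag", function(object) object@instances)

#' @describeIn Bag-class bag label (0 benign, 1 malignant).
#' @export
setGeneric("bagLabel", function(object) standardGeneric("bagLabel"))
setMethod("bagLabel", "Bag", function(object) object@label)

#' @describeIn ConcentricPartition-class zone radii in pixels.
#' @param object a ConcentricPartition.
#' @export
setGeneric("zoneRadii", function(object) standardGeneric("zoneRadii"))
setMethod("zoneRadii", "ConcentricPartition", function(object) object@radii)

#' @describeIn TopicModel-class topic-word matrix (K x M).
#' @param object a TopicModel.
#' @export
setGeneric("topicWord", function(object) standardGeneric("topicWord"))
setMethod("topicWord", "TopicModel", function(object) object@topicWord)

#' @describeIn ROCCurve-class area under the curve.
#' @param object an ROCCurve.
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
setMethod("auc", "ROCCurve", function(object) object@auc)
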