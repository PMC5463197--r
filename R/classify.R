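#' Confusion counts from predicted and true labels
#'
#' Malignant (1) is the positive class: TP counts correctly classified
#' malignant cases, TN correctly classified benign ones.
#'
#' @param pred predicted labels in \{0, 1\}.
#' @param truth true labels in \{0, 1\}.
#' @return list with integer TP, FN, TN, FP.
#' @export
confusionCounts <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) stop("length mismatch")
  list(TP = sum(pred == 1L & truth == 1L),
       FN = sum(pred == 0L & truth == 1L),
       TN = sum(pred == 0L & truth == 0L),
       FP = sum(pred == 1L & truth == 0L))
}

#' Sensitivity, specificity and accuracy (percent)
#'
#' SE = TP / (TP + FN), SP = TN / (TN + FP),
#' ACC = (TP + TN) / (TP + TN + FP + FN), each as a percentage. A metric
#' whose denominator is empty is returned as NA.
#'
#' @param counts list with TP, FN, TN, FP (from [confusionCounts()]).
#' @return list with SE, SP, ACC in percent.
#' @export
confusionMetrics <- function(counts) {
  with(counts, {
    tot <- TP + TN + FP + FN
    list(SE = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
         SP = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_,
         ACC = if (tot > 0) 100 * (TP + TN) / tot else NA_real_)
  })
}

#' ROC curve and AUC from scores
#'
#' Threshold sweep over the unique scores (plus sentinels); AUC by the
#' trapezoid rule, which with tied scores handled as diagonal segments
#' equals the rank-average Mann-Whitney statistic.
#'
#' @param scores classifier scores, larger = more malignant.
#' @param labels true labels in \{0, 1\}; both classes required.
#' @return An [ROCCurve-class].
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / nPos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nNeg,
                numeric(1))
  a <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("ROCCurve", thresholds = thr, fpr = fpr, tpr = tpr, auc = a)
}

# Majority vote over member labels (one column per member); exact ties go
# to the positive (malignant) class, the clinically conservative choice.
voteLabels <- function(memberLabels) {
  as.integer(rowMeans(memberLabels) >= 0.5)
}

# Stratified fold assignment: within each class, shuffled ids are dealt
# cyclically over the k folds.
stratifiedFolds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Train an ensemble of RVM classifiers over dictionary sizes
#'
#' For every size in `sizes`: learn a dictionary from the pooled training
#' instances by K-SVD, embed the training bags as pooled sparse codes, and
#' train an RVM on the embedded features. Seeds for the members are derived
#' from the master seed, so the fit is deterministic.
#'
#' @param bags list of training [Bag-class] objects.
#' @param sizes dictionary sizes (distinct, each >= 2).
#' @param gamma l1 weight for sparse coding.
#' @param pool pooling mode, "avg" or "max".
#' @param seed master seed.
#' @param ksvdIters K-SVD alternations per member.
#' @return An [EnsembleModel-class].
#' @export
trainEnsemble <- function(bags, sizes, gamma = 0.1, pool = c("avg", "max"),
                          seed = 1L, ksvdIters = 20L) {
  pool <- match.arg(pool)
  if (any(duplicated(sizes)) || any(sizes < 2))
    stop("dictionary sizes must be distinct and >= 2")
  labels <- vapply(bags, bagLabel, integer(1))
  if (length(unique(labels)) < 2) stop("training bags contain a single class")
  Xall <- t(do.call(rbind, lapply(bags, instances)))
  if (ncol(Xall) < max(sizes))
    stop("dictionary size ", max(sizes), " exceeds the ",
         ncol(Xall), " training instances")
  seeds <- deriveSeeds(seed, length(sizes))
  members <- lapply(seq_along(sizes), function(i) {
    s <- sizes[i]
    D <- tryCatch(ksvdLearn(Xall, s, gamma, iters = ksvdIters,
                            seed = seeds[i]),
                  error = function(e)
                    stop("ensemble member with dictionary size ", s,
                         " failed: ", conditionMessage(e)))
    emb <- embedBags(bags, D, gamma, pool)
    model <- rvmTrain(emb$features, emb$labels)
    list(dictionary = D, model = model, size = s)
  })
  new("EnsembleModel", members = members, sizes = as.numeric(sizes),
      gamma = gamma, pooling = pool)
}

#' Ensemble prediction for bags
#'
#' Each member embeds the bags with its own dictionary and scores them with
#' its RVM. Labels are the majority vote over members with ties resolved
#' toward malignant; the score is the mean member posterior.
#'
#' @param model an [EnsembleModel-class].
#' @param bags list of [Bag-class] objects.
#' @return list with `labels`, `scores`, and per-member matrices
#'   `memberProbs`, `memberLabels`.
#' @export
ensemblePredict <- function(model, bags) {
  probs <- vapply(model@members, function(mb) {
    emb <- embedBags(bags, mb$dictionary, model@gamma, model@pooling)
    rvmPredict(mb$model, emb$features)$prob
  }, numeric(length(bags)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = length(bags))
  memberLabels <- (probs >= 0.5) * 1L
  labels <- voteLabels(memberLabels)
  list(labels = labels, scores = rowMeans(probs),
       memberProbs = probs, memberLabels = memberLabels)
}

#' Repeated stratified k-fold cross-validation of the bag pipeline
#'
#' Within every training fold only: K-SVD dictionary learning on the pooled
#' training instances, bag embedding, and RVM training (one model per
#' dictionary size, combined as an ensemble when several sizes are given).
#' Test-fold bags are embedded with the training-fold dictionaries and
#' scored; per-repeat SE/SP/ACC/AUC are computed from the pooled test
#' predictions.
#'
#' @param bags list of [Bag-class] objects.
#' @param sizes dictionary size(s).
#' @param gamma l1 weight.
#' @param pool pooling mode.
#' @param k number of folds; default 10.
#' @param repeats independent repetitions; default 1.
#' @param seed master seed (drives fold assignment and member seeds).
#' @param ksvdIters K-SVD alternations per member.
#' @return list with `perRepeat` (data.frame of SE/SP/ACC/AUC), `mean`,
#'   `sd`, and the last repeat's pooled `scores`/`labels`/`truth`.
#' @export
kfoldCV <- function(bags, sizes = 32, gamma = 0.1, pool = c("avg", "max"),
                    k = 10, repeats = 1, seed = 1L, ksvdIters = 20L) {
  pool <- match.arg(pool)
  labels <- vapply(bags, bagLabel, integer(1))
  if (k < 2) stop("k must be at least 2")
  if (min(table(labels)) < k)
    k <- max(2L, min(table(labels)))  # re-stratify with fewer folds
  repSeeds <- deriveSeeds(seed, repeats)
  per <- vector("list", repeats)
  lastScores <- NULL; lastPred <- NULL
  for (rep in seq_len(repeats)) {
    folds <- withSeed(repSeeds[rep], stratifiedFolds(labels, k))
    pred <- integer(length(bags))
    score <- numeric(length(bags))
    for (f in seq_len(k)) {
      trainIdx <- which(folds != f)
      testIdx <- which(folds == f)
      if (!length(testIdx)) next
      model <- trainEnsemble(bags[trainIdx], sizes, gamma, pool,
                             seed = repSeeds[rep] %% 1000003L + f,
                             ksvdIters = ksvdIters)
      out <- ensemblePredict(model, bags[testIdx])
      pred[testIdx] <- out$labels
      score[testIdx] <- out$scores
    }
    met <- confusionMetrics(confusionCounts(pred, labels))
    aucv <- tryCatch(auc(rocAUC(score, labels)), error = function(e) NA_real_)
    per[[rep]] <- data.frame(repeat_ = rep, SE = met$SE, SP = met$SP,
                             ACC = met$ACC, AUC = 100 * aucv)
    lastScores <- score; lastPred <- pred
  }
  perRepeat <- do.call(rbind, per)
  list(perRepeat = perRepeat,
       mean = colMeans(perRepeat[, c("SE", "SP", "ACC", "AUC")]),
       sd = apply(perRepeat[, c("SE", "SP", "ACC", "AUC"), drop = FALSE],
                  2, sd),
       scores = lastScores, pred = lastPred, truth = labels)
}
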