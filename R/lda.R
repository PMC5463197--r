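#' Dirichlet probability density
#'
#' Density of Dir(alpha) at a point theta of the open simplex, computed in
#' log space: Gamma(sum alpha) / prod Gamma(alpha_k) * prod theta_k^(alpha_k - 1).
#'
#' @param theta point on the simplex (non-negative, sums to 1 within 1e-9).
#' @param alpha concentration vector, all entries > 0.
#' @return density value.
#' @export
dirichletPDF <- function(theta, alpha) {
  if (length(theta) != length(alpha)) stop("theta and alpha lengths differ")
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (any(theta <= 0) || abs(sum(theta) - 1) > 1e-9)
    stop("theta must lie on the open simplex (sum 1 within 1e-9)")
  exp(lgamma(sum(alpha)) - sum(lgamma(alpha)) +
        sum((alpha - 1) * log(theta)))
}

# Expand a count vector into 0-based word-id tokens for the Gibbs sampler.
countsToTokens <- function(counts) {
  counts <- round(counts)
  as.integer(rep(seq_along(counts) - 1L, times = counts))
}

#' Fit a topic model by collapsed Gibbs sampling
#'
#' Latent Dirichlet allocation over a corpus of word-count vectors (one
#' document per image block). Token-topic assignments are resampled from
#' their collapsed conditionals; the joint log-likelihood is recorded every
#' sweep. Deterministic given the seed.
#'
#' @param corpus matrix (documents x M) or list of length-M count vectors.
#' @param K number of topics; default 80.
#' @param alpha symmetric document-topic concentration; default 50 / K.
#' @param beta topic-word smoothing; default 0.01.
#' @param iters Gibbs sweeps; default 500.
#' @param seed RNG seed.
#' @return A [TopicModel-class].
#' @export
ldaFit <- function(corpus, K = 80, alpha = 50 / K, beta = 0.01,
                   iters = 500, seed = 1L) {
  if (is.matrix(corpus)) corpus <- asplit(corpus, 1)
  if (!length(corpus)) stop("empty corpus")
  if (K < 2) stop("K must be at least 2")
  M <- length(corpus[[1]])
  docs <- lapply(corpus, countsToTokens)
  fit <- withSeed(seed,
                  .lda_gibbs_fit(docs, as.integer(M), as.integer(K),
                                 alpha, beta, as.integer(iters)))
  new("TopicModel", nTopics = as.integer(K), alpha = alpha, beta = beta,
      topicWord = fit$topic_word, docTopic = fit$doc_topic,
      loglik = as.numeric(fit$loglik))
}

#' Infer topic proportions for a new document
#'
#' Fold-in Gibbs sampling with the trained topic-word distributions held
#' fixed; theta is the average of the post-burn-in smoothed topic counts.
#' An all-zero document returns the uniform prior mean.
#'
#' @param model a [TopicModel-class].
#' @param doc length-M count vector.
#' @param iters,burnin fold-in sweeps and burn-in.
#' @param seed RNG seed.
#' @return length-K topic proportion vector (sums to 1).
#' @export
ldaTransform <- function(model, doc, iters = 200, burnin = 100, seed = 1L) {
  if (length(doc) != ncol(model@topicWord))
    stop("document length must equal the vocabulary size")
  tokens <- countsToTokens(doc)
  if (!length(tokens)) return(rep(1 / model@nTopics, model@nTopics))
  withSeed(seed,
           as.numeric(.lda_gibbs_transform(tokens, model@topicWord,
                                           model@alpha, as.integer(iters),
                                           as.integer(burnin))))
}
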