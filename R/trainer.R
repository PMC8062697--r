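# VERSE-style embedding trainer: noise-contrastive estimation against the
# truncated RWR similarity.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration for the NCE embedding learner
#'
#' Collects the trainer hyper-parameters with size-dependent defaults:
#' `s` (negatives per positive) is 10 for networks with more than 5000 nodes
#' and 3 otherwise; the truncation size `nMax` is 300 for more than 5000
#' nodes and `ceiling(0.15 * nTotal)` otherwise. The NCE logit biases are
#' `biasPos = log(nMax)` and `biasNeg = log(nMax / s)`, the partition-function
#' correction for a noise distribution matched to the truncated support size.
#'
#' @param nTotal number of embedded nodes (`n`, or `n + m` for heterogeneous
#'   networks).
#' @param d embedding dimension; default 128.
#' @param s negative samples per positive; default by network size.
#' @param nMax truncation size for [truncateSimilarity()]; default by size.
#' @param lr learning rate (constant); default 0.0025.
#' @param totalSteps number of positive-sample updates; default
#'   `1000 * nTotal`, the plateau of the probe loss on desk-scale networks.
#' @param seed RNG seed controlling initialization and sampling.
#' @param workers group size for the grouped ("parallel") update schedule.
#' @return a list of class `"trainConfig"` (includes `biasPos`, `biasNeg`).
#' @export
trainConfig <- function(nTotal, d = 128L, s = NULL, nMax = NULL, lr = 0.0025,
                        totalSteps = NULL, seed = 1L, workers = 100L) {
  stopifnot(nTotal >= 1, d >= 1, lr > 0)
  if (is.null(s)) s <- if (nTotal > 5000) 10L else 3L
  if (is.null(nMax)) nMax <- if (nTotal > 5000) 300L else ceiling(0.15 * nTotal)
  if (is.null(totalSteps)) totalSteps <- 1000L * as.integer(nTotal)
  stopifnot(s >= 1, nMax >= 1, totalSteps >= 1)
  structure(list(nTotal = as.integer(nTotal), d = as.integer(d),
                 s = as.integer(s), nMax = as.integer(nMax), lr = lr,
                 totalSteps = as.integer(totalSteps), seed = as.integer(seed),
                 workers = as.integer(workers),
                 biasPos = log(nMax), biasNeg = log(nMax / s)),
            class = "trainConfig")
}

#' Random embedding initialization
#'
#' Entries are i.i.d. uniform on `[-0.5/d, 0.5/d]`, the usual small-scale
#' word2vec-style start.
#'
#' @param nTotal,d matrix dimensions.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return an `nTotal x d` numeric matrix.
#' @export
initEmbeddings <- function(nTotal, d, seed = NULL) {
  stopifnot(nTotal >= 1, d >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(nTotal * d, -0.5 / d, 0.5 / d), nTotal, d)
}

#' Sample positive context nodes from a truncated similarity
#'
#' Draws from the renormalized truncated distribution of node `u` (the seed
#' itself is excluded from its own support by [truncateSimilarity()]).
#'
#' @param trunc a `"truncatedSimilarity"` object.
#' @param u seed node index.
#' @param size number of draws.
#' @return integer node indices of length `size`; length 0 if `u` has empty
#'   support (fully isolated node).
#' @export
samplePositive <- function(trunc, u, size = 1L) {
  sup <- trunc$support[[u]]
  if (!length(sup)) return(integer(0))
  cp <- trunc$cumprob[[u]]
  sup[findInterval(stats::runif(size), cp) + 1L]
}

#' Sample negative (noise) nodes
#'
#' Draws `s` i.i.d. nodes (with replacement) from the uniform noise
#' distribution over all embedded nodes excluding the anchor `u`.
#'
#' @param nTotal number of embedded nodes.
#' @param u anchor node index (never returned).
#' @param s number of draws.
#' @return integer vector of length `s`, all different from `u`.
#' @export
sampleNegatives <- function(nTotal, u, s) {
  stopifnot(nTotal >= 2, s >= 1)
  k <- sample.int(nTotal - 1L, s, replace = TRUE)
  k + (k >= u)
}

#' One noise-contrastive estimation update
#'
#' Computes the unnormalized logit `g = w_u . w_v - bias`, the gradient
#' coefficient `c = label - sigmoid(g)`, and moves both rows along each
#' other: `w_u <- w_u + lr * c * w_v`, `w_v <- w_v + lr * c * w_u_old`.
#' A positive update (`label = 1`) increases the dot product, a negative one
#' decreases it.
#'
#' @param W embedding matrix.
#' @param u,v distinct row indices.
#' @param label 1 for a positive (similarity) sample, 0 for a noise sample.
#' @param lr learning rate.
#' @param bias logit bias (`biasPos` or `biasNeg` from [trainConfig()]).
#' @return the updated matrix `W`.
#' @examples
#' W <- rbind(c(1, 0), c(1, 0))
#' nceUpdate(W, 1, 2, label = 1, lr = 0.1, bias = 0)[1, 1]   # 1.02689...
#' @export
nceUpdate <- function(W, u, v, label, lr, bias) {
  stopifnot(u != v, label %in% c(0, 1))
  wu <- W[u, ]; wv <- W[v, ]
  g <- sum(wu * wv) - bias
  cc <- label - .sigmoid(g)
  W[u, ] <- wu + lr * cc * wv
  W[v, ] <- wv + lr * cc * wu
  W
}

#' Learn node embeddings by noise-contrastive estimation
#'
#' Runs `totalSteps` stochastic updates. Each step draws an anchor `u`
#' uniformly over nodes, one positive context `v` from `u`'s truncated
#' similarity, applies a positive [nceUpdate()], then draws `s` uniform
#' negatives and applies a negative update for each. Anchors with empty
#' support (fully isolated nodes) are skipped.
#'
#' Serial mode (`parallel = FALSE`, the reference semantics) is
#' bit-reproducible for a fixed `config$seed`. With `parallel = TRUE` the
#' steps are processed in synchronous groups of `config$workers`: every
#' update in a group is computed from the group-start snapshot of `W` and the
#' increments are then summed, emulating concurrent workers; the schedule
#' changes the arithmetic but not the quality of the embedding.
#'
#' @param trunc a `"truncatedSimilarity"` covering all embedded nodes.
#' @param config a [trainConfig()] list.
#' @param init optional initial matrix (default: [initEmbeddings()] under
#'   `config$seed`).
#' @param parallel use the grouped update schedule (default `FALSE`).
#' @return the `nTotal x d` embedding matrix, with node labels as row names
#'   when the truncated similarity carries them.
#' @export
trainEmbeddings <- function(trunc, config, init = NULL, parallel = FALSE) {
  stopifnot(inherits(trunc, "truncatedSimilarity"), inherits(config, "trainConfig"))
  n <- config$nTotal
  if (length(trunc$support) != n)
    stop("truncated similarity does not cover the configured number of nodes")
  if (!any(lengths(trunc$support) > 0))
    stop("no trainable similarity: all nodes are isolated")
  set.seed(config$seed)
  W <- if (is.null(init)) initEmbeddings(n, config$d) else as.matrix(init)
  WT <- t(W)                               # d x n: contiguous column access
  lr <- config$lr; s <- config$s
  bp <- config$biasPos; bn <- config$biasNeg
  steps <- config$totalSteps
  us <- sample.int(n, steps, replace = TRUE)
  if (!parallel) {
    for (t in seq_len(steps)) {
      u <- us[t]
      sup <- trunc$support[[u]]
      if (!length(sup)) next
      v <- sup[findInterval(stats::runif(1), trunc$cumprob[[u]]) + 1L]
      wu <- WT[, u]; wv <- WT[, v]
      cc <- 1 - .sigmoid(sum(wu * wv) - bp)
      WT[, u] <- wu + lr * cc * wv
      WT[, v] <- wv + lr * cc * wu
      neg <- sample.int(n - 1L, s, replace = TRUE)
      neg <- neg + (neg >= u)
      for (j in neg) {
        wu <- WT[, u]; wj <- WT[, j]
        cc <- -.sigmoid(sum(wu * wj) - bn)
        WT[, u] <- wu + lr * cc * wj
        WT[, j] <- wj + lr * cc * wu
      }
    }
  } else {
    P <- max(1L, config$workers)
    for (g0 in seq(1L, steps, by = P)) {
      grp <- us[g0:min(g0 + P - 1L, steps)]
      snap <- WT
      delta <- matrix(0, nrow(WT), ncol(WT))
      for (u in grp) {
        sup <- trunc$support[[u]]
        if (!length(sup)) next
        v <- sup[findInterval(stats::runif(1), trunc$cumprob[[u]]) + 1L]
        wu <- snap[, u]; wv <- snap[, v]
        cc <- 1 - .sigmoid(sum(wu * wv) - bp)
        delta[, u] <- delta[, u] + lr * cc * wv
        delta[, v] <- delta[, v] + lr * cc * wu
        neg <- sample.int(n - 1L, s, replace = TRUE)
        neg <- neg + (neg >= u)
        for (j in neg) {
          wj <- snap[, j]
          cc <- -.sigmoid(sum(wu * wj) - bn)
          delta[, u] <- delta[, u] + lr * cc * wj
          delta[, j] <- delta[, j] + lr * cc * wu
        }
      }
      WT <- WT + delta
    }
  }
  W <- t(WT)
  if (!is.null(trunc$nodes) && trunc$nNodes == n) rownames(W) <- trunc$nodes
  W
}

#' Kullback-Leibler divergence between graph and embedding similarities
#'
#' Monitoring quantity: the sum over the given seeds of
#' `KL(sim(., v) || softmax(W w_v))`, where the embedding-space similarity is
#' the full softmax of the dot products of row `v` against all rows. Zero
#' probabilities contribute nothing (`0 * log 0 = 0`); the divergence is
#' always non-negative and zero iff the two distributions coincide.
#'
#' @param sim similarity matrix (nodes x seeds), columns summing to 1.
#' @param W embedding matrix (nodes x d).
#' @param nodes seed subset (column indices); default all.
#' @return a non-negative scalar.
#' @export
klDivergence <- function(sim, W, nodes = NULL) {
  sim <- as.matrix(sim); W <- as.matrix(W)
  if (is.null(nodes)) nodes <- seq_len(ncol(sim))
  stopifnot(length(nodes) >= 1)
  G <- W[nodes, , drop = FALSE] %*% t(W)       # logits: seeds x nodes
  mx <- apply(G, 1, max)
  logZ <- mx + log(rowSums(exp(G - mx)))
  logQ <- G - logZ
  total <- 0
  for (k in seq_along(nodes)) {
    p <- sim[, nodes[k]]
    pos <- p > 0
    total <- total + sum(p[pos] * (log(p[pos]) - logQ[k, pos]))
  }
  total
}

#' Deterministic NCE probe loss
#'
#' The expected negative log-likelihood of the NCE classifier, computed in
#' closed form (no sampling): for every seed `u` with nonempty truncated
#' support, the positive term averages `log sigmoid(w_u . w_v - biasPos)`
#' under the truncated distribution and the noise term takes `s` times the
#' uniform average of `log(1 - sigmoid(w_u . w_j - biasNeg))` over `j != u`.
#' Useful to verify that training reduces the objective.
#'
#' @param trunc a `"truncatedSimilarity"` object.
#' @param W embedding matrix.
#' @param config a [trainConfig()] (for `s` and the biases).
#' @param nodes seed subset; default all nodes with nonempty support.
#' @return mean loss per seed (positive scalar for untrained embeddings).
#' @export
nceProbeLoss <- function(trunc, W, config, nodes = NULL) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (is.null(nodes)) nodes <- which(lengths(trunc$support) > 0)
  nodes <- nodes[lengths(trunc$support[nodes]) > 0]
  stopifnot(length(nodes) >= 1)
  s <- config$s; bp <- config$biasPos; bn <- config$biasNeg
  loss <- 0
  G <- W[nodes, , drop = FALSE] %*% t(W)
  for (k in seq_along(nodes)) {
    u <- nodes[k]
    sup <- trunc$support[[u]]
    pos <- sum(trunc$prob[[u]] * log(.sigmoid(G[k, sup] - bp)))
    gneg <- G[k, -u] - bn
    negt <- s * mean(log1p(-.sigmoid(gneg)))
    loss <- loss - (pos + negt)
  }
  loss / length(nodes)
}

#' Full embedding pipeline
#'
#' Convenience wrapper chaining [rwrSimilarity()], [truncateSimilarity()] and
#' [trainEmbeddings()]: the standard route from a network to node embeddings.
#'
#' @param x a [MultiplexNetwork-class] or
#'   [MultiplexHeterogeneousNetwork-class] object.
#' @param params a [rwrParams()] list.
#' @param config a [trainConfig()]; default `trainConfig(nNodes(x), seed = seed)`.
#' @param seed seed used when `config` is built internally.
#' @param parallel passed to [trainEmbeddings()].
#' @return the embedding matrix with node labels as row names.
#' @examples
#' mux <- generateMultiplexSBM(sbmSpec(n = 30, L = 2, blocks = c(15, 15),
#'                                     pIn = 0.4, pOut = 0.05), seed = 1)$network
#' W <- embedNodes(mux, config = trainConfig(30, d = 8, totalSteps = 500))
#' dim(W)
#' @export
setGeneric("embedNodes", function(x, params = rwrParams(), config = NULL,
                                  seed = 1L, parallel = FALSE)
  standardGeneric("embedNodes"))

.embedNodesImpl <- function(x, params, config, seed, parallel) {
  if (is.null(config)) config <- trainConfig(nNodes(x), seed = seed)
  if (config$nTotal != nNodes(x))
    stop("config$nTotal does not match the number of nodes")
  sim <- rwrSimilarity(x, params)
  trunc <- truncateSimilarity(sim, config$nMax)
  trainEmbeddings(trunc, config, parallel = parallel)
}

#' @rdname embedNodes
setMethod("embedNodes", "MultiplexNetwork", .embedNodesImpl)

#' @rdname embedNodes
setMethod("embedNodes", "MultiplexHeterogeneousNetwork", .embedNodesImpl)
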