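# Evaluation protocols: connected edge splitting (Broder random spanning
# tree), negative-pair sampling, link prediction (logistic regressor,
# ROC-AUC), network reconstruction (random forest, precision@K) and
# bipartite link prediction for heterogeneous embeddings.

.edgePairs <- function(adj) {
  up <- .asDgc(Matrix::triu(adj))
  sm <- Matrix::summary(up)
  cbind(i = sm$i, j = sm$j)
}

.pairKey <- function(pairs, n) (pmin(pairs[, 1], pairs[, 2]) - 1) * n +
  pmax(pairs[, 1], pairs[, 2])

# Broder's random-walk spanning tree on one connected component: walk until
# all vertices are visited; the first-entry edges form a uniform random
# spanning tree.
.broderTree <- function(adjL, comp) {
  size <- length(comp)
  if (size <= 1L) return(matrix(integer(0), 0, 2))
  visited <- logical(length(adjL))
  cur <- comp[sample.int(size, 1L)]
  visited[cur] <- TRUE
  seen <- 1L
  tree <- matrix(0L, size - 1L, 2L)
  while (seen < size) {
    nb <- adjL[[cur]]
    nxt <- nb[sample.int(length(nb), 1L)]
    if (!visited[nxt]) {
      visited[nxt] <- TRUE
      seen <- seen + 1L
      tree[seen - 1L, ] <- c(cur, nxt)
    }
    cur <- nxt
  }
  tree
}

#' Connectivity-preserving train/test edge split
#'
#' Splits a layer's edges into a training set that spans every connected
#' component and a test set of removed edges. Per component, a uniform random
#' spanning tree is drawn with Broder's random-walk procedure; test edges are
#' then sampled uniformly from the non-tree edges, up to
#' `round(fraction * |E|)`. If fewer non-tree edges exist (e.g. the layer is
#' a tree) all of them are taken and a shortfall warning is emitted.
#'
#' @param adj symmetric adjacency matrix of one layer.
#' @param fraction fraction of edges to remove, in (0, 1); default 0.3.
#' @param seed optional RNG seed.
#' @return list with integer pair matrices `train` and `test` (columns
#'   `i < j`), partitioning the original edge set.
#' @export
splitEdgesConnected <- function(adj, fraction = 0.3, seed = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  adj <- .asDgc(adj)
  n <- ncol(adj)
  edges <- .edgePairs(adj)
  if (!nrow(edges)) stop("layer has no edges to split")
  ptr <- adj@p; idx <- adj@i + 1L
  adjL <- lapply(seq_len(n), function(jj)
    if (ptr[jj + 1L] > ptr[jj]) idx[(ptr[jj] + 1L):ptr[jj + 1L]] else integer(0))
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  comp <- igraph::components(g)
  treeEdges <- do.call(rbind, lapply(seq_len(comp$no), function(k)
    .broderTree(adjL, which(comp$membership == k))))
  treeKey <- if (length(treeEdges)) .pairKey(treeEdges, n) else numeric(0)
  key <- .pairKey(edges, n)
  candidates <- which(!(key %in% treeKey))
  nTest <- round(fraction * nrow(edges))
  if (length(candidates) < nTest) {
    warning(sprintf("only %d of %d requested removable edges available (spanning tree protects the rest)",
                    length(candidates), nTest))
    testIdx <- candidates
  } else {
    testIdx <- candidates[sample.int(length(candidates), nTest)]
  }
  list(train = edges[setdiff(seq_len(nrow(edges)), testIdx), , drop = FALSE],
       test = edges[testIdx, , drop = FALSE])
}

#' Sample non-edges of the layer union
#'
#' Uniform sample, without replacement, of unordered node pairs that are
#' absent from every layer of the multiplex (and are not self-pairs): the
#' negative examples fed to the link-prediction classifiers.
#'
#' @param mux a [MultiplexNetwork-class] object.
#' @param count number of pairs (must not exceed the number of absent pairs).
#' @param seed optional RNG seed.
#' @param exclude optional pair matrix whose pairs must not be drawn.
#' @return integer matrix with `count` rows (columns `i < j`).
#' @export
sampleNonEdges <- function(mux, count, seed = NULL, exclude = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nNodes(mux)
  un <- Reduce(`+`, mux@layers)
  exKey <- if (is.null(exclude) || !nrow(exclude)) numeric(0) else .pairKey(exclude, n)
  if (n <= 3000) {
    A <- as.matrix(un != 0)
    cand <- which(upper.tri(A) & !A)
    i <- (cand - 1) %% n + 1; j <- (cand - 1) %/% n + 1
    key <- (i - 1) * n + j
    keep <- !(key %in% exKey)
    i <- i[keep]; j <- j[keep]
    if (count > length(i))
      stop(sprintf("requested %d non-edges but only %d exist", count, length(i)))
    pick <- sample.int(length(i), count)
    return(cbind(i = i[pick], j = j[pick]))
  }
  # rejection sampling for large node sets
  edgeKey <- .pairKey(.edgePairs(un), n)
  got <- numeric(0)
  guard <- 0L
  while (length(got) < count && guard < 200L) {
    need <- 2L * (count - length(got)) + 10L
    i <- sample.int(n, need, replace = TRUE)
    j <- sample.int(n, need, replace = TRUE)
    ok <- i != j
    key <- (pmin(i, j)[ok] - 1) * n + pmax(i, j)[ok]
    key <- setdiff(key, c(edgeKey, exKey, got))
    got <- c(got, key)
    guard <- guard + 1L
  }
  if (length(got) < count)
    stop("could not sample the requested number of non-edges")
  got <- got[seq_len(count)]
  cbind(i = as.integer((got - 1) %/% n + 1), j = as.integer((got - 1) %% n + 1))
}

#' Split a whole multiplex for link-prediction evaluation
#'
#' Applies [splitEdgesConnected()] to every layer, assembles the training
#' multiplex (same node universe, spanning train edges per layer), pools the
#' removed edges over layers as test positives (dropping pairs still present
#' in some training layer), and samples matching numbers of union non-edges
#' as train/test negatives.
#'
#' @param mux a [MultiplexNetwork-class] object.
#' @param fraction per-layer removed fraction; default 0.3.
#' @param seed RNG seed for the whole split.
#' @return an object of class `"evalSplit"`: list with `train` (the training
#'   [MultiplexNetwork-class]), pair matrices `trainPos`, `testPos`,
#'   `trainNeg`, `testNeg`, and `fraction`.
#' @export
splitMultiplex <- function(mux, fraction = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nNodes(mux)
  trainLayers <- list()
  testAll <- NULL
  for (l in layerNames(mux)) {
    A <- layerAdjacency(mux, l)
    sp <- splitEdgesConnected(A, fraction)
    w <- A[sp$train]
    trainLayers[[l]] <- Matrix::sparseMatrix(
      i = c(sp$train[, 1], sp$train[, 2]), j = c(sp$train[, 2], sp$train[, 1]),
      x = c(w, w), dims = c(n, n))
    testAll <- rbind(testAll, sp$test)
  }
  train <- .newMultiplex(trainLayers, nodeNames(mux))
  trainPosKey <- unique(unlist(lapply(trainLayers, function(A) .pairKey(.edgePairs(A), n))))
  testKey <- setdiff(unique(.pairKey(testAll, n)), trainPosKey)
  testPos <- cbind(i = as.integer((testKey - 1) %/% n + 1),
                   j = as.integer((testKey - 1) %% n + 1))
  trainPos <- cbind(i = as.integer((trainPosKey - 1) %/% n + 1),
                    j = as.integer((trainPosKey - 1) %% n + 1))
  un <- Reduce(`+`, mux@layers)
  avail <- n * (n - 1) / 2 - nrow(.edgePairs(un))
  if (avail < nrow(testPos))
    stop("not enough union non-edges to match the test positives 1:1")
  nTrainNeg <- min(nrow(trainPos), avail - nrow(testPos))
  if (nTrainNeg < nrow(trainPos))
    warning(sprintf("dense multiplex: only %d union non-edges left for %d train positives",
                    nTrainNeg, nrow(trainPos)))
  neg <- sampleNonEdges(mux, nrow(testPos) + nTrainNeg)
  structure(list(train = train,
                 trainPos = trainPos,
                 testPos = testPos,
                 trainNeg = neg[nrow(testPos) + seq_len(nTrainNeg), , drop = FALSE],
                 testNeg = neg[seq_len(nrow(testPos)), , drop = FALSE],
                 fraction = fraction),
            class = "evalSplit")
}

#' @export
print.evalSplit <- function(x, ...) {
  cat(sprintf("evalSplit: %d train / %d test positives (fraction %.2f), negatives matched 1:1\n",
              nrow(x$trainPos), nrow(x$testPos), x$fraction))
  invisible(x)
}

.aucScore <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Link prediction ROC-AUC with a logistic regressor
#'
#' Builds operator features for the train positives/negatives of an
#' [splitMultiplex()] split, fits a ridge-penalized logistic regressor, and
#' reports the ROC-AUC of its scores on the test positives/negatives.
#'
#' @param W embedding matrix covering all nodes (rows in `nodeNames` order).
#' @param split an `"evalSplit"` object.
#' @param operator edge operator name (see [edgeOperator()]).
#' @param verbatim operator variant flag (see [edgeOperator()]).
#' @param lambda ridge penalty of the logistic regressor; default 0.01.
#' @return list with `metric = "roc_auc"`, `value`, `operator`, `nTest`.
#' @export
linkPrediction <- function(W, split, operator = "hadamard", verbatim = TRUE,
                           lambda = 0.01) {
  stopifnot(inherits(split, "evalSplit"))
  W <- as.matrix(W)
  Xtr <- rbind(.edgeFeatures(W, split$trainPos, operator, verbatim),
               .edgeFeatures(W, split$trainNeg, operator, verbatim))
  ytr <- c(rep(1, nrow(split$trainPos)), rep(0, nrow(split$trainNeg)))
  if (length(unique(ytr)) < 2) stop("degenerate single-class training set")
  fit <- glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  Xte <- rbind(.edgeFeatures(W, split$testPos, operator, verbatim),
               .edgeFeatures(W, split$testNeg, operator, verbatim))
  yte <- c(rep(1, nrow(split$testPos)), rep(0, nrow(split$testNeg)))
  scores <- as.numeric(stats::predict(fit, Xte, type = "response"))
  list(metric = "roc_auc", value = .aucScore(yte, scores),
       operator = operator, nTest = length(yte))
}

#' Precision at K
#'
#' Fraction of positive labels among the `K` highest-scoring items. Ties are
#' broken by input order (stable sort).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, same length.
#' @param K number of top items, `1 <= K <= length(scores)`.
#' @return scalar in \[0, 1\].
#' @examples
#' precisionAtK(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0), 2)   # 0.5
#' @export
precisionAtK <- function(scores, labels, K) {
  if (K <= 0) stop("K must be positive")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (K > length(scores)) stop("K exceeds the number of items")
  top <- order(-scores)[seq_len(K)]        # radix order: stable for ties
  mean(labels[top] == 1)
}

#' Network reconstruction precision@K with a random forest
#'
#' Per layer: samples `pairFraction` of all unordered node pairs, labels them
#' by adjacency, fits a 100-tree random forest on the operator features of
#' this subset and scores the same subset — there is no held-out phase.
#' The subset scores are the forest's out-of-bag predictions: scoring
#' training rows with the full forest would merely read back the memorized
#' labels for any embedding, whereas out-of-bag scores measure how much
#' layer topology the embedding actually encodes (they are still optimistic
#' in that train and evaluation pairs coincide). `K` is the number of true
#' edges in the sampled subset.
#'
#' @param W embedding matrix covering all nodes.
#' @param mux the original [MultiplexNetwork-class].
#' @param pairFraction fraction of all pairs to sample, in (0, 1].
#' @param operator,verbatim edge operator (see [edgeOperator()]).
#' @param seed RNG seed (pair sampling and forest).
#' @param numTrees random-forest size; default 100.
#' @return data.frame with one row per layer: `layer`, `metric`, `value`,
#'   `K`, `nPairs`. Layers whose sampled subset has no positive pair are
#'   reported as `NA` with a message.
#' @export
networkReconstruction <- function(W, mux, pairFraction = 0.95,
                                  operator = "hadamard", verbatim = TRUE,
                                  seed = 1L, numTrees = 100L) {
  if (pairFraction <= 0 || pairFraction > 1) stop("pairFraction must be in (0, 1]")
  set.seed(seed)
  W <- as.matrix(W)
  n <- nNodes(mux)
  allPairs <- which(upper.tri(matrix(0, n, n)))
  i <- (allPairs - 1) %% n + 1; j <- (allPairs - 1) %/% n + 1
  out <- NULL
  for (l in layerNames(mux)) {
    A <- layerAdjacency(mux, l)
    nPick <- max(1L, round(pairFraction * length(allPairs)))
    pick <- if (nPick == length(allPairs)) seq_along(allPairs) else
      sample.int(length(allPairs), nPick)
    pairs <- cbind(i[pick], j[pick])
    y <- as.integer(A[pairs] != 0)
    if (!any(y == 1)) {
      message(sprintf("layer '%s': no true edges in the sampled subset; skipping", l))
      out <- rbind(out, data.frame(layer = l, metric = "precision_at_k",
                                   value = NA_real_, K = 0L, nPairs = nPick))
      next
    }
    X <- .edgeFeatures(W, pairs, operator, verbatim)
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    fit <- ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                          probability = TRUE, num.trees = numTrees,
                          seed = seed, num.threads = 1)
    scores <- fit$predictions[, "1"]        # out-of-bag subset scores
    scores[is.nan(scores)] <- 0
    K <- sum(y == 1)
    out <- rbind(out, data.frame(layer = l, metric = "precision_at_k",
                                 value = precisionAtK(scores, y, K),
                                 K = K, nPairs = nPick))
  }
  out
}

# Uniform bipartite non-pairs (i on side A, j on side B), excluding the
# given pair keys.
.sampleBipartiteNonEdges <- function(net, count, excludeKey = numeric(0)) {
  bip <- bipartiteMatrix(net)
  n <- nrow(bip); m <- ncol(bip)
  sm <- Matrix::summary(.asDgc(bip))
  edgeKey <- (sm$i - 1) * m + sm$j
  avoid <- c(edgeKey, excludeKey)
  total <- n * m - length(unique(avoid))
  if (count > total) stop("not enough absent bipartite pairs")
  if (n * m <= 4e6) {
    key <- setdiff(seq_len(n * m), avoid)
    pick <- if (length(key) == 1) key else sample(key, count)
  } else {
    pick <- numeric(0)
    while (length(pick) < count) {
      cand <- (sample.int(n, 2L * count, replace = TRUE) - 1) * m +
        sample.int(m, 2L * count, replace = TRUE)
      pick <- unique(c(pick, setdiff(cand, avoid)))
    }
    pick <- pick[seq_len(count)]
  }
  cbind(i = as.integer((pick - 1) %/% m + 1), j = as.integer((pick - 1) %% m + 1))
}

#' Bipartite link prediction for multiplex-heterogeneous embeddings
#'
#' The heterogeneous evaluation task: remove a fraction of the bipartite
#' edges (the multiplex layers are untouched and no connectivity constraint
#' applies), embed the resulting training network, fit a random forest on the
#' operator features of the remaining bipartite edges plus an equal number of
#' sampled bipartite non-pairs, and report the ROC-AUC of its scores on the
#' removed edges plus an equal number of fresh non-pairs.
#'
#' @param net a [MultiplexHeterogeneousNetwork-class] object.
#' @param fraction bipartite removal fraction; default 0.3.
#' @param operator,verbatim edge operator (see [edgeOperator()]).
#' @param params [rwrParams()] for the embedding of the training network.
#' @param config [trainConfig()] for the trainer; default built from the
#'   node count with `seed`.
#' @param seed master seed (split, negatives, training, forest).
#' @param numTrees random-forest size; default 100.
#' @param embeddings optional precomputed embeddings of the TRAINING network
#'   (rows in `nodeNames(net)` order); mainly for testing.
#' @return list with `metric = "roc_auc"`, `value`, `operator`, `nRemoved`,
#'   `nKept`.
#' @export
bipartiteLinkPrediction <- function(net, fraction = 0.3, operator = "hadamard",
                                    verbatim = TRUE, params = rwrParams(),
                                    config = NULL, seed = 1L, numTrees = 100L,
                                    embeddings = NULL) {
  stopifnot(methods::is(net, "MultiplexHeterogeneousNetwork"))
  bip <- bipartiteMatrix(net)
  sm <- Matrix::summary(.asDgc(bip))
  nE <- nrow(sm)
  if (nE < 2) stop("need at least 2 bipartite edges")
  set.seed(seed)
  n <- nNodes(multiplexA(net)); m <- nNodes(multiplexB(net))
  nRemove <- round(fraction * nE)
  testIdx <- sample.int(nE, nRemove)
  keep <- setdiff(seq_len(nE), testIdx)
  trainBip <- Matrix::sparseMatrix(i = sm$i[keep], j = sm$j[keep],
                                   x = sm$x[keep], dims = c(n, m))
  trainNet <- .newHeterogeneous(net@muxA, net@muxB, trainBip)
  W <- if (is.null(embeddings)) {
    if (is.null(config)) config <- trainConfig(n + m, seed = seed)
    embedNodes(trainNet, params, config)
  } else as.matrix(embeddings)
  # bipartite pairs indexed into the stacked embedding rows (A then B)
  trainPos <- cbind(sm$i[keep], n + sm$j[keep])
  testPos <- cbind(sm$i[testIdx], n + sm$j[testIdx])
  allEdgeKey <- (sm$i - 1) * m + sm$j
  negs <- .sampleBipartiteNonEdges(net, length(keep) + nRemove,
                                   excludeKey = allEdgeKey)
  trainNeg <- cbind(negs[seq_along(keep), 1], n + negs[seq_along(keep), 2])
  testNeg <- cbind(negs[length(keep) + seq_len(nRemove), 1],
                   n + negs[length(keep) + seq_len(nRemove), 2])
  X <- rbind(.edgeFeatures(W, trainPos, operator, verbatim),
             .edgeFeatures(W, trainNeg, operator, verbatim))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- factor(c(rep(1, nrow(trainPos)), rep(0, nrow(trainNeg))), levels = c(0, 1))
  fit <- ranger::ranger(x = X, y = y, probability = TRUE,
                        num.trees = numTrees, seed = seed, num.threads = 1)
  Xte <- rbind(.edgeFeatures(W, testPos, operator, verbatim),
               .edgeFeatures(W, testNeg, operator, verbatim))
  colnames(Xte) <- colnames(X)
  yte <- c(rep(1, nrow(testPos)), rep(0, nrow(testNeg)))
  scores <- stats::predict(fit, Xte, num.threads = 1)$predictions[, "1"]
  list(metric = "roc_auc", value = .aucScore(yte, scores), operator = operator,
       nRemoved = nRemove, nKept = length(keep))
}
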