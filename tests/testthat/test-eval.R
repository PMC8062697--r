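test_that("triangle split removes one edge and keeps the pair connected", {
  tri <- readMultiplex(c("1 a b", "1 b c", "1 a c"))
  sp <- splitEdgesConnected(layerAdjacency(tri, 1), 0.3, seed = 1)
  expect_equal(nrow(sp$test), 1L)     # round(0.9) = 1
  expect_equal(nrow(sp$train), 2L)
  g <- igraph::graph_from_edgelist(sp$train, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)
})

test_that("a tree yields no removable edges and a shortfall warning", {
  path <- readMultiplex(c("1 a b", "1 b c", "1 c d"))
  expect_warning(sp <- splitEdgesConnected(layerAdjacency(path, 1), 0.3, seed = 2),
                 "spanning tree")
  expect_equal(nrow(sp$test), 0L)
  expect_equal(nrow(sp$train), 3L)
})

test_that("a 100-edge connected layer always gives 30 test edges and a spanning train graph", {
  A <- connectedGraph(40, 100, seed = 123)
  for (seed in 1:20) {
    sp <- splitEdgesConnected(A, 0.3, seed = seed)
    expect_equal(nrow(sp$test), 30L)
    expect_equal(nrow(sp$train), 70L)
    # partition of the original edges
    allKey <- sort(c(muxembed:::.pairKey(sp$train, 40), muxembed:::.pairKey(sp$test, 40)))
    expect_equal(allKey, sort(muxembed:::.pairKey(muxembed:::.edgePairs(A), 40)))
    g <- igraph::graph_from_edgelist(sp$train, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, 40 - igraph::gorder(g)))
    expect_equal(igraph::components(g)$no, 1L)
  }
})

test_that("non-edge sampling enumerates, errors and avoids all layers", {
  mux <- readMultiplex(c("1 a b", "1 c d", "2 c d"))  # 4 nodes, union edges {ab, cd}
  neg <- sampleNonEdges(mux, 4, seed = 1)
  expect_equal(nrow(neg), 4L)                        # C(4,2) - 2 = 4 exist
  expect_error(sampleNonEdges(mux, 5), "only 4")

  complete <- readMultiplex(c("1 a b", "1 a c", "1 b c"))
  expect_error(sampleNonEdges(complete, 1), "only 0")

  mux2 <- randomMultiplex(20, 2, 0.2, seed = 9)
  un <- layerAdjacency(mux2, 1) + layerAdjacency(mux2, 2)
  neg2 <- sampleNonEdges(mux2, 50, seed = 3)
  expect_true(all(un[neg2] == 0))
  expect_false(any(duplicated(muxembed:::.pairKey(neg2, 20))))
})

test_that("multiplex splits partition edges and pair sets match 1:1", {
  mux <- randomMultiplex(30, 3, 0.08, seed = 17)
  # sparse random layers may be near-trees: the per-layer shortfall warning
  # is part of the protocol, not a failure of the split
  split <- suppressWarnings(splitMultiplex(mux, 0.3, seed = 4))
  expect_s4_class(split$train, "MultiplexNetwork")
  expect_equal(nrow(split$trainNeg), nrow(split$trainPos))
  expect_equal(nrow(split$testNeg), nrow(split$testPos))
  # test positives absent from every training layer, present in the original
  for (l in seq_len(3)) expect_true(all(layerAdjacency(split$train, l)[split$testPos] == 0))
  un <- Reduce(`+`, lapply(1:3, function(l) layerAdjacency(mux, l)))
  expect_true(all(un[split$testPos] > 0))
  expect_true(all(un[split$testNeg] == 0))
})

test_that("link prediction is perfect on separable features, null on random ones", {
  # two groups of 10; within-group pairs are positives
  d <- 4
  W <- rbind(matrix(1, 10, d), matrix(-1, 10, d))
  pairsIn <- t(combn(1:10, 2)); pairsOut <- cbind(1:10, 11:20)
  fake <- structure(list(trainPos = pairsIn[1:20, ], trainNeg = pairsOut[1:10, , drop = FALSE],
                         testPos = pairsIn[21:40, ], testNeg = cbind(2:10, 12:20),
                         fraction = 0.3),
                    class = "evalSplit")
  expect_equal(linkPrediction(W, fake, "hadamard")$value, 1.0)

  # permutation null: label-independent random features
  mux <- randomMultiplex(40, 2, 0.15, seed = 31)
  aucs <- sapply(1:20, function(seed) {
    split <- splitMultiplex(mux, 0.3, seed = seed)
    Wr <- initEmbeddings(40, 16, seed = seed + 100) * 100
    linkPrediction(Wr, split, "hadamard")$value
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("precision@K counts positives among the top-K, ties by input order", {
  expect_equal(precisionAtK(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0), 2), 0.5)
  expect_equal(precisionAtK(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 2), 1.0)
  expect_equal(precisionAtK(c(0.5, 0.4), c(0, 0), 1), 0.0)
  expect_equal(precisionAtK(rep(0.5, 4), c(1, 0, 0, 0), 1), 1.0)  # stable ties
  expect_error(precisionAtK(1:3, c(1, 0, 1), 0), "positive")
  expect_error(precisionAtK(1:3, c(1, 0), 2), "length")
})

test_that("network reconstruction: perfect information ceiling and random baseline", {
  g <- smallCommunityFixture(seed = 6)
  mux <- g$network
  # perfect information: adjacency rows plus a strong self indicator, so the
  # pair feature at coordinate u reads off the edge weight A[u, v] directly
  A <- as.matrix(layerAdjacency(mux, 1))
  Wperf <- A + 10 * diag(nrow(A))
  res <- networkReconstruction(Wperf, mux, pairFraction = 0.95,
                               operator = "hadamard", seed = 2)
  expect_true(all(res$metric == "precision_at_k"))
  expect_gte(res$value[1], 0.95)
  # K equals the number of true edges in each sampled subset
  expect_true(all(res$K > 0))

  # random embeddings score near the subset positive rate
  vals <- sapply(1:5, function(seed) {
    Wr <- initEmbeddings(60, 16, seed = seed + 50) * 100
    r <- networkReconstruction(Wr, mux, pairFraction = 0.95,
                               operator = "hadamard", seed = seed)
    mean(r$value - r$K / r$nPairs)
  })
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("bipartite link prediction removes round(fraction * E) edges", {
  muxA <- randomMultiplex(8, 1, 0.5, seed = 41)
  muxB0 <- randomMultiplex(8, 1, 0.5, seed = 42)
  muxB <- muxembed:::.newMultiplex(muxB0@layers, paste0("u", 1:8))
  # exactly 10 bipartite edges
  bip <- Matrix::sparseMatrix(i = c(1:8, 1, 2), j = c(1:8, 5, 6), x = 1,
                              dims = c(8, 8))
  net <- muxembed:::.newHeterogeneous(muxA, muxB, bip)
  Wfix <- initEmbeddings(16, 8, seed = 1)
  res <- suppressMessages(
    bipartiteLinkPrediction(net, 0.3, "hadamard", seed = 3, embeddings = Wfix))
  expect_equal(res$nRemoved, 3L)
  expect_equal(res$nKept, 7L)
  expect_error(suppressMessages(bipartiteLinkPrediction(
    muxembed:::.newHeterogeneous(muxA, muxB,
      Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(8, 8))), 0.3)),
    "at least 2")
})

test_that("bipartite link prediction is null for label-independent embeddings", {
  set.seed(77)
  mh <- generateMHSBM(sbmSpec(n = 20, L = 2, blocks = c(10, 10), pIn = 0.4),
                      sbmSpec(n = 20, L = 2, blocks = c(10, 10), pIn = 0.4),
                      pBipIn = 0.4, pBipOut = 0.1, seed = 77)$network
  aucs <- sapply(1:20, function(seed) {
    Wr <- initEmbeddings(40, 16, seed = seed + 500) * 100
    suppressMessages(bipartiteLinkPrediction(mh, 0.3, "hadamard", seed = seed,
                                             embeddings = Wr)$value)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
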