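test_that("column normalization divides nonzero columns and flags zero ones", {
  out <- columnNormalize(matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(as.matrix(out), matrix(c(0, 1, 1, 0), 2, 2), ignore_attr = TRUE)
  # already stochastic input unchanged
  path <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(as.matrix(columnNormalize(path)), path, ignore_attr = TRUE)
  # zero column preserved and flagged
  m <- matrix(c(0, 1, 0, 0), 2, 2)
  out <- columnNormalize(m)
  expect_equal(attr(out, "zeroColumns"), 2L)
  expect_equal(as.matrix(out)[, 2], c(0, 0))
  expect_error(columnNormalize(matrix(c(0, -1, 1, 0), 2, 2)), "non-negative")
})

test_that("multiplex supra-transition matches the hand construction", {
  # 2 nodes, 2 layers each with edge a-b, delta = 0.5:
  # column of state (a,1) = {(b,1): 0.5, (a,2): 0.5}
  mux <- readMultiplex(c("1 a b", "2 a b"))
  st <- supraTransition(mux, rwrParams(delta = 0.5))
  col <- as.matrix(st@matrix)[, 1]
  expect_equal(col, c(0, 0.5, 0.5, 0), ignore_attr = TRUE)
})

test_that("single-layer supra equals the column-normalized adjacency", {
  mux <- randomMultiplex(10, 1, 0.4, seed = 5)
  st <- supraTransition(mux)
  expect_equal(as.matrix(st@matrix),
               as.matrix(columnNormalize(layerAdjacency(mux, 1))),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("supra columns are stochastic on random fixtures (multiplex and MH)", {
  for (seed in 1:5) {
    mux <- randomMultiplex(15, 3, 0.2, seed)
    st <- supraTransition(mux)
    cs <- Matrix::colSums(st@matrix)
    expect_true(all(abs(cs[!st@dangling] - 1) < 1e-12))
  }
  set.seed(8)
  mh <- generateMHSBM(sbmSpec(n = 20, L = 2, blocks = c(10, 10), pIn = 0.4),
                      sbmSpec(n = 15, L = 3, blocks = c(8, 7), pIn = 0.4),
                      pBipIn = 0.3, pBipOut = 0.05, seed = 8)$network
  st <- supraTransition(mh)
  cs <- Matrix::colSums(st@matrix)
  expect_true(all(abs(cs[!st@dangling] - 1) < 1e-12))
})

test_that("heterogeneous supra matches the hand construction and limits", {
  # single bipartite edge a-x, 1 layer per side, lambda = 0.5, a-b edge on A:
  # column of (a) = {(b): 0.5, (x): 0.5}
  muxA <- readMultiplex("1 a b")
  muxB <- readMultiplex("1 x y")
  net <- suppressMessages(buildHeterogeneous(muxA, muxB, "a x"))
  st <- supraTransition(net, rwrParams(lambda = 0.5))
  col <- as.matrix(st@matrix)[, 1]          # state order: a b x y
  expect_equal(col, c(0, 0.5, 0.5, 0), ignore_attr = TRUE)

  # lambda = 0: block-diagonal, blocks equal the per-side supra matrices
  mh <- generateMHSBM(sbmSpec(n = 12, L = 2, blocks = c(6, 6), pIn = 0.5),
                      sbmSpec(n = 10, L = 2, blocks = c(5, 5), pIn = 0.5),
                      pBipIn = 0.4, pBipOut = 0.1, seed = 3)$network
  st0 <- supraTransition(mh, rwrParams(lambda = 0))
  NA_ <- nNodes(multiplexA(mh)) * 2
  M <- as.matrix(st0@matrix)
  expect_equal(M[seq_len(NA_), seq_len(NA_)],
               as.matrix(supraTransition(multiplexA(mh))@matrix),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(M[-seq_len(NA_), -seq_len(NA_)],
               as.matrix(supraTransition(multiplexB(mh))@matrix),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(M[-seq_len(NA_), seq_len(NA_)] == 0))
})

test_that("isolated-in-layer nodes reroute their mass to inter-layer jumps", {
  # c has edges only in layer 1; its layer-2 state must jump back to layer 1
  mux <- readMultiplex(c("1 a b", "1 b c", "2 a b"))
  st <- supraTransition(mux, rwrParams(delta = 0.5))
  n <- 3
  colC2 <- as.matrix(st@matrix)[, n + 3]    # state (c, layer 2)
  expect_equal(unname(colC2[3]), 1)         # all mass to (c, layer 1)
  expect_false(any(st@dangling))
})

test_that("rwrSolve matches the closed form and its limits", {
  # single node: stationary distribution is the point mass
  single <- muxembed:::.newMultiplex(
    list(l1 = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(1, 1))), "a")
  st1 <- supraTransition(single)
  expect_equal(unname(rwrSolve(st1, 1, rwrParams(r = 0.7))), 1)

  # 2-node path, r = 0.7, seed a: p_a = r / (1 - (1-r)^2)
  mux <- readMultiplex("1 a b")
  st <- supraTransition(mux)
  p <- rwrSolve(st, c(1, 0), rwrParams(r = 0.7))
  expect_equal(unname(p), c(0.7 / 0.91, 0.3 * 0.7 / 0.91), tolerance = 1e-8)
  expect_equal(unname(p), c(0.76923, 0.23077), tolerance = 1e-5)

  # restart-dominated limit r -> 1
  p1 <- rwrSolve(st, c(1, 0), rwrParams(r = 1 - 1e-12))
  expect_equal(unname(p1), c(1, 0), tolerance = 1e-9)
})

test_that("iterative solver agrees with the direct linear solution", {
  # >= 20 random fixtures with <= 50 supra states
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:12, 1)
    L <- sample(1:4, 1)
    while (n * L > 50) L <- max(1L, L - 1L)
    mux <- randomMultiplex(n, L, 0.3, seed)
    st <- supraTransition(mux)
    p0 <- rep(0, n * L); p0[sample.int(n * L, 1)] <- 1
    pIter <- rwrSolve(st, p0, rwrParams(r = 0.7, tol = 1e-12))
    pDirect <- directRWR(st, p0, 0.7)
    worst <- max(worst, max(abs(pIter - pDirect)))
  }
  expect_lt(worst, 1e-6)
})

test_that("similarity columns are probability distributions", {
  mux <- randomMultiplex(20, 3, 0.15, seed = 4)
  sim <- rwrSimilarity(mux)
  expect_true(all(sim >= 0))
  expect_true(all(abs(colSums(sim) - 1) < 1e-6))

  mh <- generateMHSBM(sbmSpec(n = 15, L = 2, blocks = c(8, 7), pIn = 0.3),
                      sbmSpec(n = 12, L = 2, blocks = c(6, 6), pIn = 0.3),
                      pBipIn = 0.3, pBipOut = 0.05, seed = 2)$network
  simMH <- rwrSimilarity(mh)
  expect_equal(dim(simMH), c(27L, 27L))
  expect_true(all(abs(colSums(simMH) - 1) < 1e-6))
})

test_that("identical layers reduce to the monoplex walk", {
  A <- connectedGraph(12, 20, seed = 9)
  mux3 <- muxembed:::.newMultiplex(list(l1 = A, l2 = A, l3 = A),
                                   paste0("v", 1:12))
  mux1 <- muxembed:::.newMultiplex(list(l1 = A), paste0("v", 1:12))
  # with inter-layer jumps off the reduction is exact
  expect_equal(rwrSimilarity(mux3, rwrParams(delta = 0)), rwrSimilarity(mux1),
               tolerance = 1e-6)
  # with jumps on, aggregation over identical layers is a lazy walk: it
  # equals the monoplex RWR at the effective restart r' = r / (1 - (1-r)*d)
  r <- 0.7; d <- 0.5
  expect_equal(rwrSimilarity(mux3, rwrParams(r = r, delta = d)),
               rwrSimilarity(mux1, rwrParams(r = r / (1 - (1 - r) * d))),
               tolerance = 1e-6)
})

test_that("the seed has the largest similarity and it grows with r", {
  mux <- randomMultiplex(10, 2, 0.35, seed = 11)   # connected w.h.p. at p=0.35
  sim <- rwrSimilarity(mux, rwrParams(r = 0.7))
  expect_true(all(apply(sim, 2, which.max) == seq_len(10)))
  # verified against the direct solve
  st <- supraTransition(mux)
  p0 <- rep(0, 20); p0[c(1, 11)] <- 0.5
  expect_equal(unname(sim[, 1]),
               unname(rowSums(matrix(directRWR(st, p0, 0.7), ncol = 2))),
               tolerance = 1e-6)
  # monotonicity of the self-probability in r
  selfProb <- sapply(c(0.3, 0.5, 0.7, 0.9), function(r)
    rwrSimilarity(mux, rwrParams(r = r), seeds = 1L)[1, 1])
  expect_true(all(diff(selfProb) > 0))
})

test_that("empty bipartite set reduces RWR-MH to two independent RWR-Ms", {
  muxA <- randomMultiplex(10, 2, 0.3, seed = 21)
  muxB0 <- randomMultiplex(8, 2, 0.3, seed = 22)
  muxB <- muxembed:::.newMultiplex(muxB0@layers, paste0("u", 1:8))
  net <- suppressWarnings(suppressMessages(
    buildHeterogeneous(muxA, muxB, character(0))))
  simMH <- suppressMessages(rwrSimilarity(net))
  expect_equal(unname(simMH[1:10, 1:10]), unname(rwrSimilarity(muxA)),
               tolerance = 1e-6)
  expect_equal(unname(simMH[11:18, 11:18]), unname(rwrSimilarity(muxB)),
               tolerance = 1e-6)
  expect_true(all(simMH[11:18, 1:10] == 0))
})

test_that("a bipartite partner is the top-ranked cross-side node of its seed", {
  # x's only distinction on side B is its bipartite link to a
  muxA <- readMultiplex(c("1 a b", "1 b c"))
  muxB <- readMultiplex(c("1 x y", "1 y z"))
  net <- suppressMessages(buildHeterogeneous(muxA, muxB, "a x"))
  sim <- rwrSimilarity(net)
  bSide <- sim[4:6, "a"]
  expect_equal(names(which.max(bSide)), "x")
  # cross-checked against the direct solve
  st <- supraTransition(net)
  p0 <- rep(0, 6); p0[1] <- 1
  expect_equal(unname(sim[, "a"]), unname(directRWR(st, p0, 0.7)),
               tolerance = 1e-6)
})

test_that("truncation keeps the largest entries and renormalizes", {
  v <- matrix(c(0.5, 0.3, 0.1, 0.06, 0.04), ncol = 1)
  tr <- truncateSimilarity(v, 2, excludeSeed = FALSE)
  expect_equal(tr$support[[1]], c(1L, 2L))
  expect_equal(tr$prob[[1]], c(0.625, 0.375))

  trAll <- truncateSimilarity(v, 5, excludeSeed = FALSE)
  expect_equal(trAll$prob[[1]], v[, 1])
  trBig <- truncateSimilarity(v, 99, excludeSeed = FALSE)
  expect_equal(trBig$prob[[1]], v[, 1])
})

test_that("truncated columns sum to 1, respect nMax and exclude the seed", {
  mux <- randomMultiplex(25, 2, 0.2, seed = 14)
  sim <- rwrSimilarity(mux)
  tr <- truncateSimilarity(sim, 6)
  expect_true(all(lengths(tr$support) <= 6))
  expect_true(all(abs(vapply(tr$prob, sum, numeric(1)) - 1) < 1e-9))
  for (s in seq_len(25)) expect_false(s %in% tr$support[[s]])
  # retained entries are the largest of the (seed-free) column
  for (s in c(1, 10, 25)) {
    p <- sim[, s]; p[s] <- 0
    expect_setequal(tr$support[[s]], order(-p, seq_along(p))[1:6])
  }
})
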