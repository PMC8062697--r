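# Independent oracles and small fixture builders shared across test files.

# Direct linear-system solution of the restart walk: solves
#   p = (1 - r) * (T + p0 %*% t(dangling)) p + r * p0
# by dense inversion. Independent of the iterative solver.
directRWR <- function(st, p0, r) {
  M <- as.matrix(st@matrix)
  if (any(st@dangling)) M <- M + outer(p0, as.numeric(st@dangling))
  N <- ncol(M)
  solve(diag(N) - (1 - r) * M, r * p0)
}

# Random Erdos-Renyi multiplex with a guaranteed non-empty edge set.
randomMultiplex <- function(n, L, p, seed) {
  set.seed(seed)
  layers <- lapply(seq_len(L), function(a) {
    repeat {
      up <- Matrix::sparseMatrix(
        i = integer(0), j = integer(0), x = numeric(0), dims = c(n, n))
      iu <- which(upper.tri(matrix(0, n, n)))
      sel <- iu[stats::runif(length(iu)) < p]
      if (length(sel)) {
        i <- (sel - 1) %% n + 1; j <- (sel - 1) %/% n + 1
        up <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
        return(up + Matrix::t(up))
      }
    }
  })
  names(layers) <- paste0("l", seq_len(L))
  muxembed:::.newMultiplex(layers, paste0("v", seq_len(n)))
}

# Connected random graph with exactly nEdges edges on n nodes:
# random spanning tree plus random extra edges.
connectedGraph <- function(n, nEdges, seed) {
  stopifnot(nEdges >= n - 1, nEdges <= n * (n - 1) / 2)
  set.seed(seed)
  perm <- sample.int(n)
  tree <- cbind(perm[2:n], perm[sapply(2:n, function(k) sample.int(k - 1, 1))])
  key <- (pmin(tree[, 1], tree[, 2]) - 1) * n + pmax(tree[, 1], tree[, 2])
  all <- which(upper.tri(matrix(0, n, n)))
  allKey <- ((all - 1) %% n + 1 - 1) * n + ((all - 1) %/% n + 1)
  extra <- sample(setdiff(allKey, key), nEdges - (n - 1))
  key <- c(key, extra)
  i <- (key - 1) %/% n + 1; j <- (key - 1) %% n + 1
  up <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  up + Matrix::t(up)
}

# A two-community multiplex small enough for fast training tests.
smallCommunityFixture <- function(seed = 1) {
  generateMultiplexSBM(sbmSpec(n = 60, L = 2, blocks = c(30, 30),
                               pIn = 0.4, pOut = 0.02), seed = seed)
}
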