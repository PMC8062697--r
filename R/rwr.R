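# Random Walk with Restart on multiplex and multiplex-heterogeneous graphs.
#
# States are (node, layer) pairs, layer-major: state (i, alpha) has index
# (alpha - 1) * n + i. For heterogeneous networks, all side-A states precede
# all side-B states.

#' Random-walk-with-restart parameters
#'
#' Bundles the walk parameters. `r` is the restart probability; at each step
#' the walker teleports back to the seed with probability `r`. `delta` splits
#' the non-restart mass between within-layer moves (`1 - delta`) and jumps to
#' the node's counterpart states in the other layers (`delta`). `tau` spreads
#' the restart mass over the layers (default uniform). For heterogeneous
#' walks, `lambda` is the probability of following a bipartite edge to the
#' other multiplex and `eta` splits restart mass between the two sides (with
#' a single seed the whole mass goes to the seed's own side, so `eta` only
#' matters for multi-side seed sets).
#'
#' @param r restart probability in (0, 1); default 0.7.
#' @param delta inter-layer jump probability in \[0, 1\]; default 0.5.
#' @param tau per-layer restart weights (must sum to 1); `NULL` = uniform.
#' @param lambda inter-network jump probability in \[0, 1\]; default 0.5.
#' @param eta restart split between the two multiplexes in \[0, 1\]; default 0.5.
#' @param tol L1 convergence threshold of the iterative solver; default 1e-8.
#' @param maxIter iteration cap; default 1000.
#' @return a list of class `"rwrParams"`.
#' @export
rwrParams <- function(r = 0.7, delta = 0.5, tau = NULL, lambda = 0.5,
                      eta = 0.5, tol = 1e-8, maxIter = 1000L) {
  stopifnot(r > 0, r < 1, delta >= 0, delta <= 1, lambda >= 0, lambda <= 1,
            eta >= 0, eta <= 1, tol > 0, maxIter >= 1)
  if (!is.null(tau)) {
    stopifnot(all(tau >= 0), abs(sum(tau) - 1) < 1e-8)
  }
  structure(list(r = r, delta = delta, tau = tau, lambda = lambda, eta = eta,
                 tol = tol, maxIter = as.integer(maxIter)),
            class = "rwrParams")
}

#' Column-normalize a non-negative matrix
#'
#' Divides every nonzero column by its sum, turning an adjacency matrix into
#' a column-stochastic transition matrix. All-zero columns are preserved
#' unchanged and flagged in the `"zeroColumns"` attribute; callers decide how
#' to repair them (the supra-transition builders reassign that mass, the
#' solver teleports it to the seed).
#'
#' @param m non-negative square matrix (dense or sparse).
#' @return a sparse column-stochastic matrix with attribute `zeroColumns`
#'   (integer indices of untouched all-zero columns).
#' @examples
#' columnNormalize(matrix(c(0, 2, 2, 0), 2, 2))
#' @export
columnNormalize <- function(m) {
  m <- .asDgc(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (length(m@x) && any(m@x < 0)) stop("matrix must be non-negative")
  cs <- Matrix::colSums(m)
  zero <- which(cs == 0)
  scale <- ifelse(cs > 0, 1 / cs, 0)
  out <- m %*% Matrix::Diagonal(x = scale)
  out <- .asDgc(out)
  attr(out, "zeroColumns") <- zero
  out
}

# Per-layer column-normalized adjacencies and the isolation mask.
.layerNorms <- function(mux) {
  L <- nLayers(mux); n <- nNodes(mux)
  iso <- matrix(FALSE, n, L)
  norms <- vector("list", L)
  for (a in seq_len(L)) {
    A <- mux@layers[[a]]
    cs <- Matrix::colSums(A)
    iso[, a] <- cs == 0
    norms[[a]] <- A %*% Matrix::Diagonal(x = ifelse(cs > 0, 1 / cs, 0))
  }
  list(norms = norms, iso = iso)
}

# Raw multiplex supra matrix (nL x nL sparse). Columns of fully dangling
# states (node isolated in a single-layer network) are all-zero.
.supraMultiplexMatrix <- function(mux, delta) {
  n <- nNodes(mux); L <- nLayers(mux)
  ln <- .layerNorms(mux)
  # column coefficients per (node, layer)
  if (L > 1) {
    cIntra <- ifelse(ln$iso, 0, 1 - delta)
    cInter <- ifelse(ln$iso, 1, delta) / (L - 1)
  } else {
    cIntra <- ifelse(ln$iso, 0, 1)
    cInter <- matrix(0, n, L)
  }
  rows <- vector("list", L)
  for (b in seq_len(L)) {
    blocks <- vector("list", L)
    for (a in seq_len(L)) {
      blocks[[a]] <- if (a == b)
        ln$norms[[a]] %*% Matrix::Diagonal(x = cIntra[, a])
      else
        Matrix::Diagonal(x = cInter[, a])
    }
    rows[[b]] <- do.call(cbind, blocks)
  }
  .asDgc(do.call(rbind, rows))
}

.stateMapMultiplex <- function(mux, side = "A") {
  n <- nNodes(mux); L <- nLayers(mux)
  data.frame(state = seq_len(n * L),
             node = rep(nodeNames(mux), times = L),
             layer = rep(layerNames(mux), each = n),
             side = side,
             stringsAsFactors = FALSE)
}

.finishSupra <- function(M, stateMap) {
  cs <- Matrix::colSums(M)
  dangling <- cs < 1e-12
  scale <- ifelse(dangling, 0, 1 / cs)
  M <- .asDgc(M %*% Matrix::Diagonal(x = scale))
  methods::new("SupraTransition", matrix = M, stateMap = stateMap,
               dangling = as.logical(dangling))
}

#' Supra-transition matrix of a (heterogeneous) multiplex walk
#'
#' Builds the column-stochastic transition matrix over (node, layer) states.
#'
#' For a [MultiplexNetwork-class], from state (i, alpha) the walker moves
#' with probability `1 - delta` to a within-layer neighbour of `i` in layer
#' alpha (weight-proportional) and with probability `delta` uniformly to one
#' of the `L - 1` counterpart states (i, beta). If `i` is isolated in layer
#' alpha, the within-layer mass is reassigned to the inter-layer jump; with a
#' single layer, the `delta` mass stays within the layer. A node isolated in
#' every layer of a single-layer network yields a dangling (all-zero) column
#' that [rwrSolve()] teleports to the restart vector.
#'
#' For a [MultiplexHeterogeneousNetwork-class], a state whose node has at
#' least one bipartite neighbour spends probability `lambda` on bipartite
#' jumps (weight-proportional over neighbours, arrival layer uniform over the
#' target side's layers) and scales its intra-multiplex moves by
#' `1 - lambda`; nodes without bipartite neighbours walk purely within their
#' own multiplex. With `lambda = 0` or an empty bipartite set the matrix is
#' block-diagonal and each block equals the corresponding multiplex supra
#' matrix.
#'
#' @param x a [MultiplexNetwork-class] or
#'   [MultiplexHeterogeneousNetwork-class] object.
#' @param params a [rwrParams()] list.
#' @return a [SupraTransition-class] object.
#' @examples
#' mux <- readMultiplex(c("1 a b", "2 a b"))
#' supraTransition(mux, rwrParams(delta = 0.5))
#' @export
setGeneric("supraTransition", function(x, params = rwrParams())
  standardGeneric("supraTransition"))

#' @rdname supraTransition
setMethod("supraTransition", "MultiplexNetwork", function(x, params = rwrParams()) {
  .finishSupra(.supraMultiplexMatrix(x, params$delta), .stateMapMultiplex(x))
})

#' @rdname supraTransition
setMethod("supraTransition", "MultiplexHeterogeneousNetwork",
          function(x, params = rwrParams()) {
  muxA <- x@muxA; muxB <- x@muxB; bip <- x@bipartite
  n <- nNodes(muxA); m <- nNodes(muxB)
  LA <- nLayers(muxA); LB <- nLayers(muxB)
  lambda <- params$lambda
  TA <- .supraMultiplexMatrix(muxA, params$delta)
  TB <- .supraMultiplexMatrix(muxB, params$delta)
  hasBipA <- Matrix::rowSums(bip) > 0
  hasBipB <- Matrix::colSums(bip) > 0
  if (!any(hasBipA))
    message("no bipartite edges: supra matrix is block-diagonal over the two multiplexes")
  # intra-multiplex blocks, scaled by (1 - lambda) on bipartite-linked nodes
  scaleA <- ifelse(hasBipA, 1 - lambda, 1)
  scaleB <- ifelse(hasBipB, 1 - lambda, 1)
  SAA <- TA %*% Matrix::Diagonal(x = rep(scaleA, LA))
  SBB <- TB %*% Matrix::Diagonal(x = rep(scaleB, LB))
  # bipartite blocks: row-normalized from side A, column-normalized from side B
  rs <- Matrix::rowSums(bip); cs <- Matrix::colSums(bip)
  Rn <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% bip   # n x m, rows sum 1
  Cn <- bip %*% Matrix::Diagonal(x = ifelse(cs > 0, 1 / cs, 0))   # n x m, cols sum 1
  SBA <- kronecker(matrix(1, LB, LA), Matrix::t(Rn) * (lambda / LB))
  SAB <- kronecker(matrix(1, LA, LB), Cn * (lambda / LA))
  M <- rbind(cbind(SAA, SAB), cbind(SBA, SBB))
  sm <- rbind(.stateMapMultiplex(muxA, "A"), .stateMapMultiplex(muxB, "B"))
  sm$state <- seq_len(nrow(sm))
  .finishSupra(M, sm)
})

#' Iterative random walk with restart
#'
#' Iterates `p <- (1 - r) * (T p + p0 * danglingMass) + r * p0` from `p0`
#' until the L1 change drops below `params$tol` or `params$maxIter` is
#' reached. Mass landing on dangling states (flagged in the supra matrix) is
#' teleported back to the restart vector, so probability is conserved.
#' `p0` may be a matrix (one restart vector per column); all walks are then
#' iterated jointly.
#'
#' @param st a [SupraTransition-class] object.
#' @param p0 restart vector over states (sums to 1), or a states-by-seeds
#'   matrix of restart vectors.
#' @param params a [rwrParams()] list (`r`, `tol`, `maxIter` are used).
#' @return the stationary vector (or matrix), same shape as `p0`.
#' @examples
#' mux <- readMultiplex("1 a b")
#' st <- supraTransition(mux)
#' rwrSolve(st, c(1, 0), rwrParams(r = 0.7))   # ~ (0.769, 0.231)
#' @export
rwrSolve <- function(st, p0, params = rwrParams()) {
  stopifnot(methods::is(st, "SupraTransition"))
  M <- st@matrix
  vec <- is.null(dim(p0))
  P0 <- if (vec) matrix(p0, ncol = 1) else as.matrix(p0)
  if (nrow(P0) != ncol(M)) stop("p0 length does not match the number of states")
  if (any(abs(Matrix::colSums(P0) - 1) > 1e-8))
    stop("each restart vector must sum to 1")
  r <- params$r
  dang <- st@dangling
  P <- P0
  for (it in seq_len(params$maxIter)) {
    lost <- if (any(dang)) colSums(P[dang, , drop = FALSE]) else 0
    Pnew <- as.matrix((1 - r) * (M %*% P)) +
      sweep(P0, 2, (1 - r) * lost, `*`) + r * P0
    res <- max(colSums(abs(Pnew - P)))
    P <- Pnew
    if (res < params$tol) break
  }
  if (res >= params$tol)
    warning(sprintf("RWR did not converge in %d iterations (L1 residual %.3g)",
                    params$maxIter, res))
  if (vec) drop(P) else P
}

# Restart matrix (states x seeds) for one multiplex side occupying rows
# offset + (alpha - 1) * n + i of an N-state system.
.restartBlock <- function(N, n, L, tau, offset = 0L) {
  if (is.null(tau)) tau <- rep(1 / L, L)
  if (length(tau) != L) stop("tau must have one weight per layer")
  i <- rep(seq_len(n), times = L) + offset + n * rep(seq_len(L) - 1L, each = n)
  j <- rep(seq_len(n), times = L)
  Matrix::sparseMatrix(i = i, j = j, x = rep(tau, each = n), dims = c(N, n))
}

#' Node-to-node RWR similarity matrix
#'
#' Runs one random walk with restart per node (each node in turn as the
#' single seed) and aggregates the stationary distribution over layers,
#' giving a node-by-node matrix whose column `v` is the probability of
#' finding the walker at each node when restarting at `v`. Every column is a
#' probability distribution (sums to 1).
#'
#' For a multiplex network the seed's restart mass is spread over its layer
#' states by `tau` and the result is `n x n`. For a heterogeneous network
#' all `n + m` nodes are used as seeds (side A first); with a single seed the
#' full restart mass goes to the seed's own side, and each column is a
#' distribution over all `n + m` nodes.
#'
#' @inheritParams supraTransition
#' @param seeds optional subset of node indices (in `nodeNames(x)` order) to
#'   use as seeds; default all nodes.
#' @return a dense numeric matrix (nodes x seeds) with dimnames.
#' @examples
#' mux <- readMultiplex(c("1 a b", "1 b c"))
#' sim <- rwrSimilarity(mux)
#' colSums(sim)   # all 1
#' @export
setGeneric("rwrSimilarity", function(x, params = rwrParams(), seeds = NULL)
  standardGeneric("rwrSimilarity"))

#' @rdname rwrSimilarity
setMethod("rwrSimilarity", "MultiplexNetwork",
          function(x, params = rwrParams(), seeds = NULL) {
  n <- nNodes(x); L <- nLayers(x)
  st <- supraTransition(x, params)
  P0 <- .restartBlock(n * L, n, L, params$tau)
  if (!is.null(seeds)) P0 <- P0[, seeds, drop = FALSE]
  P <- rwrSolve(st, as.matrix(P0), params)
  sim <- matrix(0, n, ncol(P))
  for (a in seq_len(L)) sim <- sim + P[(a - 1) * n + seq_len(n), , drop = FALSE]
  rownames(sim) <- nodeNames(x)
  colnames(sim) <- nodeNames(x)[if (is.null(seeds)) seq_len(n) else seeds]
  sim
})

#' @rdname rwrSimilarity
setMethod("rwrSimilarity", "MultiplexHeterogeneousNetwork",
          function(x, params = rwrParams(), seeds = NULL) {
  n <- nNodes(x@muxA); m <- nNodes(x@muxB)
  LA <- nLayers(x@muxA); LB <- nLayers(x@muxB)
  N <- n * LA + m * LB
  st <- supraTransition(x, params)
  P0 <- cbind(.restartBlock(N, n, LA, params$tau),
              .restartBlock(N, m, LB, if (is.null(params$tau)) NULL else
                rep(1 / LB, LB), offset = n * LA))
  if (!is.null(seeds)) P0 <- P0[, seeds, drop = FALSE]
  P <- rwrSolve(st, as.matrix(P0), params)
  nt <- n + m
  sim <- matrix(0, nt, ncol(P))
  for (a in seq_len(LA))
    sim[seq_len(n), ] <- sim[seq_len(n), , drop = FALSE] +
      P[(a - 1) * n + seq_len(n), , drop = FALSE]
  for (b in seq_len(LB))
    sim[n + seq_len(m), ] <- sim[n + seq_len(m), , drop = FALSE] +
      P[n * LA + (b - 1) * m + seq_len(m), , drop = FALSE]
  rownames(sim) <- nodeNames(x)
  colnames(sim) <- nodeNames(x)[if (is.null(seeds)) seq_len(nt) else seeds]
  sim
})

#' Truncate similarity columns to their largest entries
#'
#' Keeps, for every seed (column), the `nMax` largest probabilities and
#' renormalizes them to sum 1. The tail of an RWR distribution decays fast,
#' so the truncated distribution retains almost all the mass while shrinking
#' the positive-sampling support used by the trainer. Ties are broken by
#' ascending node index. By default the seed itself is excluded from its own
#' support before truncation (sampling a node as its own positive context is
#' uninformative); set `excludeSeed = FALSE` for plain column truncation.
#'
#' @param sim similarity matrix (nodes x seeds), e.g. from [rwrSimilarity()].
#' @param nMax maximum support size per seed (>= 1). `nMax >= n` keeps all
#'   positive entries.
#' @param excludeSeed drop the diagonal entry of square matrices first
#'   (default `TRUE`).
#' @return an object of class `"truncatedSimilarity"`: a list with `support`
#'   (integer node indices per seed), `prob` (renormalized probabilities),
#'   `cumprob` (their cumulative sums), `nNodes`, `nMax`, `nodes` (labels).
#' @examples
#' sim <- matrix(c(0.5, 0.3, 0.1, 0.06, 0.04), ncol = 1)
#' truncateSimilarity(sim, 2, excludeSeed = FALSE)$prob[[1]]   # 0.625 0.375
#' @export
truncateSimilarity <- function(sim, nMax, excludeSeed = TRUE) {
  sim <- as.matrix(sim)
  stopifnot(nMax >= 1)
  nNod <- nrow(sim); nSeed <- ncol(sim)
  square <- nNod == nSeed
  support <- vector("list", nSeed)
  prob <- vector("list", nSeed)
  for (s in seq_len(nSeed)) {
    p <- sim[, s]
    if (excludeSeed && square) p[s] <- 0
    pos <- which(p > 0)
    if (length(pos) > nMax) {
      ord <- order(-p[pos], pos)          # ties: ascending node index
      pos <- sort(pos[ord[seq_len(nMax)]])
    }
    support[[s]] <- pos
    tot <- sum(p[pos])
    prob[[s]] <- if (tot > 0) p[pos] / tot else numeric(0)
    if (tot == 0) support[[s]] <- integer(0)
  }
  structure(list(support = support,
                 prob = prob,
                 cumprob = lapply(prob, cumsum),
                 nNodes = nNod,
                 nMax = as.integer(nMax),
                 nodes = rownames(sim)),
            class = "truncatedSimilarity")
}

#' @export
print.truncatedSimilarity <- function(x, ...) {
  sz <- lengths(x$support)
  cat(sprintf("truncatedSimilarity: %d seeds over %d nodes, support <= %d (median %d)\n",
              length(x$support), x$nNodes, x$nMax, as.integer(stats::median(sz))))
  invisible(x)
}

#' Export a (truncated) similarity as a three-column table
#'
#' @param sim similarity matrix or `"truncatedSimilarity"` object.
#' @return data.frame with columns `seed`, `node`, `probability`.
#' @export
similarityTable <- function(sim) {
  if (inherits(sim, "truncatedSimilarity")) {
    seeds <- rep(seq_along(sim$support), lengths(sim$support))
    nodes <- unlist(sim$support)
    prob <- unlist(sim$prob)
    lab <- sim$nodes
    if (is.null(lab)) lab <- as.character(seq_len(sim$nNodes))
    return(data.frame(seed = lab[pmin(seeds, length(lab))], node = lab[nodes],
                      probability = prob, stringsAsFactors = FALSE))
  }
  sim <- as.matrix(sim)
  idx <- which(sim > 0, arr.ind = TRUE)
  lab <- rownames(sim); if (is.null(lab)) lab <- as.character(seq_len(nrow(sim)))
  clab <- colnames(sim); if (is.null(clab)) clab <- as.character(seq_len(ncol(sim)))
  data.frame(seed = clab[idx[, 2]], node = lab[idx[, 1]],
             probability = sim[idx], stringsAsFactors = FALSE)
}
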