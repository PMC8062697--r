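# Seeded stochastic-block-model generators for multiplex and
# multiplex-heterogeneous fixtures with planted community structure.

#' Specification of a multiplex stochastic block model
#'
#' @param n number of nodes.
#' @param L number of layers.
#' @param blocks community sizes (must sum to `n`).
#' @param pIn within-community edge probability per layer; default 0.1.
#' @param pOut between-community edge probability; default 0.01.
#' @param layerCorr probability that a node keeps its base community in a
#'   given layer (otherwise its community is redrawn uniformly); 1 means all
#'   layers share the same planted partition. Default 1.
#' @return a list of class `"sbmSpec"`.
#' @export
sbmSpec <- function(n = 300L, L = 3L, blocks = c(150L, 150L), pIn = 0.1,
                    pOut = 0.01, layerCorr = 1.0) {
  stopifnot(n >= 2, L >= 1, sum(blocks) == n, all(blocks >= 1),
            pIn >= 0, pIn <= 1, pOut >= 0, pOut <= 1,
            layerCorr >= 0, layerCorr <= 1)
  structure(list(n = as.integer(n), L = as.integer(L),
                 blocks = as.integer(blocks), pIn = pIn, pOut = pOut,
                 layerCorr = layerCorr),
            class = "sbmSpec")
}

.sbmLayer <- function(z, pIn, pOut, iu, ju, n) {
  same <- z[iu] == z[ju]
  p <- ifelse(same, pIn, pOut)
  sel <- stats::runif(length(iu)) < p
  if (!any(sel)) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                             x = numeric(0), dims = c(n, n)))
  up <- Matrix::sparseMatrix(i = iu[sel], j = ju[sel], x = 1, dims = c(n, n))
  up + Matrix::t(up)
}

#' Generate a multiplex stochastic block model
#'
#' Draws `L` SBM layers over a shared node universe. Per layer, each node's
#' community is its base community with probability `layerCorr`, otherwise
#' redrawn uniformly over the blocks; edges are then placed independently
#' with probability `pIn` within and `pOut` between the layer communities.
#' No self-loops; all layers symmetric. Node labels are `v1 ... vn`
#' (prefix configurable).
#'
#' @param spec an [sbmSpec()] object.
#' @param seed RNG seed.
#' @param prefix node-label prefix; default `"v"`.
#' @return list with `network` (a [MultiplexNetwork-class]) and
#'   `communities` (`n x L` integer matrix of per-layer community labels;
#'   column 0 base labels in attribute `"base"`).
#' @export
generateMultiplexSBM <- function(spec, seed = NULL, prefix = "v") {
  stopifnot(inherits(spec, "sbmSpec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n; L <- spec$L; K <- length(spec$blocks)
  z0 <- rep.int(seq_len(K), spec$blocks)
  iu <- rep(seq_len(n - 1), times = (n - 1):1)
  ju <- sequence((n - 1):1, from = 2:n)      # pairs with j > i
  comm <- matrix(0L, n, L)
  layers <- vector("list", L)
  for (a in seq_len(L)) {
    z <- z0
    redraw <- stats::runif(n) >= spec$layerCorr
    if (any(redraw)) z[redraw] <- sample.int(K, sum(redraw), replace = TRUE)
    comm[, a] <- z
    layers[[a]] <- .sbmLayer(z, spec$pIn, spec$pOut, iu, ju, n)
  }
  names(layers) <- paste0("l", seq_len(L))
  net <- .newMultiplex(layers, paste0(prefix, seq_len(n)))
  attr(comm, "base") <- z0
  list(network = net, communities = comm)
}

#' Generate a multiplex-heterogeneous stochastic block model
#'
#' Two multiplex SBMs (node prefixes `a` and `b`) joined by community-aligned
#' bipartite edges: a pair (i, j) is connected with probability `pBipIn` when
#' the base communities of i and j have the same block index, `pBipOut`
#' otherwise. Both specs must declare the same number of blocks.
#'
#' @param specA,specB [sbmSpec()] objects with equally many blocks.
#' @param pBipIn,pBipOut bipartite edge probabilities for matched/unmatched
#'   blocks; defaults 0.1 / 0.01.
#' @param seed RNG seed.
#' @return list with `network` (a [MultiplexHeterogeneousNetwork-class]),
#'   `communitiesA`, `communitiesB` (per-layer label matrices as in
#'   [generateMultiplexSBM()]).
#' @export
generateMHSBM <- function(specA, specB, pBipIn = 0.1, pBipOut = 0.01,
                          seed = NULL) {
  stopifnot(inherits(specA, "sbmSpec"), inherits(specB, "sbmSpec"),
            pBipIn >= 0, pBipIn <= 1, pBipOut >= 0, pBipOut <= 1)
  if (length(specA$blocks) != length(specB$blocks))
    stop("the two specs must have the same number of blocks")
  if (!is.null(seed)) set.seed(seed)
  gA <- generateMultiplexSBM(specA, seed = NULL, prefix = "a")
  gB <- generateMultiplexSBM(specB, seed = NULL, prefix = "b")
  zA <- attr(gA$communities, "base")
  zB <- attr(gB$communities, "base")
  n <- specA$n; m <- specB$n
  p <- ifelse(outer(zA, zB, `==`), pBipIn, pBipOut)
  sel <- which(matrix(stats::runif(n * m), n, m) < p)
  bip <- Matrix::sparseMatrix(i = (sel - 1) %% n + 1, j = (sel - 1) %/% n + 1,
                              x = 1, dims = c(n, m))
  net <- .newHeterogeneous(gA$network, gB$network, bip)
  list(network = net, communitiesA = gA$communities, communitiesB = gB$communities)
}
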