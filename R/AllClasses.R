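#' @import methods
#' @importFrom Matrix Matrix sparseMatrix Diagonal colSums rowSums t diag bdiag
NULL

#' MultiplexNetwork: several layers over one node set
#'
#' An undirected multiplex network: `L` layers sharing the same universe of
#' `n` nodes. Each layer is stored as a symmetric sparse adjacency matrix with
#' zero diagonal and non-negative weights; a node may be isolated in some
#' layers (the node universe is the union of the layer node sets).
#'
#' @slot layers named list of `dgCMatrix` adjacency matrices, one per layer,
#'   all `n x n` in the same node order.
#' @slot nodes character vector of node labels; position gives the 0-free
#'   1-based node index used throughout the package.
#'
#' @seealso [readMultiplex()], [generateMultiplexSBM()], [rwrSimilarity()]
#' @export
setClass("MultiplexNetwork",
  representation(layers = "list", nodes = "character"))

setValidity("MultiplexNetwork", function(object) {
  n <- length(object@nodes)
  if (length(object@layers) < 1L) return("a multiplex network needs at least one layer")
  if (anyDuplicated(object@nodes)) return("node labels must be unique")
  if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
    return("layers must carry unique names")
  for (nm in names(object@layers)) {
    A <- object@layers[[nm]]
    if (!methods::is(A, "dgCMatrix")) return(sprintf("layer '%s' is not a dgCMatrix", nm))
    if (nrow(A) != n || ncol(A) != n) return(sprintf("layer '%s' has wrong dimensions", nm))
    if (length(A@x) && any(A@x < 0)) return(sprintf("layer '%s' has negative weights", nm))
    if (any(Matrix::diag(A) != 0)) return(sprintf("layer '%s' has self-loops", nm))
    if (!Matrix::isSymmetric(A, tol = 1e-12)) return(sprintf("layer '%s' is not symmetric", nm))
  }
  TRUE
})

#' MultiplexHeterogeneousNetwork: two multiplexes joined by bipartite edges
#'
#' Two multiplex networks over disjoint node universes (e.g. genes and
#' diseases), connected by a set of weighted bipartite edges. The bipartite
#' edges are shared by every pair of layers: conceptually the heterogeneous
#' graph contains one identical copy of the bipartite graph per layer.
#'
#' @slot muxA,muxB the two [MultiplexNetwork-class] components (`n` and `m`
#'   nodes respectively).
#' @slot bipartite `n x m` sparse matrix of non-negative bipartite edge
#'   weights (rows = nodes of `muxA`, columns = nodes of `muxB`).
#'
#' @seealso [buildHeterogeneous()], [generateMHSBM()]
#' @export
setClass("MultiplexHeterogeneousNetwork",
  representation(muxA = "MultiplexNetwork", muxB = "MultiplexNetwork",
                 bipartite = "dgCMatrix"))

setValidity("MultiplexHeterogeneousNetwork", function(object) {
  n <- length(object@muxA@nodes); m <- length(object@muxB@nodes)
  if (length(intersect(object@muxA@nodes, object@muxB@nodes)))
    return("node universes of the two multiplexes must be disjoint")
  if (nrow(object@bipartite) != n || ncol(object@bipartite) != m)
    return("bipartite matrix dimensions do not match the two node universes")
  if (length(object@bipartite@x) && any(object@bipartite@x < 0))
    return("bipartite weights must be non-negative")
  TRUE
})

#' SupraTransition: column-stochastic walk matrix over node-layer states
#'
#' The transition matrix of the random walk on the flattened multiplex (or
#' multiplex-heterogeneous) graph. States are (node, layer) pairs, ordered
#' layer-major within each network side (side A states first for the
#' heterogeneous case). Every non-dangling column sums to 1; dangling columns
#' (nodes isolated everywhere with no bipartite escape) are flagged and the
#' solver routes their mass back to the restart vector.
#'
#' @slot matrix sparse column-stochastic matrix over the states.
#' @slot stateMap data.frame with columns `state`, `node` (label), `layer`,
#'   `side` ("A"/"B") mapping state indices to (node, layer) pairs.
#' @slot dangling logical vector flagging all-zero columns.
#'
#' @seealso [supraTransition()], [rwrSolve()]
#' @export
setClass("SupraTransition",
  representation(matrix = "dgCMatrix", stateMap = "data.frame", dangling = "logical"))

setValidity("SupraTransition", function(object) {
  N <- ncol(object@matrix)
  if (nrow(object@matrix) != N) return("supra matrix must be square")
  if (nrow(object@stateMap) != N) return("state map does not cover all states")
  if (length(object@dangling) != N) return("dangling flag has wrong length")
  cs <- Matrix::colSums(object@matrix)
  bad <- !object@dangling & abs(cs - 1) > 1e-12
  if (any(bad)) return(sprintf("%d non-dangling columns do not sum to 1", sum(bad)))
  if (any(object@dangling & cs > 1e-12)) return("dangling columns must be all-zero")
  TRUE
})

## ---- accessors ----

#' Accessors for network objects
#'
#' `nNodes()` and `nLayers()` count nodes/layers, `nodeNames()` and
#' `layerNames()` return labels, `layerAdjacency()` extracts one layer's
#' sparse adjacency matrix. For heterogeneous networks, `multiplexA()`,
#' `multiplexB()` and `bipartiteMatrix()` return the components;
#' `nNodes()` is the total `n + m` and `nodeNames()` concatenates side A
#' before side B (the row order of embedding matrices).
#'
#' @param x a [MultiplexNetwork-class] or
#'   [MultiplexHeterogeneousNetwork-class] object.
#' @param layer layer name or index.
#' @return counts, label vectors, or sparse matrices as described.
#' @examples
#' mux <- generateMultiplexSBM(sbmSpec(n = 20, L = 2, blocks = c(10, 10)),
#'                             seed = 1)$network
#' nNodes(mux); nLayers(mux); head(nodeNames(mux))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
#' @rdname accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))
#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname accessors
#' @export
setGeneric("layerAdjacency", function(x, layer) standardGeneric("layerAdjacency"))
#' @rdname accessors
#' @export
setGeneric("multiplexA", function(x) standardGeneric("multiplexA"))
#' @rdname accessors
#' @export
setGeneric("multiplexB", function(x) standardGeneric("multiplexB"))
#' @rdname accessors
#' @export
setGeneric("bipartiteMatrix", function(x) standardGeneric("bipartiteMatrix"))

#' @rdname accessors
setMethod("nNodes", "MultiplexNetwork", function(x) length(x@nodes))
#' @rdname accessors
setMethod("nLayers", "MultiplexNetwork", function(x) length(x@layers))
#' @rdname accessors
setMethod("nodeNames", "MultiplexNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("layerNames", "MultiplexNetwork", function(x) names(x@layers))
#' @rdname accessors
setMethod("layerAdjacency", "MultiplexNetwork", function(x, layer) x@layers[[layer]])

#' @rdname accessors
setMethod("nNodes", "MultiplexHeterogeneousNetwork",
          function(x) length(x@muxA@nodes) + length(x@muxB@nodes))
#' @rdname accessors
setMethod("nodeNames", "MultiplexHeterogeneousNetwork",
          function(x) c(x@muxA@nodes, x@muxB@nodes))
#' @rdname accessors
setMethod("multiplexA", "MultiplexHeterogeneousNetwork", function(x) x@muxA)
#' @rdname accessors
setMethod("multiplexB", "MultiplexHeterogeneousNetwork", function(x) x@muxB)
#' @rdname accessors
setMethod("bipartiteMatrix", "MultiplexHeterogeneousNetwork", function(x) x@bipartite)

setMethod("show", "MultiplexNetwork", function(object) {
  ne <- vapply(object@layers, function(A) length(A@x) / 2, numeric(1))
  cat(sprintf("MultiplexNetwork: %d nodes, %d layers\n",
              length(object@nodes), length(object@layers)))
  for (nm in names(object@layers))
    cat(sprintf("  layer '%s': %d edges\n", nm, as.integer(ne[[nm]])))
})

setMethod("show", "MultiplexHeterogeneousNetwork", function(object) {
  cat(sprintf("MultiplexHeterogeneousNetwork: %d + %d nodes, %d bipartite edges\n",
              length(object@muxA@nodes), length(object@muxB@nodes),
              length(object@bipartite@x)))
  cat("-- side A --\n"); show(object@muxA)
  cat("-- side B --\n"); show(object@muxB)
})

setMethod("show", "SupraTransition", function(object) {
  cat(sprintf("SupraTransition: %d states (%d dangling), %d nonzeros\n",
              ncol(object@matrix), sum(object@dangling), length(object@matrix@x)))
})

## internal constructors -------------------------------------------------

# Coerce any Matrix to general sparse column format.
.asDgc <- function(m) {
  as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# layers: named list of square matrices (same node order); nodes: labels.
.newMultiplex <- function(layers, nodes) {
  layers <- lapply(layers, .asDgc)
  for (i in seq_along(layers)) dimnames(layers[[i]]) <- list(nodes, nodes)
  methods::new("MultiplexNetwork", layers = layers, nodes = nodes)
}

.newHeterogeneous <- function(muxA, muxB, bipartite) {
  bip <- .asDgc(bipartite)
  dimnames(bip) <- list(muxA@nodes, muxB@nodes)
  methods::new("MultiplexHeterogeneousNetwork", muxA = muxA, muxB = muxB,
               bipartite = bip)
}
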