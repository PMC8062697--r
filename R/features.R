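# Edge feature operators and classical link-prediction heuristics.

.operatorNames <- c("hadamard", "average", "weighted_l1", "weighted_l2", "cosine")

#' Edge-feature operators on a pair of node embeddings
#'
#' Maps two d-dimensional node embeddings to a d-dimensional edge feature
#' `g(u, v)`. Component-wise definitions (`verbatim = TRUE`, the printed
#' forms):
#' \itemize{
#'   \item hadamard: `f_i(u) * f_i(v) / 2`
#'   \item average: `f_i(u) + f_i(v)`
#'   \item weighted_l1: `|f_i(u) - f_i(v)|`
#'   \item weighted_l2: `|f_i(u) - f_i(v)|^2`
#'   \item cosine: `f_i(u) * f_i(v) / (||f(u)|| ||f(v)||)` with full-vector
#'     Euclidean norms; the components sum to the classical cosine similarity.
#' }
#' `verbatim = FALSE` switches hadamard/average to the conventional variants
#' (`f_i(u) * f_i(v)` and `(f_i(u) + f_i(v)) / 2`). All operators are
#' symmetric in `(u, v)`.
#'
#' @param fu,fv numeric vectors of equal length.
#' @param name one of `"hadamard"`, `"average"`, `"weighted_l1"`,
#'   `"weighted_l2"`, `"cosine"`.
#' @param verbatim use the printed operator forms (default `TRUE`).
#' @return numeric feature vector of the same length. A zero-norm input to
#'   cosine yields a zero vector with a warning.
#' @examples
#' edgeOperator(c(2, 4), c(3, 1), "hadamard")      # 3 2
#' sum(edgeOperator(c(2, 4), c(3, 1), "cosine"))   # 0.7071
#' @export
edgeOperator <- function(fu, fv, name = .operatorNames, verbatim = TRUE) {
  name <- match.arg(name)
  if (length(fu) != length(fv)) stop("embedding vectors must have equal length")
  switch(name,
    hadamard = if (verbatim) fu * fv / 2 else fu * fv,
    average = if (verbatim) fu + fv else (fu + fv) / 2,
    weighted_l1 = abs(fu - fv),
    weighted_l2 = (fu - fv)^2,
    cosine = {
      nu <- sqrt(sum(fu^2)); nv <- sqrt(sum(fv^2))
      if (nu == 0 || nv == 0) {
        warning("zero-norm embedding in cosine operator; returning zeros")
        rep(0, length(fu))
      } else fu * fv / (nu * nv)
    })
}

# Vectorized operator over many pairs: rows of `pairs` index rows of W.
.edgeFeatures <- function(W, pairs, name, verbatim = TRUE) {
  name <- match.arg(name, .operatorNames)
  U <- W[pairs[, 1], , drop = FALSE]
  V <- W[pairs[, 2], , drop = FALSE]
  switch(name,
    hadamard = if (verbatim) U * V / 2 else U * V,
    average = if (verbatim) U + V else (U + V) / 2,
    weighted_l1 = abs(U - V),
    weighted_l2 = (U - V)^2,
    cosine = {
      nu <- sqrt(rowSums(U^2)); nv <- sqrt(rowSums(V^2))
      sc <- ifelse(nu > 0 & nv > 0, 1 / (nu * nv), 0)
      U * V * sc
    })
}

#' Classical link-prediction heuristic scores
#'
#' Neighbourhood-based scores of a candidate edge `(u, v)` in a single
#' layer. With `N(x)` the neighbour set of `x` in the layer:
#' \itemize{
#'   \item `jc` (Jaccard coefficient): `|N(u) n N(v)| / |N(u) u N(v)|`
#'     (0 when the union is empty);
#'   \item `cn` (common neighbours): `|N(u) n N(v)|`;
#'   \item `aa` (Adamic-Adar): `sum over common neighbours t of
#'     1 / log |N(t)|` (natural log; degree-1 common neighbours are skipped);
#'   \item `pa` (preferential attachment): `|N(u)| * |N(v)|`.
#' }
#'
#' @param adj a layer adjacency matrix (e.g. [layerAdjacency()]) or a
#'   [MultiplexNetwork-class] (then `layer` selects the layer).
#' @param u,v node labels or indices.
#' @param name one of `"jc"`, `"cn"`, `"aa"`, `"pa"`.
#' @param layer layer name/index when `adj` is a multiplex network.
#' @return a scalar score.
#' @examples
#' mux <- readMultiplex(c("1 a b", "1 a c", "1 b c", "1 c d"))
#' heuristicScore(mux, "a", "d", "jc")   # 0.5
#' heuristicScore(mux, "a", "d", "aa")   # 1 / log(3)
#' @export
heuristicScore <- function(adj, u, v, name = c("jc", "cn", "aa", "pa"), layer = 1L) {
  name <- match.arg(name)
  if (methods::is(adj, "MultiplexNetwork")) {
    if (is.character(u)) u <- match(u, nodeNames(adj))
    if (is.character(v)) v <- match(v, nodeNames(adj))
    adj <- layerAdjacency(adj, layer)
  }
  if (is.na(u) || is.na(v)) stop("unknown node label")
  Nu <- which(adj[, u] != 0); Nv <- which(adj[, v] != 0)
  common <- intersect(Nu, Nv)
  switch(name,
    jc = {
      uni <- union(Nu, Nv)
      if (!length(uni)) 0 else length(common) / length(uni)
    },
    cn = length(common),
    aa = {
      if (!length(common)) return(0)
      degs <- Matrix::colSums(adj[, common, drop = FALSE] != 0)
      sum(1 / log(degs[degs > 1]))
    },
    pa = length(Nu) * length(Nv))
}

#' Average per-layer scores or feature vectors
#'
#' Arithmetic mean over layers, component-wise for vectors: the aggregation
#' used for the per-layer heuristic baselines (JC-av, CN-av, ...) and for
#' per-layer monoplex embeddings.
#'
#' @param values list of per-layer scalars or equal-length numeric vectors.
#' @return the mean value (same shape as one element).
#' @examples
#' averageOverLayers(list(0.2, 0.4))              # 0.3
#' averageOverLayers(list(c(1, 2), c(3, 4)))      # 2 3
#' @export
averageOverLayers <- function(values) {
  if (!length(values)) stop("no layer values to average")
  Reduce(`+`, values) / length(values)
}
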