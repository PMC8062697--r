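# Edge-list and embedding file input/output.
#
# Dialect: one edge per line, whitespace-separated fields
#   multiplex:  layer source target [weight]
#   bipartite:  left right [weight]
# '#' starts a comment; blank lines are ignored; weight defaults to 1.

.readLinesAny <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  as.character(x)
}

.splitFields <- function(lines) {
  raw <- sub("#.*$", "", lines)
  keep <- which(trimws(raw) != "")
  list(fields = strsplit(trimws(raw[keep]), "[ \t]+"), lineno = keep)
}

#' Read a multiplex network from an edge list
#'
#' Parses a whitespace-separated edge list with fields
#' `layer source target [weight]` (weight defaults to 1; `#` comments
#' allowed). The node universe is the union of endpoints over all layers, in
#' first-appearance order; layer order is first appearance of the layer
#' identifier. Self-loops are dropped, duplicate edges within a layer are
#' collapsed keeping the maximum weight, and edges are undirected.
#'
#' @param x path to a file, or a character vector of lines.
#' @param directed must be `FALSE`; only undirected layers are supported.
#' @return a [MultiplexNetwork-class] object.
#' @examples
#' mux <- readMultiplex(c("1 a b", "1 b c", "2 a c"))
#' nNodes(mux); nLayers(mux)
#' @export
readMultiplex <- function(x, directed = FALSE) {
  if (isTRUE(directed)) stop("directed layers are not supported")
  parsed <- .splitFields(.readLinesAny(x))
  fields <- parsed$fields
  if (!length(fields)) stop("empty input: no edges, zero layers")
  nf <- lengths(fields)
  bad <- which(nf < 3L | nf > 4L)
  if (length(bad))
    stop(sprintf("malformed edge line %d: expected 'layer source target [weight]'",
                 parsed$lineno[bad[1]]))
  lay <- vapply(fields, `[`, character(1), 1L)
  src <- vapply(fields, `[`, character(1), 2L)
  tgt <- vapply(fields, `[`, character(1), 3L)
  w <- vapply(seq_along(fields), function(k)
    if (nf[k] == 4L) suppressWarnings(as.numeric(fields[[k]][4L])) else 1.0,
    numeric(1))
  badw <- which(is.na(w) | w <= 0)
  if (length(badw))
    stop(sprintf("malformed edge line %d: weight must be a positive number",
                 parsed$lineno[badw[1]]))
  nodes <- unique(c(rbind(src, tgt)))        # first-appearance order
  layers <- unique(lay)
  n <- length(nodes)
  si <- match(src, nodes); ti <- match(tgt, nodes)
  adj <- lapply(layers, function(l) {
    k <- which(lay == l & si != ti)          # drop self-loops
    if (!length(k)) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                x = numeric(0), dims = c(n, n)))
    i <- pmin(si[k], ti[k]); j <- pmax(si[k], ti[k])
    key <- (i - 1) * n + j
    wmax <- tapply(w[k], key, max)           # duplicates: keep max weight
    key <- as.numeric(names(wmax))
    i <- (key - 1) %/% n + 1; j <- (key - 1) %% n + 1
    up <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(wmax), dims = c(n, n))
    up + Matrix::t(up)
  })
  names(adj) <- layers
  .newMultiplex(adj, nodes)
}

#' Write a multiplex network as an edge list
#'
#' Inverse of [readMultiplex()]: each undirected edge is written once
#' (`layer source target weight`). Reading the written file reproduces the
#' same network.
#'
#' @param mux a [MultiplexNetwork-class] object.
#' @param file path or connection; if `NULL`, the lines are returned.
#' @return invisibly (or visibly for `file = NULL`) the character lines.
#' @export
writeMultiplex <- function(mux, file = NULL) {
  nodes <- nodeNames(mux)
  lines <- unlist(lapply(layerNames(mux), function(l) {
    A <- layerAdjacency(mux, l)
    up <- Matrix::triu(A)
    sm <- Matrix::summary(.asDgc(up))
    if (!nrow(sm)) return(character(0))
    sprintf("%s %s %s %s", l, nodes[sm$i], nodes[sm$j],
            formatC(sm$x, format = "g", digits = 10))
  }))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Join two multiplex networks with bipartite edges
#'
#' Builds a [MultiplexHeterogeneousNetwork-class] from two multiplexes and a
#' bipartite edge list (`left right [weight]`, left labels in `muxA`, right
#' labels in `muxB`). Lines referencing unknown labels are skipped and the
#' skip count is reported with a message; duplicate pairs keep the maximum
#' weight. An empty bipartite set is allowed with a warning (the random walk
#' then never crosses between the two multiplexes).
#'
#' @param muxA,muxB the two [MultiplexNetwork-class] components.
#' @param bipartite path, character lines, or a 2-3 column data.frame
#'   (`left`, `right`, optional `weight`).
#' @return a [MultiplexHeterogeneousNetwork-class]; the number of retained
#'   bipartite edges is reported via `message()`.
#' @examples
#' a <- readMultiplex(c("1 a b")); b <- readMultiplex(c("1 x y"))
#' net <- buildHeterogeneous(a, b, c("a x", "b y"))
#' @export
buildHeterogeneous <- function(muxA, muxB, bipartite = character(0)) {
  if (is.data.frame(bipartite)) {
    df <- bipartite
    lft <- as.character(df[[1]]); rgt <- as.character(df[[2]])
    w <- if (ncol(df) >= 3) as.numeric(df[[3]]) else rep(1, nrow(df))
  } else {
    parsed <- .splitFields(.readLinesAny(bipartite))
    fields <- parsed$fields
    nf <- lengths(fields)
    bad <- which(nf < 2L | nf > 3L)
    if (length(bad))
      stop(sprintf("malformed bipartite line %d: expected 'left right [weight]'",
                   parsed$lineno[bad[1]]))
    lft <- vapply(fields, `[`, character(1), 1L)
    rgt <- vapply(fields, `[`, character(1), 2L)
    w <- vapply(seq_along(fields), function(k)
      if (nf[k] == 3L) as.numeric(fields[[k]][3L]) else 1.0, numeric(1))
  }
  n <- nNodes(muxA); m <- nNodes(muxB)
  i <- match(lft, nodeNames(muxA)); j <- match(rgt, nodeNames(muxB))
  known <- !is.na(i) & !is.na(j)
  if (any(!known))
    message(sprintf("skipped %d bipartite edge(s) with unknown labels", sum(!known)))
  bip <- if (any(known)) {
    key <- (i[known] - 1) * m + j[known]
    wmax <- tapply(w[known], key, max)
    key <- as.numeric(names(wmax))
    Matrix::sparseMatrix(i = (key - 1) %/% m + 1, j = (key - 1) %% m + 1,
                         x = as.numeric(wmax), dims = c(n, m))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, m))
  }
  if (!length(bip@x))
    warning("empty bipartite edge set: the two multiplexes are disconnected")
  message(sprintf("%d bipartite edge(s) retained", length(bip@x)))
  .newHeterogeneous(muxA, muxB, bip)
}

#' Write / read node embeddings (word2vec-style text)
#'
#' The file starts with a header line `n d`, followed by one line per node:
#' `label v1 ... vd`. The round trip preserves values to at least 6 decimal
#' places.
#'
#' @param W numeric matrix, one row per node, with row names as node labels.
#' @param file path or connection; `NULL` returns the lines.
#' @return `writeEmbeddings()` the lines (invisibly when writing to a file);
#'   `readEmbeddings()` the embedding matrix with node labels as row names.
#' @export
writeEmbeddings <- function(W, file = NULL) {
  W <- as.matrix(W)
  labels <- rownames(W)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(W)))
  lines <- c(sprintf("%d %d", nrow(W), ncol(W)),
             vapply(seq_len(nrow(W)), function(i)
               paste(c(labels[i], formatC(W[i, ], format = "g", digits = 10)),
                     collapse = " "), character(1)))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' @rdname writeEmbeddings
#' @param x path or character lines to read.
#' @export
readEmbeddings <- function(x) {
  lines <- .readLinesAny(x)
  if (!length(lines)) stop("empty embedding file")
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(hdr) != 2L) stop("embedding header must be 'n d'")
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  body <- lines[-1][trimws(lines[-1]) != ""]
  if (length(body) != n)
    stop(sprintf("embedding format error: header says %d rows, found %d", n, length(body)))
  W <- matrix(0, n, d)
  labels <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(body[i]), "[ \t]+")[[1]]
    if (length(f) != d + 1L)
      stop(sprintf("embedding format error at row %d: expected %d values, found %d",
                   i, d, length(f) - 1L))
    labels[i] <- f[1]
    W[i, ] <- as.numeric(f[-1])
  }
  rownames(W) <- labels
  W
}
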