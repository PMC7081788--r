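#' Construct a network layer
#'
#' A layer is a weighted graph over an explicit node set. Directed layers
#' store every ordered edge; undirected layers store each unordered pair
#' once (endpoints in canonical sorted order) with symmetric semantics.
#' Edge weights are nonnegative interaction frequencies.
#'
#' @param name Layer name (single string).
#' @param edges A data frame with character columns `source`, `target` and a
#'   numeric column `weight`. Duplicate source--target rows are summed:
#'   weights are event frequencies, so repeated observations accumulate.
#' @param directed Logical; is the layer directed?
#' @param nodes Character vector of node IDs. Defaults to the edge
#'   endpoints; nodes listed here but absent from `edges` are isolates and
#'   keep zero degree (every node must receive a rank in every layer).
#' @return An object of class `mplx_layer`: a list with elements `name`,
#'   `directed`, `nodes`, and `edges` (aggregated, canonicalised).
#' @examples
#' layer("groom", data.frame(source = "a", target = "b", weight = 2),
#'       directed = FALSE)
#' @export
layer <- function(name, edges, directed, nodes = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.logical(directed), length(directed) == 1L)
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    need <- c("source", "target")
    if (!all(need %in% names(edges)))
      stop("edge table must have 'source' and 'target' columns")
    if (is.null(edges$weight)) edges$weight <- 1
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$weight <- as.numeric(edges$weight)
    if (anyNA(edges$weight)) stop("non-numeric edge weight")
    if (any(edges$weight < 0)) stop("negative edge weight in layer '", name, "'")
    if (!directed) {
      swap <- edges$source > edges$target
      tmp <- edges$source[swap]
      edges$source[swap] <- edges$target[swap]
      edges$target[swap] <- tmp
    }
    edges <- aggregate(weight ~ source + target, data = edges, FUN = sum)
  } else {
    edges <- data.frame(source = character(0), target = character(0),
                        weight = numeric(0))
  }
  ends <- unique(c(edges$source, edges$target))
  nodes <- if (is.null(nodes)) ends else unique(as.character(nodes))
  if (!all(ends %in% nodes))
    stop("edge endpoints outside declared node set in layer '", name, "'")
  structure(list(name = name, directed = directed, nodes = nodes,
                 edges = edges[order(edges$source, edges$target), ,
                               drop = FALSE]),
            class = "mplx_layer")
}

#' @export
print.mplx_layer <- function(x, ...) {
  cat(sprintf("<layer '%s'> %s, %d nodes, %d edges\n", x$name,
              if (x$directed) "directed" else "undirected",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Restrict or extend a layer's node set
#'
#' @param x A `mplx_layer`.
#' @param nodes New node set; must contain all edge endpoints.
#' @return The layer with `nodes` replaced.
#' @keywords internal
layer_with_nodes <- function(x, nodes) {
  layer(x$name, x$edges, x$directed, nodes = nodes)
}

#' Weighted adjacency matrix of a layer
#'
#' Rows are sources, columns targets, indexed by the layer's node set.
#' Undirected layers yield a symmetric matrix.
#'
#' @param x A `mplx_layer`.
#' @return A dense N x N numeric matrix with dimnames.
#' @export
layer_adjacency <- function(x) {
  n <- length(x$nodes)
  A <- matrix(0, n, n, dimnames = list(x$nodes, x$nodes))
  if (nrow(x$edges) > 0) {
    i <- match(x$edges$source, x$nodes)
    j <- match(x$edges$target, x$nodes)
    A[cbind(i, j)] <- x$edges$weight
    if (!x$directed) A[cbind(j, i)] <- x$edges$weight
  }
  A
}

#' Convert a layer to an igraph graph
#'
#' Isolates are retained as zero-degree vertices.
#'
#' @param x A `mplx_layer`.
#' @return An `igraph` object with edge attribute `weight`.
#' @export
layer_igraph <- function(x) {
  g <- igraph::make_empty_graph(n = 0, directed = x$directed)
  g <- igraph::add_vertices(g, length(x$nodes), name = x$nodes)
  if (nrow(x$edges) > 0) {
    idx <- rbind(match(x$edges$source, x$nodes),
                 match(x$edges$target, x$nodes))
    g <- igraph::add_edges(g, as.vector(idx), weight = x$edges$weight)
  }
  g
}
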