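#' Weighted eigenvector centrality of a layer
#'
#' Dominant-eigenvector scores computed by power iteration on the weighted
#' adjacency matrix. The score of node i grows with the scores of the nodes
#' it directs edges to (out-going convention), which under a dominance
#' reading makes aggressors of well-connected aggressors rank high; for
#' undirected layers the adjacency is symmetric and the convention is moot.
#'
#' When the graph is not strongly connected the dominant eigenvector is not
#' guaranteed unique, so a uniform teleportation mass `epsilon` is spread
#' over all entries of the adjacency (Perron--Frobenius then applies). The
#' returned vector is normalised to unit maximum.
#'
#' @param x A `mplx_layer` with at least one node.
#' @param epsilon Teleportation mass added (as `epsilon / N` per entry)
#'   when the layer is not strongly connected. Default `1e-3`.
#' @param tol Convergence tolerance: successive max-normalised iterates
#'   must differ by less than `tol` in max norm. Default `1e-10`.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return Object of class `mplx_centrality`: list with `layer`, `metric`,
#'   and `values` (named numeric over all N nodes, max = 1).
#' @export
eigenvector_centrality <- function(x, epsilon = 1e-3, tol = 1e-10,
                                   max_iter = 100000L) {
  stopifnot(inherits(x, "mplx_layer"), length(x$nodes) >= 1)
  A <- layer_adjacency(x)
  n <- nrow(A)
  if (n == 1L)
    return(centrality_vector(x$name, "eigenvector",
                             setNames(1, x$nodes)))
  g <- layer_igraph(x)
  strongly_connected <- igraph::is_connected(g, mode = "strong")
  if (!strongly_connected) A <- A + epsilon / n
  # diagonal shift: leaves every eigenvector unchanged but makes the
  # dominant eigenvalue strictly largest in modulus, so the iteration
  # cannot oscillate on periodic (e.g. bipartite) graphs
  M <- A + diag(max(rowSums(A)), n)
  v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    v_new <- as.vector(M %*% v)
    m <- max(v_new)
    if (m <= 0) stop("eigenvector iteration collapsed to zero")
    v_new <- v_new / m
    if (max(abs(v_new - v)) < tol) {
      return(centrality_vector(x$name, "eigenvector",
                               setNames(v_new, x$nodes)))
    }
    v <- v_new
  }
  stop("eigenvector centrality failed to converge after ", max_iter,
       " iterations")
}

#' Weighted degree (strength) centrality of a layer
#'
#' `mode = "in"` gives the weighted in-strength (sum of weights of incoming
#' edges); `mode = "total"` gives in-strength plus out-strength. For
#' undirected layers total strength is the sum of incident edge weights.
#'
#' @param x A `mplx_layer`.
#' @param mode `"in"` (directed layers only) or `"total"`.
#' @return A `mplx_centrality` object.
#' @export
degree_centrality <- function(x, mode = c("in", "total")) {
  stopifnot(inherits(x, "mplx_layer"))
  mode <- match.arg(mode)
  if (mode == "in" && !x$directed)
    stop("in-degree centrality requires a directed layer")
  A <- layer_adjacency(x)
  vals <- if (mode == "in") colSums(A) else colSums(A) + rowSums(A)
  if (!x$directed) vals <- vals / 2  # A is symmetric: each edge counted once
  centrality_vector(x$name, paste0(mode, "_degree"),
                    setNames(as.numeric(vals), x$nodes))
}

#' Weighted betweenness centrality of a layer
#'
#' Shortest-path betweenness with edge distance `1 / weight` (stronger,
#' more frequent affiliation means a shorter path), the standard convention
#' for frequency-weighted affiliation networks. A pair's contribution is
#' split equally among all tied shortest paths. Counts are unnormalised;
#' only their ranks are consumed downstream.
#'
#' @param x A `mplx_layer`; all edge weights must be strictly positive.
#' @return A `mplx_centrality` object.
#' @export
betweenness_centrality <- function(x) {
  stopifnot(inherits(x, "mplx_layer"))
  if (nrow(x$edges) > 0 && any(x$edges$weight <= 0))
    stop("betweenness centrality requires strictly positive edge weights")
  g <- layer_igraph(x)
  vals <- if (nrow(x$edges) == 0) {
    setNames(rep(0, length(x$nodes)), x$nodes)
  } else {
    igraph::betweenness(g, directed = x$directed,
                        weights = 1 / igraph::E(g)$weight, normalized = FALSE)
  }
  centrality_vector(x$name, "betweenness",
                    setNames(as.numeric(vals), x$nodes))
}

#' Compute the configured centrality of a layer
#'
#' Dispatch helper mapping a metric name to the corresponding centrality
#' function.
#'
#' @param x A `mplx_layer`.
#' @param metric One of `"eigenvector"`, `"in_degree"`, `"total_degree"`,
#'   `"betweenness"`.
#' @param ... Passed on to the metric function.
#' @return A `mplx_centrality` object.
#' @export
layer_centrality <- function(x, metric, ...) {
  switch(match.arg(metric, c("eigenvector", "in_degree", "total_degree",
                             "betweenness")),
         eigenvector = eigenvector_centrality(x, ...),
         in_degree = degree_centrality(x, mode = "in"),
         total_degree = degree_centrality(x, mode = "total"),
         betweenness = betweenness_centrality(x))
}

centrality_vector <- function(layer, metric, values) {
  structure(list(layer = layer, metric = metric, values = values),
            class = "mplx_centrality")
}

#' @export
print.mplx_centrality <- function(x, ...) {
  cat(sprintf("<centrality> layer '%s', metric %s, %d nodes\n",
              x$layer, x$metric, length(x$values)))
  print(head(sort(x$values, decreasing = TRUE), 5))
  invisible(x)
}

#' Dense ranks of centrality values
#'
#' Rank 1 is the largest centrality. Exactly tied values share a rank and
#' the next distinct value takes the next integer, so ranks run 1..K where
#' K is the number of distinct values. To avoid spurious tie-breaking from
#' floating-point noise, values are compared after rounding to 12
#' significant digits.
#'
#' @param values A `mplx_centrality` object or a named numeric vector.
#' @return Named integer vector of ranks.
#' @examples
#' dense_rank(c(A = 0.4, B = 0.4, C = 0.2))  # A=1, B=1, C=2
#' @export
dense_rank <- function(values) {
  v <- if (inherits(values, "mplx_centrality")) values$values else values
  stopifnot(is.numeric(v), !is.null(names(v)))
  key <- signif(v, 12)
  lev <- sort(unique(key), decreasing = TRUE)
  setNames(match(key, lev), names(v))
}
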