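# Independent brute-force oracles. These deliberately avoid the package's
# code paths: generic O(N^3) agglomeration, dense eigendecomposition,
# explicit shortest-path enumeration.

# generic complete-linkage agglomeration on the full distance matrix;
# returns the partition (list of name vectors) for every cluster count k
naive_complete_linkage <- function(values) {
  n <- length(values)
  nms <- names(values)
  clusters <- as.list(seq_len(n))
  D <- abs(outer(values, values, "-"))
  partitions <- vector("list", n)
  partitions[[n]] <- lapply(clusters, function(ix) nms[ix])
  for (k in seq(n - 1, 1)) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (a in seq_len(m - 1)) for (b in seq((a + 1), m)) {
      d <- max(D[clusters[[a]], clusters[[b]], drop = FALSE])
      if (d < best[1]) best <- c(d, a, b)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
    partitions[[k]] <- lapply(clusters, function(ix) nms[ix])
  }
  partitions
}

# canonical string form of a partition, for set-equality comparison
partition_key <- function(groups) {
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                    character(1))), collapse = "|")
}

# dominant eigenvector by full eigendecomposition of the (possibly
# teleported) adjacency, normalised to unit maximum; the Perron root of a
# nonnegative matrix is its largest *real* eigenvalue (periodic graphs
# carry complex eigenvalues of equal modulus that must be skipped)
oracle_eigenvector <- function(A, teleport_eps = NULL) {
  n <- nrow(A)
  if (!is.null(teleport_eps)) A <- A + teleport_eps / n
  e <- eigen(A)
  cand <- which(abs(Im(e$values)) < 1e-8 * (1 + Mod(e$values)))
  i <- cand[which.max(Re(e$values)[cand])]
  v <- Re(e$vectors[, i])
  v <- v * sign(v[which.max(abs(v))])
  v / max(v)
}

# betweenness by explicit enumeration of all shortest paths
# dist: matrix of edge lengths (Inf where no edge), already directed or
# symmetric as appropriate
oracle_betweenness <- function(dist, directed) {
  n <- nrow(dist)
  D <- dist
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  tol <- 1e-9
  bt <- numeric(n)
  enumerate <- function(s, t) {
    paths <- list()
    walk <- function(u, path) {
      if (u == t) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (v in seq_len(n)) {
        if (is.finite(dist[u, v]) &&
            abs(D[s, u] + dist[u, v] - D[s, v]) < tol &&
            abs(D[s, v] + D[v, t] - D[s, t]) < tol) {
          walk(v, c(path, v))
        }
      }
    }
    walk(s, c(s))
    paths
  }
  pairs <- if (directed) {
    expand.grid(s = seq_len(n), t = seq_len(n))
  } else {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    data.frame(s = idx[, 1], t = idx[, 2])
  }
  for (r in seq_len(nrow(pairs))) {
    s <- pairs$s[r]; t <- pairs$t[r]
    if (s == t || !is.finite(D[s, t])) next
    paths <- enumerate(s, t)
    np <- length(paths)
    for (p in paths) {
      interior <- p[-c(1, length(p))]
      bt[interior] <- bt[interior] + 1 / np
    }
  }
  bt
}

# random weighted layer over n nodes
rand_layer <- function(n, directed, p = 0.5, name = "rand",
                       wmin = 0.5, wmax = 2) {
  nodes <- paste0("v", seq_len(n))
  pairs <- if (directed) {
    g <- expand.grid(i = seq_len(n), j = seq_len(n))
    g[g$i != g$j, ]
  } else {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    data.frame(i = idx[, 1], j = idx[, 2])
  }
  sel <- runif(nrow(pairs)) < p
  edges <- data.frame(source = nodes[pairs$i[sel]],
                      target = nodes[pairs$j[sel]],
                      weight = round(runif(sum(sel), wmin, wmax), 3))
  layer(name, edges, directed = directed, nodes = nodes)
}

# all dense rankings (ordered set partitions) of n items, as a matrix with
# one ranking per row
all_dense_rankings <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  keep <- apply(g, 1, function(r) all(seq_len(max(r)) %in% r))
  unname(g[keep, , drop = FALSE])
}

# small deterministic synthetic group used across tests
test_group <- function(n = 40, seed = 99, zero_effect = FALSE, ...) {
  generate_group(group_scenario(n = n, zero_effect = zero_effect, ...),
                 seed = seed)
}
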