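#' One-dimensional complete-linkage merge tree over centralities
#'
#' Agglomerative clustering of scalar centrality values. Each node starts
#' in its own cluster; the distance between two nodes is the absolute
#' difference of their centralities, and the distance between clusters is
#' the maximum pairwise distance (complete linkage). In one dimension with
#' complete linkage the optimal merge at every step joins two clusters that
#' are adjacent in sorted order, so clusters are always contiguous
#' intervals of the descending ordering; this is exploited for O(N^2) work
#' and is mathematically identical to generic agglomeration. Merge-height
#' ties are broken by merging the leftmost (highest-centrality) eligible
#' pair first, making the tree deterministic given the sorted order.
#'
#' @param values A `mplx_centrality` object or named numeric vector.
#' @return Object of class `mplx_linkage`: list with `order` (node names in
#'   descending centrality order; ties by name for determinism), `sorted`
#'   (their values), `heights` (the N-1 merge heights in merge order), and
#'   `cuts` (list indexed by tier count k of the cluster end-positions in
#'   the sorted order).
#' @export
build_linkage <- function(values) {
  v <- if (inherits(values, "mplx_centrality")) values$values else values
  stopifnot(is.numeric(v), !is.null(names(v)), length(v) >= 1)
  ord <- order(-v, names(v))
  sorted <- v[ord]
  n <- length(sorted)
  # clusters are contiguous intervals [starts[c], ends[c]] of the sorted
  # descending values; complete-linkage distance of adjacent clusters is
  # the range of their union
  starts <- seq_len(n)
  ends <- seq_len(n)
  cuts <- vector("list", n)
  cuts[[n]] <- ends
  heights <- numeric(max(n - 1L, 0L))
  k <- n
  while (k > 1L) {
    d <- sorted[starts[-k]] - sorted[ends[-1L]]
    j <- which.min(d)  # leftmost minimum
    heights[n - k + 1L] <- d[j]
    ends[j] <- ends[j + 1L]
    starts <- starts[-(j + 1L)]
    ends <- ends[-(j + 1L)]
    k <- k - 1L
    cuts[[k]] <- ends
  }
  structure(list(order = names(sorted), sorted = unname(sorted),
                 heights = heights, cuts = cuts),
            class = "mplx_linkage")
}

#' Cluster membership at a given tier count
#'
#' @param linkage A `mplx_linkage`.
#' @param k Number of tiers (1..N).
#' @return Named integer vector: tier index (1 = highest centrality) per
#'   node.
#' @export
cut_linkage <- function(linkage, k) {
  n <- length(linkage$order)
  stopifnot(k >= 1, k <= n)
  ends <- linkage$cuts[[k]]
  tier <- rep(seq_along(ends), diff(c(0L, ends)))
  setNames(tier, linkage$order)
}

#' Variance explained by a tiering
#'
#' r-squared where r is the Pearson correlation between the original
#' centralities and their tiered values (every node replaced by the mean
#' centrality of its tier). Because tiered values are tier means, this
#' equals the between-tier sum of squares over the total sum of squares.
#' Degenerate conventions keeping the measure total: constant input scores
#' 1 (a single tier represents it exactly); a constant tiered vector
#' against non-constant input scores 0.
#'
#' @param values A `mplx_centrality` object or named numeric vector.
#' @param assignment Named integer/character vector mapping every node to a
#'   tier label.
#' @return r-squared in \[0, 1\].
#' @export
explained_variance <- function(values, assignment) {
  v <- if (inherits(values, "mplx_centrality")) values$values else values
  stopifnot(!is.null(names(v)), all(names(v) %in% names(assignment)),
            all(names(assignment) %in% names(v)))
  a <- assignment[names(v)]
  sst <- sum((v - mean(v))^2)
  if (sst == 0) return(1)
  means <- tapply(v, a, mean)
  tiered <- as.numeric(means[as.character(a)])
  ssb <- sum((tiered - mean(v))^2)
  if (max(tiered) - min(tiered) == 0) return(0)
  min(max(ssb / sst, 0), 1)
}

#' Assign rank tiers by the explained-variance cut
#'
#' Cuts the complete-linkage tree at the minimum number of tiers k whose
#' tiered values explain at least `threshold` of the variance of the raw
#' centralities. Tier 1 holds the largest centralities; a node's tier index
#' is its layer rank fed into the Borda aggregation.
#'
#' @param values A `mplx_centrality` object or named numeric vector.
#' @param threshold Explained-variance threshold in (0, 1\]. Default 0.99;
#'   0.995 is used for robustness checks.
#' @return Object of class `mplx_tiers`: list with `layer`, `threshold`,
#'   `k` (selected tier count), `tier_of` (named integer vector),
#'   `tiered_value` (named numeric: tier mean per node), `tiers` (list of
#'   node-name vectors, tier 1 first), and `r2_path` (r-squared for every
#'   candidate tier count 1..N; non-decreasing, 1 at N).
#' @export
assign_tiers <- function(values, threshold = 0.99) {
  stopifnot(threshold > 0, threshold <= 1)
  v <- if (inherits(values, "mplx_centrality")) values$values else values
  lname <- if (inherits(values, "mplx_centrality")) values$layer
           else NA_character_
  linkage <- build_linkage(v)
  n <- length(linkage$order)
  sorted <- linkage$sorted
  sst <- sum((sorted - mean(sorted))^2)
  r2_path <- vapply(seq_len(n), function(k) {
    ends <- linkage$cuts[[k]]
    starts <- c(1L, ends[-length(ends)] + 1L)
    if (sst == 0) return(1)
    ssw <- sum(vapply(seq_along(ends), function(c) {
      seg <- sorted[starts[c]:ends[c]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
    min(max(1 - ssw / sst, 0), 1)
  }, numeric(1))
  k <- which(r2_path >= threshold)[1]
  tier_of <- cut_linkage(linkage, k)
  means <- tapply(v[linkage$order], tier_of, mean)
  tiered_value <- setNames(as.numeric(means[as.character(tier_of)]),
                           names(tier_of))
  tiers <- split(names(tier_of), tier_of)
  names(tiers) <- NULL
  structure(list(layer = lname, threshold = threshold, k = k,
                 tier_of = tier_of[names(v)],
                 tiered_value = tiered_value[names(v)],
                 tiers = tiers, r2_path = r2_path),
            class = "mplx_tiers")
}

#' @export
print.mplx_tiers <- function(x, ...) {
  cat(sprintf("<rank tiers> layer '%s': %d tiers over %d nodes (r2 = %.4f at threshold %.3f)\n",
              x$layer, x$k, length(x$tier_of), x$r2_path[x$k], x$threshold))
  invisible(x)
}
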