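#' Borda scores from per-layer ranks
#'
#' The Borda score of node i is its average rank across the L layers,
#' `b_i = (1/L) * sum_a b_{a,i}`. Layer ranks are integers, so scores are
#' rationals with denominator L; ties downstream are decided on the exact
#' integer rank totals, never on floating-point means.
#'
#' @param layer_ranks List of L named integer vectors (node -> rank), all
#'   covering the same node set.
#' @return Named numeric vector of Borda scores.
#' @examples
#' borda_scores(list(c(a = 1, b = 3), c(a = 3, b = 1)))
#' @export
borda_scores <- function(layer_ranks) {
  totals <- rank_totals(layer_ranks)
  totals / length(layer_ranks)
}

rank_totals <- function(layer_ranks) {
  stopifnot(is.list(layer_ranks), length(layer_ranks) >= 1)
  nodes <- names(layer_ranks[[1]])
  if (is.null(nodes)) stop("layer rank vectors must be named by node")
  totals <- setNames(numeric(length(nodes)), nodes)
  for (r in layer_ranks) {
    if (!setequal(names(r), nodes))
      stop("layer rank map does not cover the full node set")
    totals <- totals + r[nodes]
  }
  totals
}

#' Consensus ranks from Borda scores
#'
#' The node with the lowest score is ranked 1 (most central overall), the
#' second-lowest score is ranked 2, and so on. Tied scores share a rank and
#' ranks are dense over distinct score values, mirroring the within-layer
#' tie rule.
#'
#' @param scores Named numeric vector of Borda scores.
#' @return Named integer vector of consensus ranks.
#' @export
consensus_ranks <- function(scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  key <- signif(scores, 12)
  lev <- sort(unique(key))
  setNames(match(key, lev), names(scores))
}

#' Reversed consensus ranks
#'
#' `reversed = max(rank) - rank`: the least central node scores 0 and the
#' most central node the largest value, giving a nonnegative count outcome
#' suitable for negative-binomial regression.
#'
#' @param ranks Named integer vector of consensus (or layer) ranks, >= 1.
#' @return Named integer vector of reversed ranks.
#' @export
reverse_ranks <- function(ranks) {
  stopifnot(is.numeric(ranks), !is.null(names(ranks)), all(ranks >= 1))
  max(ranks) - ranks
}

#' Borda-count consensus ranking across layers
#'
#' Aggregates per-layer (tier) ranks into Borda scores, consensus ranks and
#' reversed ranks. Tie comparisons use the exact integer rank totals.
#'
#' @param layer_ranks List of L named integer vectors (node -> layer rank).
#' @return Object of class `mplx_consensus`: list with `borda_score`,
#'   `consensus_rank`, and `reversed_rank`, all named by node.
#' @export
consensus_ranking <- function(layer_ranks) {
  totals <- rank_totals(layer_ranks)
  L <- length(layer_ranks)
  lev <- sort(unique(totals))
  ranks <- setNames(match(totals, lev), names(totals))
  structure(list(borda_score = totals / L,
                 consensus_rank = ranks,
                 reversed_rank = reverse_ranks(ranks)),
            class = "mplx_consensus")
}

#' @export
print.mplx_consensus <- function(x, ...) {
  n <- length(x$consensus_rank)
  cat(sprintf("<consensus ranking> %d nodes, ranks 1..%d\n",
              n, max(x$consensus_rank)))
  top <- names(sort(x$consensus_rank))[seq_len(min(5, n))]
  cat("  top:", paste(top, collapse = ", "), "\n")
  invisible(x)
}
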