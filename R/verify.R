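#' Verify a published ranking table against recomputed Borda consensus
#'
#' Given a deposited rankings table (one row per subject with per-layer
#' rank columns and a published multilayer consensus column), recompute the
#' Borda consensus from the layer columns and measure agreement with the
#' published column. Useful for checking whether deposited per-layer
#' columns are the tier ranks the Borda aggregation consumed.
#'
#' @param df Data frame, one row per node.
#' @param layer_cols Character vector naming the per-layer rank columns.
#' @param consensus_col Name of the published consensus rank column.
#' @param node_col Name of the node ID column (default `"node"`).
#' @return List with `borda_score`, `consensus_rank` (both recomputed,
#'   named by node), `agreement` (proportion of nodes whose recomputed
#'   consensus rank equals the published one), and `spearman` (rank
#'   correlation between recomputed and published).
#' @export
verify_ranking_table <- function(df, layer_cols, consensus_col,
                                 node_col = "node") {
  stopifnot(all(c(layer_cols, consensus_col, node_col) %in% names(df)))
  nodes <- as.character(df[[node_col]])
  ranks <- lapply(layer_cols, function(cl)
    setNames(as.numeric(df[[cl]]), nodes))
  cons <- consensus_ranking(ranks)
  published <- setNames(as.numeric(df[[consensus_col]]), nodes)
  list(borda_score = cons$borda_score,
       consensus_rank = cons$consensus_rank,
       agreement = mean(cons$consensus_rank[nodes] == published[nodes]),
       spearman = suppressWarnings(
         cor(cons$consensus_rank[nodes], published[nodes],
             method = "spearman")))
}
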