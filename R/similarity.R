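#' Spearman correlation matrix of layer rankings
#'
#' Pairwise Spearman rank correlations between the per-layer rankings of
#' one group, with average-rank (midrank) tie correction -- material here
#' because tier ranks contain many ties. A layer whose ranking is constant
#' has undefined correlations; those entries are reported as `NA` and
#' flagged, never coerced to 0. The diagonal is 1 by convention.
#'
#' @param rankings Named list of L named rank vectors (node -> rank), all
#'   covering `nodes`.
#' @param nodes Character vector of the group's node set (N >= 3).
#' @param consensus Optional named rank vector; when given, a
#'   `consensus` column of layer-vs-consensus correlations is attached.
#' @return Object of class `mplx_similarity`: list with `rho` (symmetric
#'   L x L matrix), `undefined` (logical vector flagging constant layers),
#'   and optionally `consensus_rho`.
#' @export
spearman_matrix <- function(rankings, nodes, consensus = NULL) {
  stopifnot(is.list(rankings), length(rankings) >= 1, length(nodes) >= 3)
  L <- length(rankings)
  if (is.null(names(rankings)))
    names(rankings) <- paste0("layer", seq_len(L))
  M <- vapply(rankings, function(r) {
    if (!all(nodes %in% names(r)))
      stop("ranking does not cover the group node set")
    as.numeric(r[nodes])
  }, numeric(length(nodes)))
  constant <- apply(M, 2, function(col) max(col) - min(col) == 0)
  rho <- suppressWarnings(cor(M, method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1
  out <- list(rho = rho, undefined = setNames(constant, names(rankings)))
  if (!is.null(consensus)) {
    cons <- as.numeric(consensus[nodes])
    cr <- vapply(seq_len(L), function(j) {
      if (constant[j] || max(cons) - min(cons) == 0) return(NA_real_)
      suppressWarnings(cor(M[, j], cons, method = "spearman"))
    }, numeric(1))
    out$consensus_rho <- setNames(cr, names(rankings))
  }
  structure(out, class = "mplx_similarity")
}

#' @export
print.mplx_similarity <- function(x, ...) {
  cat("<layer Spearman correlations>\n")
  print(round(x$rho, 3))
  if (!is.null(x$consensus_rho)) {
    cat("vs consensus:\n")
    print(round(x$consensus_rho, 3))
  }
  invisible(x)
}

#' Long-format layer correlation table
#'
#' @param x A `mplx_similarity`.
#' @param group Group label attached to every row.
#' @return Data frame with columns `group`, `layer_a`, `layer_b`, `rho`.
#' @export
similarity_long <- function(x, group = NA_character_) {
  L <- ncol(x$rho)
  nms <- colnames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  data.frame(group = group,
             layer_a = nms[idx[, 1]],
             layer_b = nms[idx[, 2]],
             rho = x$rho[idx],
             stringsAsFactors = FALSE)
}
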