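#' Assemble a multiplex network from layers
#'
#' A multiplex network is a fixed node set shared by L named layers. The
#' node set is the union of all layer endpoints plus any `extra_nodes`
#' (typically the IDs listed in an attribute table); a node absent from a
#' layer is an isolate in that layer, so all N nodes receive a rank in
#' every layer.
#'
#' @param layers List of [layer()] objects with unique names.
#' @param config Optional [layer_config()]; when supplied it must cover
#'   every layer by name and its directedness must agree with each layer.
#' @param extra_nodes Character vector of node IDs to force into the node
#'   set (isolates where unconnected).
#' @return An object of class `mplx_network`: list with `nodes` (character
#'   vector, length N) and `layers` (named list of `mplx_layer`, all sharing
#'   the full node set).
#' @examples
#' l1 <- layer("a", data.frame(source = "x", target = "y", weight = 1), TRUE)
#' l2 <- layer("b", data.frame(source = "y", target = "z", weight = 2), FALSE)
#' assemble_multiplex(list(l1, l2))
#' @export
assemble_multiplex <- function(layers, config = NULL, extra_nodes = NULL) {
  stopifnot(length(layers) >= 1)
  if (!all(vapply(layers, inherits, logical(1), "mplx_layer")))
    stop("all elements of 'layers' must be mplx_layer objects")
  nms <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("layer names must be unique")
  if (!is.null(config)) {
    if (!setequal(nms, config$layer))
      stop("layer config does not match layer names: config has {",
           paste(config$layer, collapse = ", "), "}, layers are {",
           paste(nms, collapse = ", "), "}")
    for (l in layers) {
      row <- config[config$layer == l$name, ]
      if (row$directed != l$directed)
        stop("directedness mismatch for layer '", l$name, "'")
    }
  }
  nodes <- unique(c(unlist(lapply(layers, `[[`, "nodes"), use.names = FALSE),
                    as.character(extra_nodes)))
  if (length(nodes) < 1) stop("multiplex must contain at least one node")
  layers <- lapply(layers, layer_with_nodes, nodes = nodes)
  names(layers) <- nms
  structure(list(nodes = nodes, layers = layers), class = "mplx_network")
}

#' @export
print.mplx_network <- function(x, ...) {
  cat(sprintf("<multiplex network> N = %d nodes, L = %d layers\n",
              length(x$nodes), length(x$layers)))
  for (l in x$layers)
    cat(sprintf("  %-12s %s  %5d edges\n", l$name,
                if (l$directed) "directed  " else "undirected", nrow(l$edges)))
  invisible(x)
}

#' Build and validate a node attribute table
#'
#' Validates per-node covariates and derives the transformed dominance
#' certainty and the matriline size category. Dominance certainty is
#' recorded raw in \[0.5, 1\] (0.5 ambiguous, 1 certain) and transformed to
#' `dc = 1 - certainty` so that 0 means complete certainty. Matriline size
#' categories are small (1-5), medium (6-10) and large (11+) members.
#'
#' @param df Data frame with columns `node`, `group`, `sex`
#'   ("female"/"male"), `age` (years), `dominance_rank` (fraction of group
#'   members outranked, in \[0,1\]), `dominance_certainty` (raw, in
#'   \[0.5,1\]), `matriline_size` (positive integer count), `rearing`
#'   ("mother"/"nursery").
#' @return A data frame of class `mplx_attributes` with the input columns
#'   coerced to factors where categorical, plus derived columns `dc`
#'   (transformed certainty) and `matriline_size_cat`.
#' @examples
#' attribute_table(data.frame(
#'   node = c("a", "b"), group = "G", sex = c("female", "male"),
#'   age = c(7, 9), dominance_rank = c(0.9, 0.2),
#'   dominance_certainty = c(0.95, 0.7), matriline_size = c(12, 3),
#'   rearing = c("mother", "nursery")))
#' @export
attribute_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("node", "group", "sex", "age", "dominance_rank",
            "dominance_certainty", "matriline_size", "rearing")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("attribute table missing columns: ", paste(miss, collapse = ", "))
  df$node <- as.character(df$node)
  if (anyDuplicated(df$node)) stop("duplicate node IDs in attribute table")
  sex <- as.character(df$sex)
  if (!all(sex %in% c("female", "male")))
    stop("unknown sex level: ", paste(setdiff(unique(sex),
         c("female", "male")), collapse = ", "))
  rearing <- as.character(df$rearing)
  if (!all(rearing %in% c("mother", "nursery")))
    stop("unknown rearing level: ", paste(setdiff(unique(rearing),
         c("mother", "nursery")), collapse = ", "))
  # reference levels: female, mother-reared (coefficients read as male /
  # nursery contrasts)
  df$sex <- factor(sex, levels = c("female", "male"))
  df$rearing <- factor(rearing, levels = c("mother", "nursery"))
  df$group <- factor(as.character(df$group))
  df$age <- as.numeric(df$age)
  df$dominance_rank <- as.numeric(df$dominance_rank)
  if (any(df$dominance_rank < 0 | df$dominance_rank > 1))
    stop("dominance_rank must lie in [0, 1]")
  df$dominance_certainty <- as.numeric(df$dominance_certainty)
  if (any(df$dominance_certainty < 0.5 | df$dominance_certainty > 1))
    stop("dominance_certainty must lie in [0.5, 1]")
  df$dc <- 1 - df$dominance_certainty
  df$matriline_size <- as.numeric(df$matriline_size)
  if (any(df$matriline_size < 1)) stop("matriline_size must be >= 1")
  df$matriline_size_cat <- matriline_category(df$matriline_size)
  if (!is.null(df$matriline_size_cat) && anyNA(df$matriline_size_cat))
    stop("could not categorise matriline sizes")
  class(df) <- c("mplx_attributes", "data.frame")
  df
}

#' Matriline size category
#'
#' @param size Numeric vector of matriline member counts.
#' @return Factor with levels `1-5`, `6-10`, `11+`.
#' @export
matriline_category <- function(size) {
  cut(size, breaks = c(0, 5, 10, Inf), labels = c("1-5", "6-10", "11+"))
}
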