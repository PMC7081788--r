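#' Read a weighted edge list
#'
#' Delimited text (comma by default, tab auto-detected) with a mandatory
#' header. Columns `source` and `target` are required; `weight` is optional
#' and defaults to 1 per row. Duplicate rows are summed.
#'
#' @param path Path to the file.
#' @param directed Logical; treat edges as directed?
#' @param name Layer name; defaults to the file name without extension.
#' @return A [layer()].
#' @export
read_edge_list <- function(path, directed, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- read_delimited(path)
  if (!all(c("source", "target") %in% names(df)))
    stop("edge list ", path, " must have header columns 'source','target'")
  if (is.null(df$weight)) df$weight <- 1
  w <- suppressWarnings(as.numeric(as.character(df$weight)))
  bad <- which(is.na(w) & !is.na(df$weight))
  if (length(bad))
    stop("malformed weight in ", path, " at data line ", bad[1])
  if (anyNA(df$source) || anyNA(df$target) || anyNA(w)) {
    ln <- which(is.na(df$source) | is.na(df$target) | is.na(w))[1]
    stop("malformed row in ", path, " at data line ", ln)
  }
  if (any(w < 0))
    stop("negative weight in ", path, " at data line ", which(w < 0)[1])
  df$weight <- w
  layer(name, df[c("source", "target", "weight")], directed = directed)
}

#' Write a layer's edge list as CSV
#'
#' Round-trips exactly with [read_edge_list()] for the same directedness.
#'
#' @param x A `mplx_layer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  write.csv(x$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a node attribute table
#'
#' See [attribute_table()] for the expected columns and validation rules.
#'
#' @param path Path to a CSV/TSV file with one row per node.
#' @return A validated `mplx_attributes` data frame.
#' @export
read_attributes <- function(path) {
  attribute_table(read_delimited(path))
}

#' Write a node attribute table as CSV
#' @param x A `mplx_attributes` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attributes <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Layer configuration
#'
#' One row per layer: which centrality metric measures importance in that
#' layer, whether the layer is directed, and the explained-variance
#' threshold used when cutting centralities into rank tiers.
#'
#' @param layer Character vector of layer names.
#' @param directed Logical vector.
#' @param metric Character vector; each one of `"eigenvector"`,
#'   `"in_degree"`, `"total_degree"`, `"betweenness"`.
#' @param tier_threshold Numeric in (0, 1\]; fraction of centrality
#'   variance the tiered values must explain (default 0.99).
#' @param path Optional character vector of edge-list paths (used by
#'   [run_rank()]).
#' @return Data frame of class `mplx_config`.
#' @export
layer_config <- function(layer, directed, metric,
                         tier_threshold = 0.99, path = NA_character_) {
  metric <- match.arg(metric, c("eigenvector", "in_degree", "total_degree",
                                "betweenness"), several.ok = TRUE)
  df <- data.frame(layer = as.character(layer),
                   directed = as.logical(directed),
                   metric = metric,
                   tier_threshold = as.numeric(tier_threshold),
                   path = as.character(path),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$layer)) stop("duplicate layer names in config")
  if (any(df$tier_threshold <= 0 | df$tier_threshold > 1))
    stop("tier_threshold must lie in (0, 1]")
  if (any(df$metric == "in_degree" & !df$directed))
    stop("in_degree centrality requires a directed layer")
  class(df) <- c("mplx_config", "data.frame")
  df
}

#' Read a layer configuration file
#'
#' CSV/TSV with header columns `layer`, `path`, `directed`, `metric` and
#' optionally `tier_threshold`.
#'
#' @param path Path to the file.
#' @param default_threshold Threshold used where the column is absent.
#' @return A `mplx_config` data frame.
#' @export
read_layer_config <- function(path, default_threshold = 0.99) {
  df <- read_delimited(path)
  need <- c("layer", "path", "directed", "metric")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("layer config missing columns: ", paste(miss, collapse = ", "))
  thr <- if (is.null(df$tier_threshold)) default_threshold
         else as.numeric(df$tier_threshold)
  layer_config(df$layer, directed = as.logical(df$directed),
               metric = as.character(df$metric), tier_threshold = thr,
               path = as.character(df$path))
}

# comma default; fall back to tab when the header has no comma
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (!grepl(",", header) && grepl("\t", header)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE,
           strip.white = TRUE, blank.lines.skip = TRUE)
}
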