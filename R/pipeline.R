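#' Rank a multiplex network
#'
#' The full consensus-ranking pipeline for one group: compute the
#' configured centrality of every layer, collapse each into rank tiers at
#' the layer's explained-variance threshold, and aggregate the tier ranks
#' across layers by Borda count.
#'
#' @param multiplex A `mplx_network`.
#' @param config A `mplx_config` covering every layer.
#' @return Object of class `mplx_result`: list with `layers` (per layer:
#'   `centrality`, `tiers`, `tier_rank`, `dense_rank`), `consensus` (a
#'   `mplx_consensus`), and `config`.
#' @export
rank_multiplex <- function(multiplex, config) {
  stopifnot(inherits(multiplex, "mplx_network"),
            inherits(config, "mplx_config"))
  if (!setequal(names(multiplex$layers), config$layer))
    stop("layer config does not cover the multiplex layers")
  per_layer <- lapply(multiplex$layers, function(l) {
    row <- config[config$layer == l$name, ]
    cent <- layer_centrality(l, row$metric)
    tiers <- assign_tiers(cent, threshold = row$tier_threshold)
    list(centrality = cent, tiers = tiers, tier_rank = tiers$tier_of,
         dense_rank = dense_rank(cent))
  })
  cons <- consensus_ranking(lapply(per_layer, `[[`, "tier_rank"))
  structure(list(layers = per_layer, consensus = cons, config = config),
            class = "mplx_result")
}

#' @export
print.mplx_result <- function(x, ...) {
  cat("<multiplex ranking result>\n")
  for (nm in names(x$layers))
    cat(sprintf("  %-12s %d tiers\n", nm, x$layers[[nm]]$tiers$k))
  print(x$consensus)
  invisible(x)
}

#' Run the ranking pipeline from files
#'
#' Reads a layer configuration (columns `layer`, `path`, `directed`,
#' `metric`, optional `tier_threshold`) and optionally an attribute table,
#' assembles the multiplex, ranks it, computes the layer correlation
#' matrix, and writes CSV outputs: one `layer_<name>.csv` per layer (node,
#' centrality, dense_rank, tier, tiered_value), `r2_<name>.csv` curves,
#' `consensus.csv`, and `correlations.csv`.
#'
#' @param layers Path to the layer configuration file, or a `mplx_config`
#'   with the `path` column filled in.
#' @param attributes Optional path to an attribute CSV (or a
#'   `mplx_attributes`); its nodes are forced into the node set.
#' @param out Output directory (created if missing). `NULL` skips writing.
#' @param threshold Optional tier threshold overriding the config.
#' @return A list with `result` (`mplx_result`), `similarity`
#'   (`mplx_similarity`), `multiplex`, and `attributes`, invisibly.
#' @export
run_rank <- function(layers, attributes = NULL, out = NULL,
                     threshold = NULL) {
  config <- if (inherits(layers, "mplx_config")) layers
            else read_layer_config(layers)
  if (!is.null(threshold)) config$tier_threshold <- threshold
  if (any(is.na(config$path)))
    stop("layer config must provide an edge-list path for every layer")
  layer_objs <- lapply(seq_len(nrow(config)), function(i)
    read_edge_list(config$path[i], directed = config$directed[i],
                   name = config$layer[i]))
  attrs <- NULL
  extra <- NULL
  if (!is.null(attributes)) {
    attrs <- if (inherits(attributes, "mplx_attributes")) attributes
             else read_attributes(attributes)
    extra <- attrs$node
  }
  mplx <- assemble_multiplex(layer_objs, config = config,
                             extra_nodes = extra)
  res <- rank_multiplex(mplx, config)
  sim <- spearman_matrix(lapply(res$layers, `[[`, "tier_rank"),
                         nodes = mplx$nodes,
                         consensus = res$consensus$consensus_rank)
  group <- if (!is.null(attrs)) as.character(attrs$group[1]) else "G1"
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res$layers)) {
      pl <- res$layers[[nm]]
      nodes <- names(pl$centrality$values)
      write.csv(data.frame(node = nodes,
                           centrality = as.numeric(pl$centrality$values),
                           dense_rank = as.integer(pl$dense_rank[nodes]),
                           tier = as.integer(pl$tier_rank[nodes]),
                           tiered_value = as.numeric(pl$tiers$tiered_value[nodes])),
                file.path(out, paste0("layer_", nm, ".csv")),
                row.names = FALSE, quote = FALSE)
      write.csv(data.frame(k = seq_along(pl$tiers$r2_path),
                           r2 = pl$tiers$r2_path),
                file.path(out, paste0("r2_", nm, ".csv")),
                row.names = FALSE, quote = FALSE)
    }
    cons <- res$consensus
    nodes <- names(cons$consensus_rank)
    write.csv(data.frame(group = group, node = nodes,
                         borda_score = as.numeric(cons$borda_score[nodes]),
                         consensus_rank = as.integer(cons$consensus_rank[nodes]),
                         reversed_rank = as.integer(cons$reversed_rank[nodes])),
              file.path(out, "consensus.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(similarity_long(sim, group = group),
              file.path(out, "correlations.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(as.data.frame(sim$rho),
              file.path(out, "correlations_wide.csv"), quote = FALSE)
  }
  invisible(list(result = res, similarity = sim, multiplex = mplx,
                 attributes = attrs))
}

#' Run attribute inference on a ranked group
#'
#' Fits a catalogue of negative-binomial models of the reversed consensus
#' ranks, selects the AICc candidate set, and runs the node-label
#' permutation test on the best model.
#'
#' @param consensus Path to a `consensus.csv` written by [run_rank()] (or
#'   an equivalent data frame with `node` and `reversed_rank` columns).
#' @param attributes Path to the attribute CSV, or a `mplx_attributes`.
#' @param catalogue Named list of model formulas; default the published
#'   consensus catalogue.
#' @param replicates Permutation replicates (default 1000).
#' @param seed Root seed for the randomisations.
#' @param out Optional output directory for `model_selection.csv` and
#'   `permutation_<model>.csv`.
#' @param method Fit method passed to [fit_nb_model()] and replicate
#'   refits.
#' @return List with `fits`, `selection` (candidate-set table), and
#'   `permutation` (test on the best model), invisibly.
#' @export
run_infer <- function(consensus, attributes,
                      catalogue = default_model_catalogue()$consensus,
                      replicates = 1000, seed = 1, out = NULL,
                      method = "fixed") {
  if (is.null(attributes)) stop("attributes required")
  cons <- if (is.data.frame(consensus)) consensus else read_delimited(consensus)
  if (!all(c("node", "reversed_rank") %in% names(cons)))
    stop("consensus table must have 'node' and 'reversed_rank' columns")
  attrs <- if (inherits(attributes, "mplx_attributes")) attributes
           else read_attributes(attributes)
  outcome <- setNames(as.numeric(cons$reversed_rank),
                      as.character(cons$node))
  data <- as.data.frame(attrs)
  data$reversed_rank <- outcome[data$node]
  fits <- lapply(catalogue, fit_nb_model, data = data, method = method)
  sel <- aicc_candidate_set(fits)
  best <- sel$model[1]
  perm <- permutation_test(catalogue[[best]], outcome = outcome,
                           attributes = attrs, replicates = replicates,
                           seed = seed, method = method)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write.csv(sel, file.path(out, "model_selection.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(permutation_summary(perm),
              file.path(out, paste0("permutation_", best, ".csv")),
              row.names = FALSE, quote = FALSE)
    write.csv(as.data.frame(perm$null),
              file.path(out, paste0("null_draws_", best, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  invisible(list(fits = fits, selection = sel, permutation = perm))
}

#' Simulate a group and write it in the pipeline's input formats
#'
#' @param scenario A `mplx_scenario` (default [group_scenario()]).
#' @param seed Integer seed.
#' @param out Output directory; edge lists (`<layer>.csv`), the attribute
#'   table (`attributes.csv`) and a ready-to-use layer configuration
#'   (`layers.csv`) are written there.
#' @return The generated list (`multiplex`, `attributes`, `config`),
#'   invisibly.
#' @export
run_simulate <- function(scenario = group_scenario(), seed = 1, out) {
  gen <- generate_group(scenario, seed = seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg <- gen$config
  cfg$path <- file.path(out, paste0(cfg$layer, ".csv"))
  for (i in seq_len(nrow(cfg)))
    write_edge_list(gen$multiplex$layers[[cfg$layer[i]]], cfg$path[i])
  write_attributes(gen$attributes, file.path(out, "attributes.csv"))
  write.csv(as.data.frame(cfg), file.path(out, "layers.csv"),
            row.names = FALSE, quote = FALSE)
  gen$config <- cfg
  invisible(gen)
}
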