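#' Scenario for a synthetic multiplex social group
#'
#' Describes a macaque-style social group: N adults with roughly a 1:2.5
#' male:female ratio, matrilines of size 1--36, a latent dominance
#' hierarchy driving the directed layers, and kin-biased affiliation.
#' Defaults reproduce a group of the size and layer densities of the
#' largest study-group configuration (N = 87, 30 males, layer densities
#' aggression 0.271, status 0.085, policing 0.021, grooming 0.259,
#' huddling 0.190).
#'
#' Effect sizes are log-odds slopes on the pair covariates: rank advantage
#' for aggression, rank of the signal receiver for status, elite-male
#' indicator for policing out-edges, matriline co-membership and mean rank
#' for the undirected affiliation layers. Setting `zero_effect = TRUE`
#' zeroes all of them, making every layer an Erdos--Renyi draw at the
#' target density, independent of the attributes -- the null world used
#' for type-I-error calibration.
#'
#' @param n Group size (adults). Study groups ranged 55--101.
#' @param n_males Number of males (default scales n by 1/3.5).
#' @param densities Named numeric vector of target layer densities in
#'   (0,1) for aggression, status, policing, grooming, huddling.
#' @param effects Named list of log-odds effect sizes; see Details.
#' @param matriline_geom_p Success probability of the truncated geometric
#'   distribution of matriline sizes (support 1..36).
#' @param weight_lambda Rate of the zero-truncated Poisson edge weights
#'   (interaction frequencies).
#' @param prop_nursery Probability an individual is nursery-reared.
#' @param zero_effect Logical; zero all effect sizes.
#' @param group Group label for the attribute table.
#' @return List of class `mplx_scenario`.
#' @export
group_scenario <- function(n = 87,
                           n_males = max(1L, round(n / 3.5)),
                           densities = c(aggression = 0.271, status = 0.085,
                                         policing = 0.021, grooming = 0.259,
                                         huddling = 0.190),
                           effects = list(aggression_rank = 4,
                                          status_rank = 6,
                                          policing_elite = 6,
                                          kin_bias = 2.5,
                                          affiliation_rank = 1),
                           matriline_geom_p = 0.2,
                           weight_lambda = 2,
                           prop_nursery = 0.07,
                           zero_effect = FALSE,
                           group = "G1") {
  stopifnot(n >= 2, n_males >= 1, n_males < n,
            all(densities > 0), all(densities < 1),
            length(densities) == 5)
  need <- c("aggression", "status", "policing", "grooming", "huddling")
  if (!all(need %in% names(densities)))
    stop("densities must be named: ", paste(need, collapse = ", "))
  if (zero_effect)
    effects <- lapply(effects, function(x) 0)
  structure(list(n = n, n_males = n_males, densities = densities[need],
                 effects = effects, matriline_geom_p = matriline_geom_p,
                 weight_lambda = weight_lambda,
                 prop_nursery = prop_nursery, group = group),
            class = "mplx_scenario")
}

#' Generate a synthetic multiplex social group
#'
#' Draws the five behavioural layers and the node attribute table implied
#' by a [group_scenario()]. Edge probabilities follow a logistic link in
#' the pair covariates with the intercept calibrated so the expected
#' density equals the scenario target; edge weights are zero-truncated
#' Poisson interaction frequencies. Dominance certainty follows a U-shape
#' in rank with noise, clipped to the observed range \[0.69, 0.98\].
#' Deterministic given `seed`.
#'
#' @param scenario A `mplx_scenario`.
#' @param seed Integer seed.
#' @return List with elements `multiplex` (a `mplx_network`), `attributes`
#'   (a `mplx_attributes`), and `config` (the default layer configuration).
#' @export
generate_group <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "mplx_scenario"))
  with_seed(seed, generate_group_impl(scenario))
}

generate_group_impl <- function(sc) {
  n <- sc$n
  nodes <- sprintf("n%03d", seq_len(n))
  # matrilines: truncated geometric sizes on 1..36
  sizes <- integer(0)
  while (sum(sizes) < n) {
    s <- min(stats::rgeom(1, sc$matriline_geom_p) + 1L, 36L)
    sizes <- c(sizes, s)
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  if (sizes[length(sizes)] == 0L) sizes <- sizes[-length(sizes)]
  matriline <- rep(seq_along(sizes), sizes)
  matriline_size <- sizes[matriline]
  sex <- rep("female", n)
  sex[sample.int(n, sc$n_males)] <- "male"
  # latent hierarchy: dominance rank = fraction of the group outranked
  pos <- sample.int(n)  # 1 = top animal
  d <- (n - pos) / (n - 1)
  elite <- as.numeric(sex == "male" & d >= 0.9)
  dens <- sc$densities
  ef <- sc$effects

  directed_layer <- function(name, xfun, slope, target) {
    i <- rep(seq_len(n), each = n)
    j <- rep(seq_len(n), times = n)
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    x <- xfun(i, j)
    p <- calibrated_prob(x, slope, target)
    sel <- runif(length(p)) < p
    edges <- data.frame(source = nodes[i[sel]], target = nodes[j[sel]],
                        weight = ztpois(sum(sel), sc$weight_lambda))
    layer(name, edges, directed = TRUE, nodes = nodes)
  }
  undirected_layer <- function(name, xfun, target) {
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pr[, 1]; j <- pr[, 2]
    x <- xfun(i, j)
    p <- calibrated_prob(x, 1, target)  # slope folded into xfun
    sel <- runif(length(p)) < p
    edges <- data.frame(source = nodes[i[sel]], target = nodes[j[sel]],
                        weight = ztpois(sum(sel), sc$weight_lambda))
    layer(name, edges, directed = FALSE, nodes = nodes)
  }

  layers <- list(
    directed_layer("aggression", function(i, j) d[i] - d[j],
                   ef$aggression_rank, dens[["aggression"]]),
    directed_layer("status", function(i, j) d[j] - d[i],
                   ef$status_rank, dens[["status"]]),
    directed_layer("policing", function(i, j) elite[i],
                   ef$policing_elite, dens[["policing"]]),
    undirected_layer("grooming", function(i, j)
      ef$kin_bias * (matriline[i] == matriline[j]) +
        ef$affiliation_rank * (d[i] + d[j]) / 2, dens[["grooming"]]),
    undirected_layer("huddling", function(i, j)
      ef$kin_bias * (matriline[i] == matriline[j]) +
        0.5 * ef$affiliation_rank * (d[i] + d[j]) / 2, dens[["huddling"]]))

  certainty <- 0.69 + 0.29 *
    pmin(1, pmax(0, 4 * (d - 0.5)^2 + rnorm(n, 0, 0.1)))
  attrs <- attribute_table(data.frame(
    node = nodes,
    group = sc$group,
    sex = sex,
    age = pmin(3 + round(rgamma(n, shape = 2, rate = 0.45), 1), 29),
    dominance_rank = d,
    dominance_certainty = pmin(pmax(certainty, 0.69), 0.98),
    matriline_size = matriline_size,
    rearing = ifelse(runif(n) < sc$prop_nursery, "nursery", "mother"),
    stringsAsFactors = FALSE))
  list(multiplex = assemble_multiplex(layers, extra_nodes = nodes),
       attributes = attrs,
       config = default_layer_config())
}

# P(edge) = plogis(a0 + x) with a0 solved so that mean(P) hits the target
calibrated_prob <- function(x, slope, target) {
  x <- slope * x
  if (all(x == 0)) return(rep(target, length(x)))
  f <- function(a0) mean(plogis(a0 + x)) - target
  a0 <- uniroot(f, c(-30, 30), tol = 1e-10)$root
  plogis(a0 + x)
}

# zero-truncated Poisson draws via inverse CDF above P(X = 0)
ztpois <- function(m, lambda) {
  if (m == 0) return(numeric(0))
  qpois(runif(m, ppois(0, lambda), 1), lambda)
}

#' Default five-layer configuration
#'
#' Aggression is measured with eigenvector centrality (hubs in a connected
#' dominance network), status signaling with in-degree and policing with
#' total degree (sparse, not always connected), grooming and huddling with
#' betweenness (cohesion in affiliation networks).
#'
#' @param tier_threshold Explained-variance threshold for all layers
#'   (default 0.99).
#' @return A `mplx_config` data frame.
#' @export
default_layer_config <- function(tier_threshold = 0.99) {
  layer_config(
    layer = c("aggression", "status", "policing", "grooming", "huddling"),
    directed = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    metric = c("eigenvector", "in_degree", "total_degree",
               "betweenness", "betweenness"),
    tier_threshold = tier_threshold)
}

#' Redraw attributes independently of the network
#'
#' Each base attribute column is permuted independently across the nodes
#' of a group (marginal multisets preserved exactly; inter-attribute and
#' attribute--network associations destroyed); derived columns are then
#' recomputed. Used for type-I-error studies.
#'
#' @param table A `mplx_attributes` data frame.
#' @param seed Integer seed.
#' @return A `mplx_attributes` data frame.
#' @export
generate_null_attributes <- function(table, seed) {
  base_cols <- c("sex", "age", "dominance_rank", "dominance_certainty",
                 "matriline_size", "rearing")
  out <- as.data.frame(table)
  with_seed(seed, {
    for (g in unique(out$group)) {
      idx <- which(out$group == g)
      for (cl in base_cols)
        out[idx, cl] <- out[idx, cl][sample.int(length(idx))]
    }
  })
  out$dc <- NULL
  out$matriline_size_cat <- NULL
  attribute_table(out)
}

#' Realized density of a layer
#'
#' Proportion of possible (ordered for directed, unordered for undirected)
#' node pairs joined by an edge.
#'
#' @param x A `mplx_layer`.
#' @return Numeric density in \[0, 1\].
#' @export
layer_density <- function(x) {
  n <- length(x$nodes)
  if (n < 2) return(0)
  m <- sum(x$edges$source != x$edges$target)
  denom <- if (x$directed) n * (n - 1) else n * (n - 1) / 2
  m / denom
}
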