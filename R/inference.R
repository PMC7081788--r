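#' Fit a negative-binomial model of reversed ranks
#'
#' Reversed (consensus or layer) ranks are nonnegative counts with a
#' right-skewed distribution, modelled with a negative-binomial family and
#' log link. The study design has several social groups, entering as a
#' group random intercept; when the mixed fit fails (or there is a single
#' group) the model falls back to a group fixed effect, and the fallback is
#' recorded in the result.
#'
#' @param formula Model formula over the attribute vocabulary, e.g.
#'   `reversed_rank ~ dominance_rank * sex * dc + matriline_size_cat * sex
#'   + rearing`. Do not include the group term; it is added automatically.
#' @param data Data frame containing the outcome and all covariates, plus a
#'   `group` column.
#' @param method `"auto"` (mixed with fixed fallback), `"mixed"`, or
#'   `"fixed"`. Fixed-effect fits are much faster and are the default
#'   inside permutation replicates.
#' @return Object of class `mplx_fit`: list with `model`, `coefficients`
#'   (fixed effects, excluding group dummies), `logLik`, `K` (parameter
#'   count), `n`, `aic`, `aicc`, `method` used, `family`
#'   (`"negative_binomial"`, or `"poisson_limit"` when theta estimation
#'   diverged on underdispersed counts and the Poisson limit was fitted),
#'   and `formula`.
#' @export
fit_nb_model <- function(formula, data, method = c("auto", "mixed", "fixed")) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  outcome_name <- all.vars(formula)[1]
  y <- data[[outcome_name]]
  if (is.null(y) || any(y < 0) || any(y != round(y)))
    stop("outcome must be nonnegative integers")
  multi_group <- !is.null(data$group) && length(unique(data$group)) > 1
  fit <- NULL
  used <- NULL
  if (method %in% c("auto", "mixed") && multi_group) {
    fit <- tryCatch(
      suppressMessages(lme4::glmer.nb(
        update(formula, . ~ . + (1 | group)), data = data,
        nb.control = list())),
      error = function(e) NULL)
    if (!is.null(fit)) used <- "mixed"
    if (is.null(fit) && method == "mixed")
      stop("mixed negative-binomial fit failed and method = 'mixed'")
  }
  if (is.null(fit)) {
    f <- if (multi_group) update(formula, . ~ . + group) else formula
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(f, data = data,
                                    control = stats::glm.control(maxit = 50))),
      error = function(e) NULL)
    used <- "fixed"
    if (is.null(fit)) {
      # theta estimation diverges when the counts are underdispersed; the
      # NB family degenerates to Poisson as theta -> Inf, so fit that limit
      fit <- tryCatch(
        stats::glm(f, family = stats::poisson(), data = data),
        error = function(e)
          stop("negative-binomial fit failed: ", conditionMessage(e)))
      used <- "fixed_poisson_limit"
    }
  }
  ll <- logLik(fit)
  K <- attr(ll, "df")
  n <- length(y)
  if (n <= K + 1) stop("too few observations (n must exceed K + 1)")
  family <- if (used == "fixed_poisson_limit") "poisson_limit" else
    "negative_binomial"
  if (used == "fixed_poisson_limit") used <- "fixed"
  co <- if (used == "mixed") lme4::fixef(fit) else coef(fit)
  co <- co[!grepl("^group", names(co))]
  aic_val <- AIC(fit)
  structure(list(model = fit, coefficients = co,
                 logLik = as.numeric(ll), K = K, n = n,
                 aic = aic_val, aicc = aic_val + 2 * K * (K + 1) / (n - K - 1),
                 method = used, family = family, formula = formula),
            class = "mplx_fit")
}

#' @export
print.mplx_fit <- function(x, ...) {
  cat(sprintf("<NB fit (%s)> n = %d, K = %d, AICc = %.1f\n",
              x$method, x$n, x$K, x$aicc))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2K(K+1)/(n - K - 1)`; converges to AIC as n grows.
#'
#' @param aic AIC value(s).
#' @param K Number of estimated parameters.
#' @param n Number of observations (must exceed K + 1).
#' @return AICc value(s).
#' @export
aicc <- function(aic, K, n) {
  stopifnot(all(n > K + 1))
  aic + 2 * K * (K + 1) / (n - K - 1)
}

#' AICc candidate set and Akaike weights
#'
#' Retains every model within `delta_max` AICc points of the best model and
#' computes Akaike weights `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))`
#' over the retained candidate set.
#'
#' @param fits List of `mplx_fit` objects (or a bare numeric vector of AICc
#'   values), all fitted to the same data.
#' @param delta_max Inclusion threshold on delta-AICc (default 4).
#' @return Data frame with columns `model`, `aicc`, `delta`, `in_set`,
#'   `weight` (NA outside the candidate set), ordered by AICc.
#' @export
aicc_candidate_set <- function(fits, delta_max = 4) {
  if (is.numeric(fits)) {
    vals <- fits
    nms <- if (is.null(names(fits))) paste0("model", seq_along(fits))
           else names(fits)
  } else {
    stopifnot(length(fits) >= 1)
    ns <- vapply(fits, `[[`, numeric(1), "n")
    if (length(unique(ns)) > 1)
      stop("models fitted to differing numbers of observations are not comparable")
    vals <- vapply(fits, `[[`, numeric(1), "aicc")
    nms <- if (is.null(names(fits))) paste0("model", seq_along(fits))
           else names(fits)
  }
  ord <- order(vals)
  delta <- vals[ord] - vals[ord][1]
  in_set <- delta <= delta_max
  w <- rep(NA_real_, length(vals))
  raw <- exp(-delta[in_set] / 2)
  w[in_set] <- raw / sum(raw)
  data.frame(model = nms[ord], aicc = vals[ord], delta = delta,
             in_set = in_set, weight = w, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Permute node attributes within groups
#'
#' Node-based randomisation: attribute row-tuples are shuffled jointly
#' across the nodes of each group, leaving the network layers untouched.
#' Joint (row-wise) shuffling preserves attribute inter-correlations (for
#' example the U-shaped rank--certainty relationship) under the null, so
#' the test targets the attribute--network association only.
#'
#' @param table A `mplx_attributes` data frame.
#' @param seed Integer seed; the permutation is deterministic given it.
#' @return The table with attribute columns permuted; `node` and `group`
#'   stay in place.
#' @export
permute_attributes <- function(table, seed) {
  keep <- c("node", "group")
  cols <- setdiff(names(table), keep)
  out <- table
  with_seed(seed, {
    for (g in unique(table$group)) {
      idx <- which(table$group == g)
      out[idx, cols] <- table[idx[sample.int(length(idx))], cols]
    }
  })
  out
}

#' Node-label permutation test for attribute effects
#'
#' Refits a negative-binomial model of reversed ranks under node-label
#' randomisations and compares each observed coefficient with its null
#' distribution. Centrality rankings depend only on the network, not on
#' the attributes, so they are computed once; each replicate shuffles the
#' attribute rows within groups, re-pairs them with the fixed outcome, and
#' refits the same model.
#'
#' Two decision rules are reported per term: the literal two-tailed 2.5%/
#' 97.5% rule (significant at p = 0.05 if fewer than 2.5% or more than
#' 97.5% of null coefficients exceed the observed one) and a corrected
#' empirical p-value `2 * min(q, 1 - q)` with the (1 + count) / (1 + R)
#' small-sample adjustment.
#'
#' @param formula Model formula (outcome on the left; its values are taken
#'   from `outcome`, not from `attributes`).
#' @param outcome Named numeric vector of reversed ranks keyed by node. May
#'   be omitted when `multiplex` and `config` are given, in which case the
#'   reversed consensus ranks are computed from the network.
#' @param attributes A `mplx_attributes` data frame covering the nodes.
#' @param replicates Number of randomisations R (default 1000).
#' @param seed Root seed; per-replicate seeds are spawned from it so each
#'   replicate is reproducible independently of execution order.
#' @param method Fitting method per replicate; `"fixed"` (default) refits
#'   with a group fixed effect for speed, `"mixed"` re-uses the random
#'   intercept.
#' @param multiplex,config Optional `mplx_network` and `mplx_config` used
#'   to compute `outcome` when it is not supplied.
#' @return Object of class `mplx_permutation`: list with `observed`
#'   (coefficients), `null` (R x terms matrix), `null_mean`, `null_sd`,
#'   `tail_prop` (share of null values >= observed), `significant_tail`
#'   (the 2.5%/97.5% rule), `p_value` (corrected empirical), `n_failed`,
#'   `replicates`, and `seed`.
#' @export
permutation_test <- function(formula, outcome = NULL, attributes,
                             replicates = 1000, seed = 1,
                             method = c("fixed", "mixed"),
                             multiplex = NULL, config = NULL) {
  method <- match.arg(method)
  stopifnot(replicates >= 1)
  if (is.null(outcome)) {
    if (is.null(multiplex) || is.null(config))
      stop("supply either 'outcome' or both 'multiplex' and 'config'")
    ranked <- rank_multiplex(multiplex, config)
    outcome <- ranked$consensus$reversed_rank
  }
  outcome_name <- all.vars(formula)[1]
  build_data <- function(tab) {
    d <- as.data.frame(tab)
    if (!all(d$node %in% names(outcome)))
      stop("outcome does not cover all attribute-table nodes")
    d[[outcome_name]] <- as.numeric(outcome[d$node])
    d
  }
  obs_fit <- fit_nb_model(formula, build_data(attributes), method = method)
  obs <- obs_fit$coefficients
  terms_nms <- names(obs)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, replicates))
  null <- matrix(NA_real_, nrow = replicates, ncol = length(terms_nms),
                 dimnames = list(NULL, terms_nms))
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    tab_r <- permute_attributes(attributes, seeds[r])
    fit_r <- tryCatch(
      fit_nb_model(formula, build_data(tab_r), method = method),
      error = function(e) NULL)
    if (is.null(fit_r)) {
      n_failed <- n_failed + 1L
    } else {
      null[r, names(fit_r$coefficients)] <- fit_r$coefficients
    }
  }
  if (n_failed > 0.1 * replicates)
    warning(n_failed, " of ", replicates, " replicate fits failed")
  stats_per_term <- function(j) {
    z <- null[, j]
    z <- z[!is.na(z)]
    R <- length(z)
    q <- mean(z >= obs[j])
    p <- 2 * min((1 + sum(z >= obs[j])) / (1 + R),
                 (1 + sum(z <= obs[j])) / (1 + R))
    c(mean = mean(z), sd = sd(z), q = q, p = min(p, 1))
  }
  st <- vapply(seq_along(terms_nms), stats_per_term, numeric(4))
  structure(list(observed = obs,
                 null = null,
                 null_mean = setNames(st["mean", ], terms_nms),
                 null_sd = setNames(st["sd", ], terms_nms),
                 tail_prop = setNames(st["q", ], terms_nms),
                 significant_tail = setNames(st["q", ] < 0.025 |
                                             st["q", ] > 0.975, terms_nms),
                 p_value = setNames(st["p", ], terms_nms),
                 n_failed = n_failed, replicates = replicates, seed = seed,
                 formula = formula, observed_fit = obs_fit),
            class = "mplx_permutation")
}

#' @export
print.mplx_permutation <- function(x, ...) {
  cat(sprintf("<permutation test> R = %d (%d failed), seed = %s\n",
              x$replicates, x$n_failed, format(x$seed)))
  print(permutation_summary(x), digits = 3)
  invisible(x)
}

#' Summary table of a permutation test
#'
#' One row per model term: observed coefficient, null mean and SD,
#' corrected empirical p, and the tail-rule flag. Terms at p <= 0.10 are
#' starred in the `flag` column.
#'
#' @param x A `mplx_permutation`.
#' @return Data frame.
#' @export
permutation_summary <- function(x) {
  data.frame(term = names(x$observed),
             observed = as.numeric(x$observed),
             null_mean = as.numeric(x$null_mean),
             null_sd = as.numeric(x$null_sd),
             p = as.numeric(x$p_value),
             tail_significant = as.logical(x$significant_tail),
             flag = ifelse(x$p_value <= 0.10, "*", ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Published model catalogue
#'
#' The default set of candidate formulas for each outcome: the reversed
#' consensus rank and the reversed aggression, status-signaling and
#' grooming layer ranks. Terms use the attribute vocabulary of
#' [attribute_table()] (`dominance_rank`, `sex`, `dc`, `age`,
#' `matriline_size_cat`, `rearing`).
#'
#' @return Named list of lists of formulas.
#' @export
default_model_catalogue <- function() {
  list(
    consensus = list(
      model1 = reversed_rank ~ dominance_rank * sex * dc +
        matriline_size_cat * sex + rearing,
      model2 = reversed_rank ~ dominance_rank * sex * dc +
        matriline_size_cat + rearing),
    aggression = list(
      model1 = reversed_rank ~ dominance_rank * sex * dc,
      model2 = reversed_rank ~ dominance_rank * age * dc + sex),
    status = list(
      model1 = reversed_rank ~ dominance_rank * age * sex + dc),
    grooming = list(
      model1 = reversed_rank ~ dominance_rank * matriline_size_cat + sex +
        rearing,
      model2 = reversed_rank ~ dominance_rank * matriline_size_cat + sex,
      model3 = reversed_rank ~ dominance_rank + matriline_size_cat + sex +
        rearing,
      model4 = reversed_rank ~ dominance_rank * sex + matriline_size_cat,
      model5 = reversed_rank ~ dominance_rank + matriline_size_cat))
}

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
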