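# multiplexrank

Consensus ranking of node centrality in multiplex social networks.

Animal (and human) social life is multi-layered: the same individuals
fight, signal status, police conflicts, groom and huddle, and each
interaction type forms its own weighted network over the same node set.
No single layer captures who is socially central overall, and tensor-style
multilayer centralities assume the layers are structurally alike — which
behavioural layers are not (directed vs. undirected, dense vs. sparse,
competitive vs. affiliative).

`multiplexrank` implements **consensus ranking**, which handles this
heterogeneity by design:

1. **Per-layer centrality**, chosen to fit each layer's structure:
   weighted eigenvector centrality (power iteration, with uniform
   teleportation ε when the layer is not strongly connected), weighted
   in-/total degree (strength), or weighted betweenness with edge
   distance 1/weight.
2. **Rank tiers.** Raw centralities are collapsed into tiers by
   one-dimensional agglomerative clustering with complete linkage
   (distance = |c_i − c_j|), cutting the tree at the minimum tier count
   whose tiered values (tier means) explain at least a threshold fraction
   of variance, r² ≥ 0.99 by default. The tier index of node *i* in layer
   *α* is its layer rank *b(α,i)*.
3. **Borda count.** The consensus score of node *i* is its mean layer
   rank, *b_i = (1/L) Σ_α b(α,i)*; the lowest score takes consensus rank
   1, ties share a dense rank. Reversed ranks (max − rank) give a
   nonnegative count outcome for regression.
4. **Inference.** Reversed ranks are regressed on node attributes (sex,
   age, dominance rank and certainty, matriline size category, rearing)
   with a negative-binomial GLMM (group random intercept, fixed-effect
   fallback), candidate models selected by ΔAICc ≤ 4 with Akaike weights,
   and per-term significance derived from node-label permutation nulls
   (attribute rows shuffled within groups; two-tailed 2.5%/97.5% rule plus
   a corrected empirical p).

A synthetic generator (`group_scenario()` / `generate_group()`) produces
macaque-style groups — latent dominance hierarchy, matrilineal kin bias,
five behavioural layers at realistic densities — used throughout the test
suite, so no external data are required.

## Worked example

```r
library(multiplexrank)

gen <- generate_group(group_scenario(n = 87, n_males = 30), seed = 11)
res <- rank_multiplex(gen$multiplex, gen$config)
res
#> <multiplex ranking result>
#>   aggression   11 tiers
#>   status       10 tiers
#>   policing     6 tiers
#>   grooming     10 tiers
#>   huddling     11 tiers
#> <consensus ranking> 87 nodes, ranks 1..28
#>   top: n050, n026, n052, n039, n056
```

Each layer collapses to 6–11 tiers at the 99% explained-variance
threshold, and the 87 animals spread over 28 consensus ranks. The two
dominance-driven layers agree strongly:

```r
sim <- spearman_matrix(lapply(res$layers, `[[`, "tier_rank"),
                       gen$multiplex$nodes)
round(sim$rho["aggression", "status"], 2)
#> [1] 0.84
```

Permutation inference on the reversed consensus ranks recovers the
planted dominance effect and nothing else:

```r
pt <- permutation_test(reversed_rank ~ dominance_rank + sex,
                       outcome = res$consensus$reversed_rank,
                       attributes = gen$attributes,
                       replicates = 199, seed = 11)
permutation_summary(pt)
#>             term observed null_mean null_sd    p tail_significant flag
#> 1    (Intercept)  1.19938   2.33917   0.129 0.01             TRUE    *
#> 2 dominance_rank  1.97727   0.00786   0.237 0.01             TRUE    *
#> 3        sexmale -0.00912  -0.00396   0.145 0.95            FALSE
```

The observed dominance-rank coefficient (1.98) sits far outside its
permutation null (0.01 ± 0.24), so higher-ranked animals are more central
across the multiplex; sex has no effect beyond rank in this simulation,
and its coefficient sits squarely inside the null.

## Command line

```sh
Rscript inst/cli/multiplexrank.R simulate --out demo --n 87 --seed 1
Rscript inst/cli/multiplexrank.R rank --layers demo/layers.csv \
    --attributes demo/attributes.csv --out demo/ranked
Rscript inst/cli/multiplexrank.R infer --consensus demo/ranked/consensus.csv \
    --attributes demo/attributes.csv --replicates 1000 --seed 1 --out demo/inf
```

`rank` writes per-layer centrality/tier tables, r²-vs-k curves, the
consensus table (group, node, borda_score, consensus_rank, reversed_rank)
and the layer Spearman matrix; `infer` writes the AICc model-selection
table and permutation summaries.

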