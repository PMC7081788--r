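---
title: "Consensus ranking for multiplex social networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ranking for multiplex social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiplexrank)
```

## The problem

A multiplex social network records several interaction types — here
aggression, status signaling, conflict policing, grooming and huddling —
over one fixed set of individuals. The layers differ structurally:
dominance-driven layers are directed and hub-like, affiliative layers are
undirected and clustered by kinship, and densities range from ~0.01
(policing) to ~0.35. A centrality notion that treats all layers alike
either ignores this heterogeneity or cannot be applied at all. Consensus
ranking sidesteps the issue: measure each layer with the metric that suits
it, reduce every layer to a *ranking*, and aggregate the rankings.

## The model

### Per-layer centrality

Three metrics are available per layer (`layer_config()`):

* **Eigenvector** (`eigenvector_centrality`) for connected dominance
  layers with clear hubs. Computed by power iteration on the weighted
  adjacency; node *i*'s score grows with the scores of the nodes it
  directs edges to. The source data do not pin down this direction
  convention (out-edges vs in-edges vs symmetrised); we chose the
  out-going reading — an aggressor of well-connected aggressors ranks
  high — and it is a single switch in the code. Two numerical choices:
  (1) when the layer is not strongly connected, a uniform teleportation
  mass `epsilon = 1e-3` (spread as ε/N per matrix entry) makes the
  dominant eigenvector unique; (2) iteration runs on the diagonally
  shifted operator A + max(rowSums(A))·I, which has the same eigenvectors
  but a strictly dominant top eigenvalue, so the iteration cannot
  oscillate on periodic graphs (a bipartite star is the canonical
  failure). Convergence: successive max-normalised iterates within 1e-10
  in max norm; non-convergence is an error, never a silent result.
* **Degree/strength** (`degree_centrality`) for sparse, possibly
  disconnected layers: weighted in-strength (status signaling — receivers
  of subordination signals are central) or in+out strength (policing,
  where both directions carry information).
* **Betweenness** (`betweenness_centrality`) for affiliative layers where
  cohesion matters. Edge distance is 1/weight — frequent interaction
  means a short path — and tied shortest paths split a pair's
  contribution equally. Counts are left unnormalised because only their
  ranks are consumed downstream.

All metrics are invariant in rank to rescaling a layer's weights and
equivariant to node relabeling (property-tested).

### Rank tiers

Centrality values are very unevenly spaced: top animals are well
separated, the bulk nearly indistinguishable. Converting raw values to
ordinal ranks would manufacture distinctions the data cannot support, so
values are collapsed into **tiers** by one-dimensional agglomerative
clustering with complete linkage (inter-point distance = absolute
centrality difference; inter-cluster distance = maximum pairwise
distance, which keeps tier spreads comparable). In one dimension the
minimum complete-linkage merge is always between clusters adjacent in
sorted order, so clusters are contiguous intervals; the implementation
exploits this for O(N²) work and the test suite proves it equal to
generic O(N³) agglomeration.

The tree is cut at the **minimum number of tiers k whose tiered values
(tier means) explain at least a threshold fraction of variance**,
measured as r², the squared Pearson correlation between raw and tiered
values — algebraically the between-tier over total sum of squares.
Default threshold 0.99; 0.995 is exposed for robustness checks, and
raising the threshold can only increase k (tested). On ~90-node synthetic
groups the 0.99 cut yields roughly 6–12 tiers per layer. Degenerate
conventions keeping the cut total: constant input has r² = 1 (one tier is
exact); a constant tiered vector against varying input scores 0.
Merge-height ties are resolved leftmost-first (highest centrality), so
the tree is deterministic.

### Borda consensus

With *b(α,i)* the tier index of node *i* in layer *α* (tier 1 = most
central), the Borda score is the mean layer rank
*b_i = (1/L) Σ_α b(α,i)*, and consensus rank 1 goes to the lowest score;
equal scores share a dense rank. Because layer ranks are integers, scores
are compared via exact integer rank totals — ties are decided exactly,
never by floating-point coincidence. With one layer the consensus is that
layer's tiering; the aggregation is invariant to layer order; and if a
node weakly outranks another in every layer and strictly in one, it
strictly wins the consensus (verified by brute force over every dense-rank
profile with N ≤ 4, L ≤ 3). Reversed ranks, max(rank) − rank, make larger
= more central and start at 0 — a count-like outcome.

Each group is ranked independently; nothing is pooled across groups
before regression.

### Attribute inference

Reversed consensus (or single-layer) ranks are regressed on node
attributes with a **negative-binomial, log-link** model, group as a random
intercept (`lme4::glmer.nb`), falling back to a group fixed effect
(`MASS::glm.nb`) when the mixed fit fails or only one group is present.
When the counts are *under*dispersed, NB theta estimation diverges; the
fit then uses the Poisson limit of the family (theta → ∞) and records
`family = "poisson_limit"`. Model selection follows the
information-theoretic recipe: AICc = AIC + 2K(K+1)/(n−K−1), candidate set
= all models within 4 AICc points of the best, Akaike weights
exp(−Δ/2)/Σexp(−Δ/2) over the candidate set. The published candidate
formulas for each outcome ship as `default_model_catalogue()`.

Network ranks violate independence assumptions, so p-values come from
**node-label permutations**: attribute row-tuples are shuffled jointly
across nodes *within each group*, the same model is refitted, and each
observed coefficient is compared with its null distribution. Joint
(row-wise) shuffling is a deliberate choice — the sources say only
"shuffle the attributes" — because marginal shuffling would destroy
attribute inter-correlations (e.g. the U-shaped rank–certainty relation)
and test a different null. Rankings depend only on the network, so they
are computed once, not per replicate. Significance is reported two ways:
the literal two-tailed tail rule (significant at p = 0.05 when fewer than
2.5% or more than 97.5% of null coefficients exceed the observed one) and
a corrected empirical p = 2·min(q, 1−q) with the (1+count)/(1+R)
adjustment. Replicates refit with the group *fixed* effect by default
(whether the original randomizations refit the random intercept is not
documented; fixed refits are ~100× faster and target the same
coefficients), and a root seed spawns per-replicate seeds so any replicate
is reproducible in isolation. Replicate fit failures are dropped from the
null, with a warning above 10%.

## The synthetic world

`group_scenario()` states the world the tests assume; its defaults are
fixed, not tuned:

* N = 87 with 30 males (the largest study-group configuration; the study
  population spans 55–101 adults at roughly 1:2.5 male:female).
* Target layer densities: aggression 0.271, status 0.085, policing 0.021,
  grooming 0.259, huddling 0.190.
* Matriline sizes: truncated geometric (p = 0.2) on 1–36 members;
  categories 1–5 / 6–10 / 11+.
* A latent dominance hierarchy: dominance rank = fraction of the group
  outranked. Directed-layer edge probabilities follow a logistic link in
  the rank difference (aggression flows down-hierarchy, status signals up,
  policing out-edges concentrate on top-decile males), with the intercept
  solved by `uniroot` so the expected density hits the target exactly.
  Affiliation layers mix a matriline co-membership bonus with a mild
  rank attraction. Edge weights are zero-truncated Poisson (λ = 2)
  interaction frequencies.
* Dominance certainty is quadratic-in-rank (U-shape) plus noise, clipped
  to the observed range [0.69, 0.98] — its true generative process
  (aggression-pathway consistency) is upstream of this artifact. Ages are
  3 + Gamma(2, rate 0.45) years capped at 29; nursery rearing has
  probability 0.07.

`zero_effect = TRUE` zeroes every slope, making each layer an
Erdős–Rényi draw at the target density, independent of all attributes —
the exchangeable null used to calibrate the permutation test.

What the generator does **not** emulate: temporal dynamics, behavioural
event streams, rank inheritance within matrilines, reciprocity or
triadic closure beyond what the block structure induces. A green test on
synthetic data therefore establishes that the machinery is correct and
calibrated under the stated world, not that the biological conclusions of
any particular study replicate.

## Design choices where the design was open

* **Ties.** Dense ranking throughout (tied items share a rank, next
  distinct value increments by 1); float ties are declared after rounding
  to 12 significant digits; Borda ties use exact integer totals.
* **Betweenness normalisation**: none, since only ranks are used.
* **Deposited-table verification.** `verify_ranking_table()` recomputes
  the Borda consensus from per-layer rank columns of a deposited table
  and reports agreement — built for checking whether such columns are the
  tier ranks the aggregation consumed; exercised on the pipeline's own
  output in the acceptance suite because the original deposited data
  cannot be redistributed.
* **Calibration scale.** The type-I-error acceptance check runs 500
  zero-effect simulations at N = 100 with R = 199 permutation replicates
  (scaled down from 1000 for runtime); with the tail rule at R = 199 the
  nominal rejection rate is exactly 5%, and the accepted band
  [0.03, 0.07] is ±2 binomial standard errors.

## Known limitations

* The consensus deliberately ignores inter-layer dependence: a node
  connected to the same ten partners in two layers outranks one connected
  to ten different partners in each, even though the latter touches more
  of the group.
* Mixed-model permutation refits are available but slow; the default
  fixed-effect refit changes the group adjustment, not the tested
  coefficients.
* Eigenvector direction and the teleportation mass are conventions, not
  estimates; both are exposed as arguments.
* `aicc_candidate_set` compares models on the same data only; it refuses
  differing n rather than guessing.
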