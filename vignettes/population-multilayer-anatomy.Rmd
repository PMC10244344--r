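---
title: "Measuring the anatomy of a population-scale multilayer social network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the anatomy of a population-scale multilayer social network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmln)
```

## The setting

Administrative registers let one build a social network for a complete
population, with *formal ties* sorted into well-defined contexts: close
family (C), extended family (E), household (H), next-door neighbours (N),
school (S) and work (W). popmln models such data as a *node-aligned
multilayer graph*: every layer shares one node set, each layer is a simple
undirected graph, and a pair of people may be connected in several layers at
once. Three of the layers (H, S, W) are affiliation networks — cliques
projected from shared group membership — which shapes every measure
downstream: degrees are bounded by group sizes rather than fat-tailed,
clustering is high *by construction*, and shortest paths hinge on how the
layers interleave rather than on rare long-range ties.

The package provides the measurement stack for such networks (degree
systems, embeddedness and tie range, clustering and excess closure, path
and closeness summaries), a register-style synthetic population generator
so every measure can be exercised without access to restricted microdata,
and a pipeline that strings the analyses together.

## The degree system

For node $u$ and layer $\ell$, $k_{u,\ell}$ counts layer-$\ell$ neighbours.
The total degree $k_u = \sum_\ell k_{u,\ell}$ counts a pair once per layer
it appears in; the unique-neighbour degree $k'_u$ counts distinct alters.
`node_degrees()` returns all of them, and the handshake identity
$\sum_u k_{u,\ell} = 2m_\ell$ is enforced by tests on random graphs.

Family layers derived from a parent-child register with a cutoff date are
incomplete for older cohorts: if a parent was never registered, sibling and
cousin links through that parent cannot be derived.
`missing_family_weights()` implements an inverse-probability weighting:
weight 1 for the strata that are complete by construction (first-generation
migrants, and anyone born after the cutoff — default cutoff age 23,
matching a 2018 reference date with a 1995 register cutoff), and
$w_g = p_{\mathrm{pop}} / p_g$ within 10-year age groups otherwise, where
$p$ is the fraction of people with complete parent information. The source
description of this scheme can be read two ways ("the fraction … in the
group and in the population"); we use the ratio form because it up-weights
under-observed groups and leaves the fully observed population at weight 1.
An age group with *no* complete-information people would get an infinite
weight; such groups (which only arise in small synthetic populations) fall
back to the pooled completeness of all reweighted strata, with a warning.

Degree histograms (`degree_distribution()`) carry a disclosure-control rule
from register practice: bins supported by fewer than `min_cell = 10`
people are suppressed and reported separately, never silently dropped.

`ccdf_tail_slope()` reports the log-log slope of the empirical inverse
cumulative degree distribution over the top `tail_fraction` (default 0.1)
of observations, by OLS by default or a Hill-type estimator. We
deliberately define the tail by the observation quantile rather than by the
top fraction of the *degree range*: a heavy-tailed sample leaves only a
handful of observations in the top tenth of its range, which makes any
range-based estimator degenerate. The slope is descriptive; no power law or
log-normal is fitted or selected, because total degrees in a formal-tie
network follow neither.

## Embeddedness and tie range

The embeddedness of an edge $\{u,v\}$ is its multiplicity-weighted common
neighbour count $\sum_w m_{uw} m_{wv}$ — the number of triangles through the
edge when a triangle is counted once per layer combination of its two wing
edges (`embeddedness()`, with a plain common-neighbour variant behind
`unique_neighbours = TRUE`). Edges with embeddedness zero are *local
bridges*.

The *tie range* of an edge is the length of the second-shortest path
between its endpoints — equivalently their distance once the direct edge is
removed, or one less than the shortest cycle through the edge. Embedded
edges have tie range 2 by definition; an edge with an endpoint of degree
one has tie range $\infty$. `tie_range()` computes it with two alternating
breadth-first searches from the endpoints, each excluding the opposite
endpoint. The implementation expands the smaller frontier first (a
performance choice that cannot change the result), checks every newly
reached node against the other search's distance labels, and returns the
minimal summed depth at the first intersection; a search whose frontier
empties has exhausted its reachable set, and only when both empty is the
range infinite. Ranges beyond `max_range` (default 10, comfortably above
the "long tie" threshold of 6 used in the census) are *censored*, encoded
as `NA` and kept distinct from `Inf`; raising the cap never changes a
finite value, which is property-tested. The whole procedure is verified
edge-by-edge against shortest paths on the edge-deleted graph on hundreds
of random multilayer graphs.

## Clustering and excess closure

The local clustering coefficient $c^{\mathrm{local}}_u$ is computed on the
flattened simple graph: closed alter pairs over $\binom{k'_u}{2}$. In an
affiliation-heavy network it is structurally inflated — every household,
class and small workplace is a clique — so it mostly measures the
generating mechanism, not social structure. *Excess closure* discounts the
within-layer part. Around an ego $u$:

* $P_u = \binom{k_u}{2} - \sum_v \binom{m_{uv}}{2}$ — the number of *alter
  tie pairs*: pairs of ego edges leading to two different alters (pairs of
  parallel edges to the same alter cannot form a wedge);
* $T^{\mathrm{pure}}_u$ — alter pairs closed entirely inside at least one
  single layer;
* $T^{\mathrm{unique}}_u$ — alter pairs closed by any layer combination,
  each node triplet counted once;
* $c^{\mathrm{pure}}_u = T^{\mathrm{pure}}_u / P_u$ and
  $c^{\mathrm{actual}}_u = T^{\mathrm{unique}}_u / P_u$;
* $c^{\mathrm{excess}}_u = \dfrac{c^{\mathrm{actual}}_u -
  c^{\mathrm{pure}}_u}{1 - c^{\mathrm{pure}}_u}$.

$c^{\mathrm{pure}}$ is the clustering the layer mechanisms alone would
produce if the ego's per-layer neighbourhoods neither overlapped nor
cross-linked; $c^{\mathrm{excess}}$ locates the actual clustering between
that floor and 1. Two numerical choices matter:

* **Triplet-level deduplication of $T^{\mathrm{pure}}$.** Summing per-layer
  triangle counts would count a triplet once per layer that closes it,
  which can push $T^{\mathrm{pure}}$ above $T^{\mathrm{unique}}$ and
  $c^{\mathrm{excess}}$ below 0. We therefore count a triplet as pure if
  *some* single layer closes it, computed exactly by inclusion–exclusion
  over layer subsets (triangles of layer-intersection graphs — fast,
  because cross-layer edge overlap is sparse). This guarantees
  $0 \le c^{\mathrm{pure}} \le c^{\mathrm{actual}} \le 1$ and
  $c^{\mathrm{excess}} \in [0,1]$. The literal per-layer sum is still
  reported as `t_pure_multiplicity`.
* **Degenerate egos are flagged, not zeroed.** When $P_u = 0$ (fewer than
  two ego edges to distinct alters) or $c^{\mathrm{pure}}_u = 1$ (no room
  above the floor), `c_excess` is `NA` with `defined = FALSE`, and all
  averaging functions exclude such egos. Coercing them to 0 would bias
  every life-course curve toward zero exactly where degrees are small.

On any single-layer graph $c^{\mathrm{excess}} \equiv 0$ wherever defined
and $c^{\mathrm{actual}} = c^{\mathrm{local}}$ wherever both are defined;
both collapses are property-tested, and all quantities are verified against
brute-force triangle enumeration on random multilayer graphs.

`triangle_type_census()` classifies each triangle realisation around an ego
by the layer triplet $(\ell_1, \ell_2, \ell_3)$ — wing layers ordered by
alter label, closing layer in the middle. A realisation is *cohesive* when
$\ell_1 = \ell_3$ (both ego edges from the same context). For *bridging* we
require all three layers distinct: the natural reading of "the closing edge
bridges two different contexts of the ego" excludes the case
$\ell_1 = \ell_3$ (two family ties closed by a household edge do not bridge
contexts, whatever the closing layer is), even though the closing-edge
condition alone would admit it. Realisations with $\ell_1 \ne \ell_3$ whose
closing edge lies in a wing layer count as neither — they are overlap
between two contexts rather than a bridge from a third.

## Paths, components, closeness

All path-based measures run on the flattened simple graph — multiplicities
never shorten a path. `graph_components()` wraps component extraction;
`exact_diameter()` computes the exact diameter with a double-sweep lower
bound followed by an eccentricity-bounded scan (nodes processed by
decreasing BFS level from a central root; a node at level $l$ cannot raise
the bound once $2l$ falls below it), falling back to all-pairs BFS for
small graphs; the bounded search is tested to equal all-pairs BFS on random
graphs. `avg_shortest_path_sampled()` estimates the mean distance from
uniformly sampled ordered node pairs with replacement (self-pairs
excluded); the sampling scheme is our choice, as the source protocol for
the published $1000\,n$-pair samples is not stated. The estimate switches
to the exact all-pairs mean when the budget covers all pairs, and is tested
to fall within three standard errors of the exact mean. Closeness
centrality $(n-1)/\sum_v d_{uv}$ is exact via BFS from every node, or
approximated from a uniform pivot sample (default 0.03% of nodes, raised to
one pivot minimum): distance sums are estimated unbiasedly from the pivots,
excluding a pivot's own zero self-distance.

## The synthetic register generator

`generate_primitives()` draws the raw register material — people with ages,
registered parent-child and partner links, households with coordinates,
school groups, employers — and the six layers are *derived* from it exactly
the way the register construction rules prescribe:

* **C** — undirected union of parent-child, partner and sibling links
  (siblings = shared registered parent, observable even if the parent has
  died, as long as the link was recorded);
* **E** — deterministic kin compositions: grandparent, aunt/uncle, first
  cousin, parent-in-law, sibling-in-law, stepparent, step-sibling; pairs
  already in C are excluded;
* **H** — a clique per household, institutional households included;
* **N** — per person, the households within 50 m of their own address,
  randomly down-sampled to 10 when more qualify; the person links to every
  member of the selected households, and an undirected edge exists when
  either side selects the other;
* **S** — a clique per (school, year, class group, level[, programme]),
  with level tags for primary/secondary sublayer filters;
* **W** — full clique for workplaces under 100 employees; in larger ones
  each employee links to their 100 geographically closest colleagues
  (Euclidean distance between home addresses, ties broken by person id),
  again with union semantics.

The mechanistic rules above (radii, caps, thresholds, cutoff logic) are the
generator's contract and are what the tests pin down: household degree
equals household size minus one, school groups and small workplaces are
cliques, a person with more than ten 50-metre neighbours gets exactly ten,
an employee of a large workplace selects exactly one hundred colleagues,
siblings sit at parent-child distance 2 and first cousins at 4.

The *distributional* choices are ours and are deliberately plain:

* a three-and-a-half-generation population (defaults: 24% aged 60+, 48%
  aged 25–59, the rest children of the middle generation). Adults are
  assigned as children of elderly units with mean sibship 2.6 — the
  completed cohort fertility of the oldest generation — and younger adults
  (25–37) additionally as children of older adult couples (50+). Without
  that second rung the parent-child backbone would fall apart into shallow
  two-generation stubs; with it, co-parenting (two parents linked through
  a common child) percolates family trees into larger components, the
  mechanism behind the kinship "backbone" of the real network;
* partnership rates 0.55 (elderly) / 0.62 (adults), partners matched by
  age, sibling pairings vetoed;
* a register cutoff completeness model: people born after the cutoff and
  first-generation migrants are complete by construction; for the rest the
  probability of observable parent links declines with age;
* geometry: households scattered around town centres (Gaussian, sd 250 m)
  with a 15% uniform rural fraction over a 20 km square; urbanisation
  levels are distance-to-centre bands; workplace sizes are log-normal
  (meanlog 2.7, sdlog 1.2, capped at 400); income deciles are ranked
  household scores that rise with employment, workplace size, education
  and age.

What the generator emulates is the *construction logic* of register data;
what it does not emulate is Dutch demographic calibration (no census
marginals, no migration history, no longitudinal dynamics, no
institutional-household typology beyond a size flag). Passing tests
therefore certify the measurement machinery and the construction rules —
they do not certify that any statistic matches the published values of the
real 17.2M-person network, which sit outside what a $10^4$-person desk
model can reproduce.

## The pipeline and problem sizes

`run_anatomy()` chains generation (optional), the degree block, the
layer-combination path study (default sequence: parent-child backbone;
C+E+H; +N; +primary; +secondary; + rest of school and small work; + all
work — the cumulative order of increasing tie "likeliness"), the
embeddedness/tie-range census, closure-versus-degree curves, and
life-course curves, writing plain CSVs plus a run log; identical seeds
yield byte-identical outputs, which is tested.

Default desk-scale sizes are our own: populations of $10^3$–$10^4$ people
in tests, `pairs_per_node = 5` in the pipeline (the low-level function
defaults to the published budget of 1000), closeness pivots at 0.5% of the
giant component, and 5-year age bins in examples (1-year bins are the
natural choice at population scale; at $10^4$ people the 10-node
suppression rule would erase most 1-year cells). The oracle suites run 200
random multilayer graphs against brute-force enumeration and a dozen
random graphs against all-pairs BFS.

## Worked example

```{r example, eval = FALSE}
pop <- synth_population(population_config(n_people = 10000, seed = 42))
cs <- ego_closure_all(pop$graph)
summary(cs$c_local)             # high: affiliation cliques everywhere
summary(cs$c_excess[cs$defined])  # much lower: cross-layer closure only

ps <- layer_combination_study(pop$graph, pairs_per_node = 5, seed = 42)
ps[, c("combination", "gc", "diameter", "mean_distance")]

lt <- long_tie_census(pop$graph)
lt$long_share                   # long ties are vanishingly rare
```

## Known limitations

* The generator's demographic realism is intentionally minimal; it is a
  test-bed, not a calibrated synthetic population.
* Excess closure needs at least two ego edges to distinct alters; in
  sparse layers many egos are undefined and group averages rest on fewer
  people than the population size suggests.
* The closeness approximation is a pivot estimator: unbiased for distance
  sums, slightly biased for their reciprocal; at the default pivot fraction
  it ranks nodes well but individual values carry sampling noise.
* Tie-range censoring at `max_range` trades exactness beyond the cap for
  speed; the census needs only "at least 6", so the default cap of 10
  loses nothing there.
* No inter-layer coupling edges, no weighted or directed paths, no
  betweenness, and no global transitivity variants — they are outside the
  measurement stack this package implements.
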