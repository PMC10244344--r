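# popmln

Measurement stack for population-scale multilayer social networks.

Register data lets one map the social network of an entire population:
people connected by *formal ties* in well-defined contexts — close family
(C), extended family (E), household (H), next-door neighbours (N), school
(S) and work (W). Each context is a layer of a *node-aligned multilayer
graph* $G=(V,E,L)$ with edges encoded by a reduced adjacency tensor
$A_{uv\ell}$. Three layers are affiliation networks (cliques projected from
shared households, school groups and workplaces), which makes the standard
social-network toolkit behave unusually: degrees are bounded rather than
fat-tailed, local clustering is enormous *by construction*, and small-world
distances arise from layer interplay rather than from rare long-range
edges. popmln is for network and computational social scientists (and
epidemic modellers building contact structures) who need the measurement
machinery for such data.

The package implements:

* **Degree systems** — layer degrees $k_{u,\ell}$, total degree
  $k_u=\sum_\ell k_{u,\ell}$ and unique-neighbour degree $k'_u$;
  zero-degree and active-layer censuses; weighted histograms with the
  `min_cell = 10` disclosure-suppression rule; CCDF tail slopes;
  inverse-probability weights for register-cutoff missingness; weighted
  degree correlations with Fisher-z intervals; layer edge-overlap matrices.
* **Embeddedness and tie range** — multiplicity-weighted triangle count per
  edge $\sum_w m_{uw}m_{wv}$; the tie range (second-shortest path between
  an edge's endpoints) by an alternating bidirectional BFS with censoring;
  the long-tie ("network wormhole", range ≥ 6) census.
* **Excess closure** — the ego-level measure
  $c^{excess}_u = (c^{actual}_u - c^{pure}_u)/(1 - c^{pure}_u)$, where
  $c^{pure}$ is the clustering floor produced by single-layer triangles
  alone, over the alter tie pairs
  $P_u=\binom{k_u}{2}-\sum_v\binom{m_{uv}}{2}$; plus the
  cohesion/bridging triangle-type census.
* **Paths** — components and giant component, exact diameter by a
  double-sweep + eccentricity-bounded search, sampled average shortest
  path length, exact and pivot-approximated closeness centrality.
* **A synthetic register generator** — family trees with partner links,
  household cliques, 50 m / cap-10 next-door assignment, school-group
  cliques, and small-workplace cliques with geographic 100-nearest
  sampling above the 100-employee threshold, so the whole stack runs
  without restricted microdata.
* **An anatomy pipeline** — layer-combination path study, long-tie census,
  closure-vs-degree curves, demographic life-course curves; seeded and
  byte-reproducible.

## Worked example

```r
library(popmln)
pop <- synth_population(population_config(n_people = 10000, seed = 42))
pop$graph
#> Node-aligned multilayer graph: 10000 nodes, 296080 edges, 6 layers
#>   C   17129 edges
#>   E   16641 edges
#>   H   6364 edges
#>   N   67906 edges
#>   S   5262 edges
#>   W   182778 edges

cs <- ego_closure_all(pop$graph)
mean(cs$c_local, na.rm = TRUE)      #> 0.511
mean(cs$c_excess[cs$defined])       #> 0.112
```

Local clustering averages 0.51 — the affiliation cliques and kinship
structure close half of all alter pairs — while excess closure averages
only 0.11: most of that closure is *expected* within single layers, and
only a ninth of the available room is closed by genuine cross-layer
overlap and bridging.

```r
layer_combination_study(pop$graph, pairs_per_node = 5, seed = 42)
#>     combination     gc diameter mean_distance
#> 1            Cp 0.0103       31         11.80
#> 2         C+E+H 0.1369       20          6.46
#> 3       C+E+H+N 0.9686       10          4.30
#> 4    C+E+H+N+Sp 0.9686       10          4.16
#> 5 C+E+H+N+Sp+Ss 0.9690       10          4.08
#> 6  C+E+H+N+S+Ws 0.9773        8          3.59
#> 7   C+E+H+N+S+W 0.9915        6          3.00
```

Read down the rows: starting from the sparse parent-child backbone (a
fragmented forest of family trees, giant component ~1% of the population,
mean distance ~12), each added layer merges components and cuts distances —
next-door neighbours alone lift the giant component to 97% of the
population, and school plus work edges push mean distances to 3. The
distance column is non-increasing and the giant-component column
non-decreasing along any cumulative sequence, the mechanism behind the
small-world property of these networks.

```r
lt <- long_tie_census(pop$graph)
lt$n_bridges; lt$long_share
#> 306 of 291512 edges have embeddedness zero; long-tie share 6.9e-06
```

Local bridges (edges whose endpoints share no neighbour) are 0.1% of the
network and ties of range ≥ 6 are practically absent — shortcuts come from
co-affiliation, not from "wormhole" edges.

```r
# the excess-closure mechanics on a minimal ego: two alters in different
# layers whose own tie lives in a third layer
g <- mln_graph(data.frame(u = c("u", "u", "a"), v = c("a", "b", "b"),
                          layer = c("C", "S", "N")))
ego_closure(g, "u")[, c("p_u", "t_pure", "t_unique", "c_excess")]
#>   p_u t_pure t_unique c_excess
#> 1   1      0        1        1
```

One alter tie pair, no single layer closes it, one cross-layer triangle:
all of the ego's closure is excess.

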