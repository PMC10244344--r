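# All path-based measures operate on the flattened simple graph: layer
# multiplicities never shorten paths in a node-aligned multilayer network.
flat_igraph <- function(g) {
  if (inherits(g, "igraph")) g
  else if (inherits(g, "mln_flat")) as_igraph(g)
  else as_igraph(flatten(g))
}

#' Connected components and the giant component
#'
#' @param g an `mln_graph`, `mln_flat` or igraph object; paths use the
#'   flattened simple graph
#' @return list with `membership` (named component labels), `sizes`
#'   (decreasing), `n_components`, `giant` (node ids of the largest
#'   component) and `gc` (relative giant-component size, giant / all nodes)
#' @export
graph_components <- function(g) {
  ig <- flat_igraph(g)
  comp <- igraph::components(ig)
  sizes <- sort(comp$csize, decreasing = TRUE)
  giant_label <- which.max(comp$csize)
  giant <- igraph::V(ig)$name[comp$membership == giant_label]
  list(membership = stats::setNames(comp$membership, igraph::V(ig)$name),
       sizes = sizes, n_components = comp$no, giant = giant,
       gc = comp$csize[giant_label] / igraph::vcount(ig))
}

# Single-source BFS distances (unreachable = Inf) on an igraph.
bfs_dist <- function(ig, from) {
  as.numeric(igraph::distances(ig, v = from, algorithm = "unweighted"))
}

#' Exact diameter of a connected graph
#'
#' Longest shortest path length, computed without a full all-pairs sweep:
#' a double-sweep BFS gives a lower bound, then nodes are processed in
#' decreasing order of BFS level from a central root; each node's
#' eccentricity can only raise the bound, and the scan stops once the
#' remaining levels can no longer beat it (iFUB-style bounding). Small
#' graphs (`n <= all_pairs_limit`) fall back to all-pairs BFS.
#'
#' @param g a *connected* `mln_graph`, `mln_flat` or igraph object (use the
#'   giant component from [graph_components()])
#' @param all_pairs_limit below this many nodes, use all-pairs BFS
#' @return integer diameter
#' @export
exact_diameter <- function(g, all_pairs_limit = 1000) {
  ig <- flat_igraph(g)
  n <- igraph::vcount(ig)
  if (n <= 1) return(0L)
  if (igraph::ecount(ig) == 0 || igraph::components(ig)$no > 1) {
    stop("disconnected input: extract the giant component first ",
         "(see graph_components())", call. = FALSE)
  }
  if (n <= all_pairs_limit) {
    return(as.integer(max(igraph::distances(ig, algorithm = "unweighted"))))
  }
  # double sweep: farthest node from an arbitrary start, then its farthest
  d0 <- bfs_dist(ig, 1)
  a <- which.max(d0)
  da <- bfs_dist(ig, a)
  b <- which.max(da)
  lb <- as.integer(da[b])
  # root the level structure at a midpoint of the a-b path (low eccentricity)
  path <- igraph::shortest_paths(ig, from = a, to = b)$vpath[[1]]
  root <- path[[ceiling(length(path) / 2)]]
  lev <- bfs_dist(ig, root)
  ord <- order(lev, decreasing = TRUE)
  best <- lb
  for (i in ord) {
    # any path through a node at level l has length <= 2l; once 2l <= best,
    # deeper nodes cannot improve the bound
    if (2 * lev[i] <= best) break
    ecc <- max(bfs_dist(ig, i))
    if (ecc > best) best <- as.integer(ecc)
  }
  as.integer(best)
}

#' Sampled average shortest path length
#'
#' Estimates the mean shortest path length of a connected graph from
#' uniformly sampled ordered node pairs (with replacement, excluding
#' self-pairs). Distances are computed by BFS, batched per distinct source
#' node to bound memory. When the pair budget covers all unordered pairs the
#' exact mean is returned with zero standard error.
#'
#' @param g a connected `mln_graph`, `mln_flat` or igraph object
#' @param pairs_per_node sampled pairs per node; total budget is
#'   `pairs_per_node * n` (default 1000 as used for population-scale runs;
#'   scale down at desk scale)
#' @param seed integer seed for the pair sample (mandatory for reproducible
#'   pipeline runs)
#' @param block number of source nodes per BFS batch
#' @return list `mean`, `se`, `n_pairs`, `exact` (logical), `seed`
#' @export
avg_shortest_path_sampled <- function(g, pairs_per_node = 1000, seed,
                                      block = 200L) {
  ig <- flat_igraph(g)
  n <- igraph::vcount(ig)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  budget <- ceiling(pairs_per_node * n)
  if (budget < 1) stop("pair budget must be >= 1", call. = FALSE)
  if (choose(n, 2) <= budget) {
    dmat <- igraph::distances(ig, algorithm = "unweighted")
    d <- dmat[upper.tri(dmat)]
    if (any(is.infinite(d))) stop("disconnected input", call. = FALSE)
    return(list(mean = mean(d), se = 0, n_pairs = length(d), exact = TRUE,
                seed = if (missing(seed)) NA_integer_ else seed))
  }
  if (missing(seed)) stop("seed is required for sampled estimates",
                          call. = FALSE)
  set.seed(seed)
  src <- sample.int(n, budget, replace = TRUE)
  dst <- sample.int(n - 1L, budget, replace = TRUE)
  dst <- ifelse(dst >= src, dst + 1L, dst)  # uniform over ordered pairs
  ord <- order(src)
  src <- src[ord]; dst <- dst[ord]
  d <- numeric(budget)
  uniq <- unique(src)
  pos <- 1L
  for (s in seq(1L, length(uniq), by = block)) {
    batch <- uniq[s:min(s + block - 1L, length(uniq))]
    dmat <- igraph::distances(ig, v = batch, algorithm = "unweighted")
    rows <- match(src[src %in% batch], batch)
    sel <- which(src %in% batch)
    d[sel] <- dmat[cbind(rows, dst[sel])]
  }
  if (any(is.infinite(d))) stop("disconnected input", call. = FALSE)
  list(mean = mean(d), se = stats::sd(d) / sqrt(budget), n_pairs = budget,
       exact = FALSE, seed = seed)
}

#' Closeness centrality, exact or pivot-approximated
#'
#' Closeness of `u` is `(n - 1) / sum_v d(u, v)` on the (connected) flattened
#' graph. The exact mode computes all BFS trees; the approximate mode
#' estimates each node's distance sum from a uniform pivot sample,
#' `sum_v d(u, v) ~ (n - 1) / p * sum_pivots d(u, pivot)` (an unbiased
#' estimate of the distance sum, with pivots drawn without replacement and
#' self-distances excluded).
#'
#' @param g a connected `mln_graph`, `mln_flat` or igraph object
#' @param mode `"exact"` or `"approx"`
#' @param sample_frac fraction of nodes used as pivots in approximate mode
#'   (default `3e-4`, raised to at least one pivot with a warning)
#' @param seed integer seed for the pivot sample (approx mode)
#' @return named numeric vector of closeness values
#' @export
closeness_centrality <- function(g, mode = c("exact", "approx"),
                                 sample_frac = 3e-4, seed = NULL) {
  mode <- match.arg(mode)
  ig <- flat_igraph(g)
  n <- igraph::vcount(ig)
  nm <- igraph::V(ig)$name
  if (mode == "exact") {
    cc <- igraph::closeness(ig, normalized = TRUE)
    return(stats::setNames(as.numeric(cc), nm))
  }
  p <- floor(sample_frac * n)
  if (p < 1) {
    warning("sample_frac yields no pivots; using 1 pivot")
    p <- 1L
  }
  if (!is.null(seed)) set.seed(seed)
  pivots <- sample.int(n, p)
  dmat <- igraph::distances(ig, v = pivots, algorithm = "unweighted")
  # per node: mean distance to pivots, excluding the node itself when it is
  # a pivot (self-distance 0 would bias the sum downwards)
  sums <- Matrix::colSums(dmat)
  npiv <- rep(p, n)
  npiv[pivots] <- p - 1L
  npiv[npiv == 0] <- NA_integer_
  est_sum <- (n - 1) * sums / npiv
  stats::setNames((n - 1) / est_sum, nm)
}

#' Component / distance summary of a layer combination
#'
#' Bundles the global measures reported for a layer combination: number of
#' non-isolated nodes, edge count (flattened pairs and layer edges),
#' component count, relative giant-component size, exact giant-component
#' diameter, and sampled average shortest path length within the giant
#' component.
#'
#' @param g an `mln_graph`
#' @param pairs_per_node pair budget per node for the distance sample
#' @param seed integer seed for the sample
#' @param diameter compute the exact diameter (can be skipped for speed)
#' @return object of class `path_report`: list with `layers`, `n_nodes`,
#'   `n_non_isolated`, `n_pair_edges`, `n_layer_edges`, `n_components`,
#'   `gc`, `diameter`, `mean_distance`, `se`, `n_pairs`, `exact`, `seed`
#' @export
path_report <- function(g, pairs_per_node = 1000, seed = 1L, diameter = TRUE) {
  stopifnot(inherits(g, "mln_graph"))
  fl <- flatten(g)
  ig <- as_igraph(fl)
  deg <- igraph::degree(ig)
  comp <- graph_components(ig)
  giant <- igraph::induced_subgraph(ig, comp$giant)
  d <- if (igraph::vcount(giant) >= 2) {
    avg_shortest_path_sampled(giant, pairs_per_node, seed)
  } else list(mean = NA_real_, se = NA_real_, n_pairs = 0L, exact = TRUE,
              seed = seed)
  structure(list(
    layers = unique(g$edges$layer),
    n_nodes = length(g$nodes),
    n_non_isolated = sum(deg > 0),
    n_pair_edges = nrow(fl$edges),
    n_layer_edges = nrow(g$edges),
    n_components = comp$n_components,
    gc = comp$gc,
    diameter = if (diameter && igraph::vcount(giant) >= 1)
      exact_diameter(giant) else NA_integer_,
    mean_distance = d$mean, se = d$se, n_pairs = d$n_pairs,
    exact = d$exact, seed = d$seed), class = "path_report")
}

#' @export
print.path_report <- function(x, ...) {
  cat(sprintf(
    "Path report [%s]: %d/%d non-isolated nodes, %d pairs (%d layer edges)\n",
    paste(x$layers, collapse = "+"), x$n_non_isolated, x$n_nodes,
    x$n_pair_edges, x$n_layer_edges))
  cat(sprintf("  components %d, GC %.4f, D %s, mean distance %.3f (se %.4f)\n",
              x$n_components, x$gc, as.character(x$diameter),
              x$mean_distance, x$se))
  invisible(x)
}
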