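# Per-node triangle counts for an edge set given as pair keys, on n nodes.
triangles_from_keys <- function(keys, n) {
  if (length(keys) == 0) return(integer(n))
  ui <- (keys - 1) %/% n + 1
  vi <- keys - (ui - 1) * n
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(ui, vi))
  igraph::count_triangles(ig)
}

# Deduplicated pure-triangle count per node: number of alter pairs {v, w}
# such that all three edges {u,v}, {u,w}, {v,w} lie within at least one
# single layer. Exact inclusion-exclusion over layer subsets: a triplet
# closed within every layer of a subset S is a triangle of the
# edge-intersection graph of S, so
#   T_pure = sum_S (-1)^(|S|+1) triangles(intersection(S)).
# Subsets with an empty edge intersection are pruned, which terminates fast
# because cross-layer edge overlap is sparse.
t_pure_dedup <- function(layer_keys, n) {
  total <- integer(n)
  frontier <- lapply(seq_along(layer_keys), function(i) {
    list(last = i, keys = layer_keys[[i]], size = 1L)
  })
  while (length(frontier) > 0) {
    nxt <- list()
    for (s in frontier) {
      if (length(s$keys) == 0) next
      sign <- if (s$size %% 2 == 1) 1L else -1L
      total <- total + sign * triangles_from_keys(s$keys, n)
      if (s$last < length(layer_keys)) {
        for (j in (s$last + 1):length(layer_keys)) {
          inter <- intersect(s$keys, layer_keys[[j]])
          if (length(inter) >= 3) {
            nxt[[length(nxt) + 1]] <- list(last = j, keys = inter,
                                           size = s$size + 1L)
          }
        }
      }
    }
    frontier <- nxt
  }
  total
}

#' Ego-level closure summary: local clustering and excess closure
#'
#' For every node `u` of a multilayer graph this computes the quantities
#' behind the excess-closure measure:
#' \describe{
#'   \item{`k_total`, `k_unique`}{total degree (counting multi-layer ties
#'     once per layer) and number of distinct alters}
#'   \item{`p_u`}{number of alter tie pairs,
#'     `choose(k_total, 2) - sum_v choose(m_uv, 2)`, i.e. pairs of ego edges
#'     leading to two *different* alters}
#'   \item{`t_pure`}{number of alter pairs closed entirely within at least
#'     one single layer (each node triplet counted once);
#'     `t_pure_multiplicity` is the per-layer sum that counts a triplet once
#'     per layer closing it}
#'   \item{`t_unique`}{number of alter pairs closed by any layer combination
#'     (each triplet once)}
#'   \item{`c_pure`, `c_actual`}{`t_pure / p_u` and `t_unique / p_u`;
#'     `c_pure` is the theoretical minimum clustering if layers neither
#'     overlapped nor cross-linked}
#'   \item{`c_excess`}{`(c_actual - c_pure) / (1 - c_pure)`: closure in
#'     excess of what single-layer triangles provide, in `[0, 1]`}
#'   \item{`c_local`}{ordinary local clustering on the flattened simple
#'     graph, `t_unique / choose(k_unique, 2)`}
#' }
#' Egos with `p_u = 0` (fewer than two ego edges to distinct alters) or
#' `c_pure = 1` have no room for excess closure; their `c_excess` is `NA`
#' with `defined = FALSE`, and they must be excluded from averages rather
#' than coerced to zero. `c_local` is likewise `NA` when `k_unique < 2`.
#'
#' @param g an `mln_graph`
#' @param nodes optional subset of node ids to return (all nodes by default)
#' @return data.frame with one row per node and the columns above plus
#'   `defined` (logical: `c_excess` well-defined)
#' @examples
#' g <- mln_graph(data.frame(u = c("u", "u", "a"), v = c("a", "b", "b"),
#'                           layer = c("C", "S", "N")))
#' ego_closure_all(g)
#' @export
ego_closure_all <- function(g, nodes = NULL) {
  stopifnot(inherits(g, "mln_graph"))
  n <- length(g$nodes)
  fl <- flatten(g)
  idx <- edge_indices(g, fl$edges)
  k_unique <- tabulate(c(idx$ui, idx$vi), nbins = n)
  m <- fl$edges$m
  k_total <- numeric(n)
  sum_choose_m <- numeric(n)
  for (side in list(idx$ui, idx$vi)) {
    k_total <- k_total + unname(tapply2(m, side, n))
    sum_choose_m <- sum_choose_m + unname(tapply2(choose(m, 2), side, n))
  }
  p_u <- choose(k_total, 2) - sum_choose_m

  flat_ig <- igraph::make_empty_graph(n, directed = FALSE)
  flat_ig <- igraph::add_edges(flat_ig, rbind(idx$ui, idx$vi))
  t_unique <- igraph::count_triangles(flat_ig)

  layer_keys <- lapply(g$layers, function(l) {
    e <- g$edges[g$edges$layer == l, , drop = FALSE]
    li <- edge_indices(g, e)
    pair_key(li$ui, li$vi, n)
  })
  t_pure_mult <- integer(n)
  for (keys in layer_keys) t_pure_mult <- t_pure_mult + triangles_from_keys(keys, n)
  t_pure <- t_pure_dedup(layer_keys, n)

  c_pure <- ifelse(p_u > 0, t_pure / p_u, NA_real_)
  c_actual <- ifelse(p_u > 0, t_unique / p_u, NA_real_)
  defined <- p_u > 0 & !is.na(c_pure) & c_pure < 1
  c_excess <- ifelse(defined, (c_actual - c_pure) / (1 - c_pure), NA_real_)
  c_local <- ifelse(k_unique >= 2, t_unique / choose(k_unique, 2), NA_real_)

  out <- data.frame(node = g$nodes, k_total = as.integer(k_total),
                    k_unique = as.integer(k_unique), p_u = p_u,
                    t_pure = as.integer(t_pure),
                    t_pure_multiplicity = as.integer(t_pure_mult),
                    t_unique = as.integer(t_unique),
                    c_pure = c_pure, c_actual = c_actual,
                    c_local = c_local, c_excess = c_excess,
                    defined = defined, stringsAsFactors = FALSE)
  if (!is.null(nodes)) {
    out <- out[match(nodes, out$node), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Grouped sum of x by integer index (1..n); dense result.
tapply2 <- function(x, index, n) {
  out <- numeric(n)
  agg <- rowsum(x, group = index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @rdname ego_closure_all
#' @param u a node id
#' @return `ego_closure(g, u)` returns the single-row summary for `u`
#' @export
ego_closure <- function(g, u) {
  if (!u %in% g$nodes) stop("unknown node: ", u, call. = FALSE)
  ego_closure_all(g, nodes = u)
}

#' Local clustering coefficient on the flattened graph
#'
#' Fraction of pairs of distinct flattened neighbours of `u` that are
#' themselves connected (in any layer). `NA` when `u` has fewer than two
#' distinct neighbours.
#'
#' @param g an `mln_graph`
#' @param u node id (or vector of ids)
#' @return numeric vector of clustering coefficients in `[0, 1]`
#' @export
local_clustering <- function(g, u = NULL) {
  cs <- ego_closure_all(g, nodes = u)
  stats::setNames(cs$c_local, cs$node)
}

#' Edge embeddedness
#'
#' Multiplicity-weighted common-neighbour count of an edge: the number of
#' triangles the edge takes part in, where a triangle is counted once per
#' combination of layers carrying its two wing edges
#' (`sum_w m_uw * m_wv` over common flattened neighbours `w`). With
#' `unique_neighbours = TRUE` the plain number of common flattened
#' neighbours is returned instead. Edges with embeddedness zero are local
#' bridges: their endpoints share no neighbour.
#'
#' @param g an `mln_graph`
#' @param u,v endpoints of an edge of `g` (in any layer)
#' @param unique_neighbours count each common neighbour once instead of
#'   weighting by layer multiplicities
#' @return non-negative number
#' @export
embeddedness <- function(g, u, v, unique_neighbours = FALSE) {
  fl <- flatten(g)
  e <- fl$edges
  is_edge <- (e$u == u & e$v == v) | (e$u == v & e$v == u)
  if (!any(is_edge)) stop("(", u, ", ", v, ") is not an edge", call. = FALSE)
  nb_u <- c(stats::setNames(e$m[e$u == u], e$v[e$u == u]),
            stats::setNames(e$m[e$v == u], e$u[e$v == u]))
  nb_v <- c(stats::setNames(e$m[e$u == v], e$v[e$u == v]),
            stats::setNames(e$m[e$v == v], e$u[e$v == v]))
  common <- setdiff(intersect(names(nb_u), names(nb_v)), c(u, v))
  if (length(common) == 0) return(0)
  if (unique_neighbours) length(common)
  else sum(as.numeric(nb_u[common]) * as.numeric(nb_v[common]))
}

#' Embeddedness of every flattened edge
#'
#' Vectorised multiplicity-weighted embeddedness over all unique node pairs
#' of the flattened graph, computed blockwise through sparse
#' adjacency-column products.
#'
#' @param g an `mln_graph`
#' @param unique_neighbours see [embeddedness()]
#' @param block number of edges per sparse block
#' @return data.frame `u`, `v`, `m` (layer multiplicity), `embeddedness`
#' @export
edge_embeddedness <- function(g, unique_neighbours = FALSE, block = 20000L) {
  fl <- flatten(g)
  n <- length(fl$nodes)
  e <- fl$edges
  if (nrow(e) == 0) {
    return(data.frame(u = character(), v = character(), m = integer(),
                      embeddedness = numeric()))
  }
  idx <- edge_indices(g, e)
  vals <- if (unique_neighbours) rep(1, nrow(e)) else e$m
  M <- Matrix::sparseMatrix(i = c(idx$ui, idx$vi), j = c(idx$vi, idx$ui),
                            x = c(vals, vals), dims = c(n, n))
  emb <- numeric(nrow(e))
  starts <- seq(1L, nrow(e), by = block)
  for (s in starts) {
    sel <- s:min(s + block - 1L, nrow(e))
    emb[sel] <- Matrix::colSums(M[, idx$ui[sel], drop = FALSE] *
                                  M[, idx$vi[sel], drop = FALSE])
  }
  data.frame(u = e$u, v = e$v, m = e$m, embeddedness = emb,
             stringsAsFactors = FALSE)
}

# 1-based integer adjacency list of the flattened graph.
flat_adjacency <- function(g) {
  fl <- flatten(g)
  n <- length(fl$nodes)
  idx <- edge_indices(g, fl$edges)
  adj <- vector("list", n)
  ii <- c(idx$ui, idx$vi)
  jj <- c(idx$vi, idx$ui)
  ord <- order(ii)
  split_sizes <- tabulate(ii, nbins = n)
  jj <- jj[ord]
  pos <- 1L
  for (i in seq_len(n)) {
    if (split_sizes[i] > 0) {
      adj[[i]] <- jj[pos:(pos + split_sizes[i] - 1L)]
      pos <- pos + split_sizes[i]
    } else adj[[i]] <- integer()
  }
  adj
}

# Alternating bidirectional BFS for the second-shortest path between the
# endpoints of an edge. The two searches exclude the opposite endpoint (so
# the direct edge is never traversed); the smaller frontier is expanded
# first; on the first intersection of the search trees the minimum summed
# depth over intersecting nodes is the tie range. Returns Inf when a search
# dies out, NA when censored at max_range.
alt_bfs_tie_range <- function(adj, s, t, max_range) {
  n <- length(adj)
  dist_s <- rep(-1L, n); dist_t <- rep(-1L, n)
  dist_s[s] <- 0L; dist_t[t] <- 0L
  dist_s[t] <- -2L; dist_t[s] <- -2L  # opposite endpoint excluded
  frontier_s <- s; frontier_t <- t
  depth_s <- 0L; depth_t <- 0L
  repeat {
    # a search with an exhausted frontier has seen its whole reachable set;
    # only when both are exhausted is there no second path at all
    if (length(frontier_s) == 0 && length(frontier_t) == 0) return(Inf)
    if (depth_s + depth_t >= max_range) return(NA_real_)
    expand_s <- length(frontier_s) > 0 &&
      (length(frontier_t) == 0 || length(frontier_s) <= length(frontier_t))
    if (expand_s) {
      nxt <- unique(unlist(adj[frontier_s], use.names = FALSE))
      nxt <- nxt[dist_s[nxt] == -1L]
      if (length(nxt) > 0) {           # depth counts reached levels only
        depth_s <- depth_s + 1L
        dist_s[nxt] <- depth_s
      }
      frontier_s <- nxt
    } else {
      nxt <- unique(unlist(adj[frontier_t], use.names = FALSE))
      nxt <- nxt[dist_t[nxt] == -1L]
      if (length(nxt) > 0) {
        depth_t <- depth_t + 1L
        dist_t[nxt] <- depth_t
      }
      frontier_t <- nxt
    }
    inter <- nxt[dist_s[nxt] >= 0L & dist_t[nxt] >= 0L]
    if (length(inter) > 0) {
      return(min(dist_s[inter] + dist_t[inter]))
    }
  }
}

#' Tie range of an edge
#'
#' The tie range is the length of the second-shortest path between the
#' endpoints of an edge, i.e. their distance in the flattened graph with the
#' direct edge removed; it is one less than the length of the shortest cycle
#' through the edge. Any edge inside a triangle (positive embeddedness) has
#' tie range 2; a pendant edge has tie range `Inf`. Computed by an
#' alternating breadth-first search from the two endpoints that stops at the
#' first intersection of the two search trees.
#'
#' @param g an `mln_graph`
#' @param u,v endpoints of an edge of `g`
#' @param max_range distances beyond this cap are censored (default 10)
#' @return integer `>= 2`, `Inf` (endpoints disconnected without the edge),
#'   or `NA` meaning "censored: `> max_range`"
#' @export
tie_range <- function(g, u, v, max_range = 10) {
  fl <- flatten(g)
  e <- fl$edges
  is_edge <- (e$u == u & e$v == v) | (e$u == v & e$v == u)
  if (!any(is_edge)) stop("(", u, ", ", v, ") is not an edge", call. = FALSE)
  adj <- flat_adjacency(g)
  si <- match(u, g$nodes); ti <- match(v, g$nodes)
  if (length(adj[[si]]) <= 1 || length(adj[[ti]]) <= 1) return(Inf)
  alt_bfs_tie_range(adj, si, ti, max_range)
}

#' Embeddedness and tie range for a set of edges
#'
#' Per-edge census used for the local-bridge / long-tie analysis. Tie ranges
#' are only searched for local bridges (embeddedness zero); embedded edges
#' have tie range 2 by construction.
#'
#' @param g an `mln_graph`
#' @param max_range censoring cap for the tie-range search
#' @param only_bridges return only rows with embeddedness zero
#' @return data.frame `u`, `v`, `m`, `embeddedness`, `tie_range`
#'   (`Inf` = no second path, `NA` = censored beyond `max_range`),
#'   `censored` (logical)
#' @export
edge_tie_ranges <- function(g, max_range = 10, only_bridges = FALSE) {
  emb <- edge_embeddedness(g)
  adj <- flat_adjacency(g)
  tr <- rep(2, nrow(emb))
  zero <- which(emb$embeddedness == 0)
  ui <- match(emb$u, g$nodes); vi <- match(emb$v, g$nodes)
  for (i in zero) {
    if (length(adj[[ui[i]]]) <= 1 || length(adj[[vi[i]]]) <= 1) {
      tr[i] <- Inf
    } else {
      tr[i] <- alt_bfs_tie_range(adj, ui[i], vi[i], max_range)
    }
  }
  emb$tie_range <- tr
  emb$censored <- is.na(tr)
  if (only_bridges) emb <- emb[emb$embeddedness == 0, , drop = FALSE]
  rownames(emb) <- NULL
  emb
}

#' Layer-triplet census of an ego's triangles
#'
#' Every triangle around an ego `u` is realised by layer triplets
#' `(l1, l2, l3)`: `l1` and `l3` are the layers of the edges to the two
#' alters (ordered by ascending alter label), `l2` the layer of the closing
#' alter-alter edge. Each combination of layers is counted as its own
#' realisation. A realisation is *cohesive* when `l1 == l3` (the two ego
#' edges come from the same social context, whatever closes them) and
#' *bridging* when all three layers differ (`l1 != l2`, `l2 != l3` and
#' `l1 != l3`): the closing edge then connects two different contexts of the
#' ego and itself belongs to neither. Realisations with `l1 != l3` whose
#' closing edge lies in one of the wing layers count as neither class (they
#' are overlap between two contexts). A node triplet realised by several
#' layer combinations can contribute to both classes.
#'
#' @param g an `mln_graph`
#' @param u ego node id
#' @return list with `census` (data.frame `l1`, `l2`, `l3`, `count`),
#'   `total`, `cohesion` and `bridging` realisation counts
#' @export
triangle_type_census <- function(g, u) {
  stopifnot(inherits(g, "mln_graph"))
  if (!u %in% g$nodes) stop("unknown node: ", u, call. = FALSE)
  e <- g$edges
  inc <- e$u == u | e$v == u
  alter <- ifelse(e$u[inc] == u, e$v[inc], e$u[inc])
  alter_layers <- split(e$layer[inc], alter)
  alters <- names(alter_layers)
  alters <- alters[order(match(alters, g$nodes))]
  rows <- list()
  if (length(alters) >= 2) {
    n <- length(g$nodes)
    idx <- edge_indices(g)
    ekey <- pair_key(idx$ui, idx$vi, n)
    ai <- match(alters, g$nodes)
    for (i in seq_len(length(alters) - 1)) {
      for (j in (i + 1):length(alters)) {
        ki <- min(ai[i], ai[j]); kj <- max(ai[i], ai[j])
        closing <- e$layer[ekey == pair_key(ki, kj, n)]
        if (length(closing) == 0) next
        l1s <- alter_layers[[alters[i]]]
        l3s <- alter_layers[[alters[j]]]
        combos <- expand.grid(l1 = l1s, l2 = closing, l3 = l3s,
                              stringsAsFactors = FALSE)
        rows[[length(rows) + 1]] <- combos
      }
    }
  }
  census <- if (length(rows) == 0) {
    data.frame(l1 = character(), l2 = character(), l3 = character(),
               count = integer())
  } else {
    all <- do.call(rbind, rows)
    agg <- stats::aggregate(list(count = rep(1L, nrow(all))),
                            by = all[, c("l1", "l2", "l3")], FUN = sum)
    agg[order(agg$l1, agg$l2, agg$l3), , drop = FALSE]
  }
  rownames(census) <- NULL
  total <- sum(census$count)
  cohesion <- sum(census$count[census$l1 == census$l3])
  bridging <- sum(census$count[census$l1 != census$l2 &
                                 census$l2 != census$l3 &
                                 census$l1 != census$l3])
  list(census = census, total = total, cohesion = cohesion,
       bridging = bridging)
}

#' Closure as a function of degree
#'
#' Mean and 25th/75th percentile bands of a closure metric within each total
#' degree value, with disclosure suppression of thin degree cells. Egos with
#' undefined metric values are excluded.
#'
#' @param g an `mln_graph`
#' @param metric `"c_local"` or `"c_excess"`
#' @param min_cell minimum number of egos for a degree value to be emitted
#' @param summary optional precomputed [ego_closure_all()] result
#' @return data.frame `degree`, `n`, `mean`, `q25`, `q75`
#' @export
closure_by_degree <- function(g, metric = c("c_local", "c_excess"),
                              min_cell = 10, summary = NULL) {
  metric <- match.arg(metric)
  cs <- if (is.null(summary)) ego_closure_all(g) else summary
  x <- cs[[metric]]
  ok <- !is.na(x)
  cs <- cs[ok, , drop = FALSE]; x <- x[ok]
  if (nrow(cs) == 0) {
    return(data.frame(degree = integer(), n = integer(), mean = numeric(),
                      q25 = numeric(), q75 = numeric()))
  }
  f <- factor(cs$k_total)
  out <- data.frame(
    degree = as.integer(levels(f)),
    n = as.integer(table(f)),
    mean = as.numeric(tapply(x, f, mean)),
    q25 = as.numeric(tapply(x, f, stats::quantile, probs = 0.25)),
    q75 = as.numeric(tapply(x, f, stats::quantile, probs = 0.75)))
  out <- out[out$n >= min_cell, , drop = FALSE]
  rownames(out) <- NULL
  out
}
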