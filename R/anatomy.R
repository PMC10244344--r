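#' Default cumulative layer-combination sequence
#'
#' The combinations range from the sparse parent-child backbone to the full
#' six-layer network, adding layers in increasing order of how likely their
#' formal ties are to represent realised social ties: parent-child only;
#' close family, extended family and household; plus next-door neighbours;
#' plus primary schools; plus secondary schools; plus the rest of the school
#' layer and small workplaces; plus all workplaces.
#'
#' @return named list of layer/sublayer selections (see [subgraph_layers()])
#' @export
default_layer_sequence <- function() {
  list(
    "Cp" = "Cp",
    "C+E+H" = c("C", "E", "H"),
    "C+E+H+N" = c("C", "E", "H", "N"),
    "C+E+H+N+Sp" = c("C", "E", "H", "N", "Sp"),
    "C+E+H+N+Sp+Ss" = c("C", "E", "H", "N", "Sp", "Ss"),
    "C+E+H+N+S+Ws" = c("C", "E", "H", "N", "S", "Ws"),
    "C+E+H+N+S+W" = c("C", "E", "H", "N", "S", "W"))
}

#' Path study over a sequence of layer combinations
#'
#' Computes one [path_report()] per layer combination, with identical
#' pair-sample seeds across rows so the sampled mean distances are
#' comparable. Along a cumulative sequence the giant component can only grow
#' and mean distances can only shrink (edge addition never lengthens a
#' shortest path).
#'
#' @param g an `mln_graph`
#' @param sequence list of layer selections (default
#'   [default_layer_sequence()])
#' @param pairs_per_node pair budget per node for sampled mean distances
#' @param seed integer seed shared by all rows
#' @param small_work workplace-size threshold for the `Ws` filter
#' @param diameter compute exact diameters (can be slow on sparse backbones)
#' @return data.frame with one row per combination: `combination`,
#'   `n_non_isolated`, `n_pair_edges`, `n_layer_edges`, `n_components`,
#'   `gc`, `diameter`, `mean_distance`, `se`
#' @export
layer_combination_study <- function(g, sequence = default_layer_sequence(),
                                    pairs_per_node = 1000, seed = 1L,
                                    small_work = 50, diameter = TRUE) {
  stopifnot(inherits(g, "mln_graph"), length(sequence) > 0)
  if (is.null(names(sequence))) {
    names(sequence) <- vapply(sequence, paste, character(1), collapse = "+")
  }
  rows <- lapply(names(sequence), function(nm) {
    sub <- subgraph_layers(g, sequence[[nm]], small_work = small_work)
    rep <- path_report(sub, pairs_per_node = pairs_per_node, seed = seed,
                       diameter = diameter)
    data.frame(combination = nm,
               n_non_isolated = rep$n_non_isolated,
               n_pair_edges = rep$n_pair_edges,
               n_layer_edges = rep$n_layer_edges,
               n_components = rep$n_components,
               gc = rep$gc, diameter = rep$diameter,
               mean_distance = rep$mean_distance, se = rep$se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Embeddedness / tie-range census and long-tie composition
#'
#' Tabulates the embeddedness distribution over all flattened edges, the
#' tie-range distribution of local bridges (embeddedness-zero edges), the
#' share of *long ties* — edges with tie range at least `min_range`
#' (censored ranges count as long, infinite ranges do not) — and the layer
#' composition of those long ties, in particular the share carried by the
#' kinship/household layers (C, E, H).
#'
#' @param g an `mln_graph`
#' @param min_range minimum tie range of a long tie (default 6)
#' @param max_range censoring cap of the tie-range search (default 10)
#' @return list with `edges` (per-edge census of local bridges),
#'   `embeddedness_distribution`, `tie_range_distribution` (bridges only),
#'   `n_edges`, `n_bridges`, `n_long`, `long_share`,
#'   `long_layer_composition` (fraction of long ties containing each layer)
#'   and `long_family_share` (fraction containing a C, E or H edge)
#' @export
long_tie_census <- function(g, min_range = 6, max_range = 10) {
  census <- edge_tie_ranges(g, max_range = max_range)
  n_edges <- nrow(census)
  emb_dist <- table(census$embeddedness)
  bridges <- census[census$embeddedness == 0, , drop = FALSE]
  finite <- bridges[is.finite(bridges$tie_range) & !is.na(bridges$tie_range), ,
                    drop = FALSE]
  tr_dist <- table(finite$tie_range)
  long <- bridges[(!is.na(bridges$tie_range) &
                     is.finite(bridges$tie_range) &
                     bridges$tie_range >= min_range) |
                    bridges$censored, , drop = FALSE]
  comp <- stats::setNames(numeric(length(g$layers)), g$layers)
  fam_share <- NA_real_
  if (nrow(long) > 0) {
    n <- length(g$nodes)
    li <- edge_indices(g, long)
    long_keys <- pair_key(li$ui, li$vi, n)
    idx <- edge_indices(g)
    ekey <- pair_key(idx$ui, idx$vi, n)
    present <- g$edges$layer[ekey %in% long_keys]
    by_edge <- split(g$edges$layer[ekey %in% long_keys],
                     ekey[ekey %in% long_keys])
    for (l in g$layers) {
      comp[l] <- mean(vapply(by_edge, function(ls) l %in% ls, logical(1)))
    }
    fam_share <- mean(vapply(by_edge,
                             function(ls) any(ls %in% c("C", "E", "H")),
                             logical(1)))
  }
  list(edges = bridges, embeddedness_distribution = emb_dist,
       tie_range_distribution = tr_dist, n_edges = n_edges,
       n_bridges = nrow(bridges), n_long = nrow(long),
       long_share = if (n_edges > 0) nrow(long) / n_edges else NA_real_,
       long_layer_composition = comp, long_family_share = fam_share)
}

#' Life-course curves of network position by demographic group
#'
#' Mean of a node-level network metric per (age bin x demographic group)
#' cell, with disclosure suppression of thin cells. Egos whose metric is
#' undefined (e.g. excess closure with no alter tie pairs) are excluded
#' rather than counted as zero. Optionally the group contrast is controlled
#' for degree by direct standardisation over total-degree deciles.
#'
#' @param g an `mln_graph`
#' @param nodes node table with `node_id`, `age` and the grouping column
#' @param metric `"degree"` (total degree), `"c_excess"` or `"closeness"`
#' @param group_by `"income_decile"`, `"education_level"` or
#'   `"urbanization_level"` (any column of `nodes`)
#' @param age_bin_width age bin width in years (default 1)
#' @param min_cell minimum cell size for a cell to be emitted
#' @param control_degree standardise within total-degree deciles
#' @param closeness_mode,sample_frac,seed closeness options (see
#'   [closeness_centrality()]); nodes outside the giant component get `NA`
#' @param closure optional precomputed [ego_closure_all()] result
#' @param values optional precomputed node-level metric values aligned with
#'   `nodes` (bypasses the internal metric computation)
#' @return data.frame `age_bin`, `group`, `n`, `mean`
#' @export
lifecourse_curves <- function(g, nodes, metric = c("degree", "c_excess",
                                                   "closeness"),
                              group_by = "income_decile", age_bin_width = 1,
                              min_cell = 10, control_degree = FALSE,
                              closeness_mode = "approx", sample_frac = 0.005,
                              seed = 1L, closure = NULL, values = NULL) {
  metric <- match.arg(metric)
  if (!group_by %in% names(nodes)) {
    stop("grouping column not in node table: ", group_by, call. = FALSE)
  }
  cs <- if (is.null(closure)) ego_closure_all(g) else closure
  ord <- match(nodes$node_id, cs$node)
  deg <- cs$k_total[ord]
  x <- if (!is.null(values)) values else switch(metric,
    degree = as.numeric(deg),
    c_excess = cs$c_excess[ord],
    closeness = {
      comp <- graph_components(g)
      ig <- igraph::induced_subgraph(as_igraph(flatten(g)), comp$giant)
      cc <- closeness_centrality(ig, mode = closeness_mode,
                                 sample_frac = sample_frac, seed = seed)
      as.numeric(cc[nodes$node_id])
    })
  bin <- (nodes$age %/% age_bin_width) * age_bin_width
  grp <- nodes[[group_by]]
  ok <- !is.na(x) & !is.na(grp) & !is.na(bin)
  df <- data.frame(bin = bin[ok], grp = grp[ok], x = x[ok], deg = deg[ok])
  if (nrow(df) == 0) {
    return(data.frame(age_bin = numeric(), group = character(),
                      n = integer(), mean = numeric()))
  }
  if (!control_degree) {
    agg <- stats::aggregate(x ~ bin + grp, data = df,
                            FUN = function(v) c(n = length(v), m = mean(v)))
    out <- data.frame(age_bin = agg$bin, group = agg$grp,
                      n = as.integer(agg$x[, "n"]), mean = agg$x[, "m"])
  } else {
    # direct standardisation over population degree deciles
    qs <- unique(stats::quantile(df$deg, probs = seq(0, 1, 0.1)))
    df$dd <- cut(df$deg, breaks = qs, include.lowest = TRUE, labels = FALSE)
    wts <- table(df$dd) / nrow(df)
    cell <- stats::aggregate(x ~ bin + grp + dd, data = df, FUN = mean)
    rows <- list()
    for (key in unique(paste(cell$bin, cell$grp))) {
      sel <- cell[paste(cell$bin, cell$grp) == key, , drop = FALSE]
      w <- as.numeric(wts[as.character(sel$dd)])
      rows[[key]] <- data.frame(
        age_bin = sel$bin[1], group = sel$grp[1],
        n = sum(df$bin == sel$bin[1] & df$grp == sel$grp[1]),
        mean = sum(sel$x * w) / sum(w))
    }
    out <- do.call(rbind, rows)
  }
  out <- out[out$n >= min_cell, , drop = FALSE]
  out <- out[order(out$group, out$age_bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full anatomy pipeline
#'
#' Orchestrates the complete analysis of a multilayer population network:
#' synthetic generation (when no graph is supplied), degree metrics (per
#' layer histograms with missing-family weights, zero-degree census, active
#' layers, degree correlations, layer overlap), the layer-combination path
#' study, the embeddedness / tie-range census, closure-versus-degree curves,
#' and life-course curves. All tables are written as CSV into `out_dir`
#' together with a small JSON log holding the seed and configuration hash;
#' identical seeds give byte-identical outputs.
#'
#' @param config list with entries: either `graph` + `nodes` or `population`
#'   (a [population_config()]); optional `out_dir` (no files written when
#'   `NULL`), `seed` (default 1), `pairs_per_node` (default 5),
#'   `sequence` (default [default_layer_sequence()]), `min_cell` (default
#'   10), `metrics` / `groupings` for the life-course curves,
#'   `closeness_frac` (default 0.005), `max_range` (default 10),
#'   `diameter` (default TRUE)
#' @return invisible list with all result tables
#' @export
run_anatomy <- function(config) {
  seed <- config$seed %||% 1L
  min_cell <- config$min_cell %||% 10
  pairs_per_node <- config$pairs_per_node %||% 5
  sequence <- config$sequence %||% default_layer_sequence()
  metrics <- config$metrics %||% c("degree", "c_excess", "closeness")
  groupings <- config$groupings %||% c("income_decile", "education_level",
                                       "urbanization_level")
  if (!is.null(config$graph)) {
    g <- config$graph; nodes <- config$nodes
  } else if (!is.null(config$population)) {
    pop <- synth_population(config$population)
    g <- pop$graph; nodes <- pop$nodes
  } else {
    stop("config must supply `graph`+`nodes` or `population`", call. = FALSE)
  }
  res <- list(seed = seed)

  w <- missing_family_weights(nodes)
  deg <- node_degrees(g)
  hist_rows <- lapply(g$layers, function(l) {
    h <- degree_distribution(deg[[paste0("k_", l)]], weights = w[deg$node],
                             min_cell = min_cell)
    if (nrow(h) == 0) return(NULL)
    data.frame(layer = l, h)
  })
  h_tot <- degree_distribution(deg$k_total, weights = w[deg$node],
                               min_cell = min_cell)
  if (nrow(h_tot) > 0) hist_rows <- c(hist_rows,
                                      list(data.frame(layer = "total", h_tot)))
  res$degree_histograms <- do.call(rbind, hist_rows)
  res$zero_degree <- data.frame(layer = g$layers,
                                n_zero = as.integer(zero_degree_census(g)))
  lad <- layers_active_distribution(g)
  res$layers_active <- data.frame(n_layers = as.integer(names(lad)),
                                  n_nodes = as.integer(lad))
  corr <- weighted_degree_correlation(g, weights = w, node_table = nodes)
  res$degree_correlation <- corr$r
  res$layer_overlap <- layer_overlap_matrix(g)

  res$path_study <- layer_combination_study(
    g, sequence = sequence, pairs_per_node = pairs_per_node, seed = seed,
    diameter = config$diameter %||% TRUE)

  res$long_ties <- long_tie_census(g, max_range = config$max_range %||% 10)

  cs <- ego_closure_all(g)
  res$closure_by_degree <- rbind(
    data.frame(metric = "c_local",
               closure_by_degree(g, "c_local", min_cell = min_cell,
                                 summary = cs)),
    data.frame(metric = "c_excess",
               closure_by_degree(g, "c_excess", min_cell = min_cell,
                                 summary = cs)))

  # node-level metric values computed once, shared across groupings
  ord <- match(nodes$node_id, cs$node)
  metric_values <- list()
  for (m in metrics) {
    metric_values[[m]] <- switch(m,
      degree = as.numeric(cs$k_total[ord]),
      c_excess = cs$c_excess[ord],
      closeness = {
        comp <- graph_components(g)
        ig <- igraph::induced_subgraph(as_igraph(flatten(g)), comp$giant)
        cc <- closeness_centrality(ig, mode = "approx",
                                   sample_frac = config$closeness_frac %||%
                                     0.005, seed = seed)
        as.numeric(cc[nodes$node_id])
      })
  }
  res$lifecourse <- list()
  for (m in metrics) {
    for (grp in groupings) {
      res$lifecourse[[paste(m, grp, sep = ".")]] <-
        lifecourse_curves(g, nodes, metric = m, group_by = grp,
                          age_bin_width = config$age_bin_width %||% 5,
                          min_cell = min_cell, closure = cs,
                          values = metric_values[[m]])
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) utils::write.csv(d, file.path(config$out_dir, f),
                                          row.names = FALSE)
    wr(res$degree_histograms, "degree_histograms.csv")
    wr(res$zero_degree, "zero_degree.csv")
    wr(res$layers_active, "layers_active.csv")
    wr(as.data.frame(res$degree_correlation), "degree_correlation.csv")
    wr(as.data.frame(res$layer_overlap), "layer_overlap.csv")
    wr(res$path_study, "path_study.csv")
    wr(res$closure_by_degree, "closure_by_degree.csv")
    lt <- res$long_ties
    wr(data.frame(embeddedness = names(lt$embeddedness_distribution),
                  n = as.integer(lt$embeddedness_distribution)),
       "embeddedness_distribution.csv")
    wr(data.frame(tie_range = names(lt$tie_range_distribution),
                  n = as.integer(lt$tie_range_distribution)),
       "tie_range_distribution.csv")
    wr(data.frame(n_edges = lt$n_edges, n_bridges = lt$n_bridges,
                  n_long = lt$n_long, long_share = lt$long_share,
                  long_family_share = lt$long_family_share),
       "long_ties.csv")
    for (nm in names(res$lifecourse)) {
      wr(res$lifecourse[[nm]], paste0("lifecourse_", nm, ".csv"))
    }
    log <- c(sprintf("seed: %d", seed),
             sprintf("generated: %s", !is.null(config$population)),
             sprintf("pairs_per_node: %g", pairs_per_node))
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
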