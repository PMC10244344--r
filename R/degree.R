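#' Per-layer node degrees
#'
#' @param g an `mln_graph`
#' @param layer a layer code of `g`
#' @return named integer vector: number of layer neighbours per node (zero
#'   for nodes absent from the layer), in node order
#' @export
layer_degree <- function(g, layer) {
  stopifnot(inherits(g, "mln_graph"))
  if (!layer %in% g$layers) stop("unknown layer: ", layer, call. = FALSE)
  n <- length(g$nodes)
  e <- g$edges[g$edges$layer == layer, , drop = FALSE]
  idx <- edge_indices(g, e)
  k <- tabulate(c(idx$ui, idx$vi), nbins = n)
  stats::setNames(as.integer(k), g$nodes)
}

#' Degree system of a multilayer graph
#'
#' Computes, per node, the layer degrees `k_{u,l}`, the total degree
#' `k_u = sum_l k_{u,l}` (which counts a pair connected in several layers
#' once per layer) and the unique-neighbour degree `k'_u` (number of distinct
#' alters over all layers). Always `k'_u <= k_u`, with equality iff no alter
#' of `u` is connected in more than one layer.
#'
#' @param g an `mln_graph`
#' @return data.frame with columns `node`, one `k_<layer>` per layer,
#'   `k_total`, `k_unique`
#' @export
node_degrees <- function(g) {
  stopifnot(inherits(g, "mln_graph"))
  n <- length(g$nodes)
  out <- data.frame(node = g$nodes, stringsAsFactors = FALSE)
  total <- integer(n)
  for (l in g$layers) {
    k <- layer_degree(g, l)
    out[[paste0("k_", l)]] <- as.integer(k)
    total <- total + k
  }
  fl <- flatten(g)
  idx <- edge_indices(g, fl$edges)
  out$k_total <- as.integer(total)
  out$k_unique <- tabulate(c(idx$ui, idx$vi), nbins = n)
  out
}

#' Zero-degree census per layer
#'
#' Number of nodes with no neighbour in each layer (e.g. people with no
#' registered close family, or one-person households).
#'
#' @param g an `mln_graph`
#' @return named integer vector over layers
#' @export
zero_degree_census <- function(g) {
  vapply(g$layers, function(l) sum(layer_degree(g, l) == 0L), integer(1))
}

#' Distribution of the number of active layers per node
#'
#' Histogram over nodes of the number of layers in which the node has nonzero
#' degree (0 = isolated node, up to the number of layers).
#'
#' @param g an `mln_graph`
#' @return named integer vector with bins `0 .. n_layers`
#' @export
layers_active_distribution <- function(g) {
  n <- length(g$nodes)
  active <- integer(n)
  for (l in g$layers) active <- active + (layer_degree(g, l) > 0L)
  counts <- tabulate(active + 1L, nbins = length(g$layers) + 1L)
  stats::setNames(counts, 0:length(g$layers))
}

#' Weighted degree histogram with disclosure suppression
#'
#' Builds a (optionally weighted) histogram over integer values and omits
#' bins whose unweighted support falls below `min_cell`, the usual
#' disclosure-control rule for register-derived outputs.
#'
#' @param values integer vector (e.g. degrees)
#' @param weights optional non-negative weights, same length as `values`
#' @param min_cell minimum unweighted bin count for a bin to be emitted
#'   (default 10); `0` disables suppression
#' @return data.frame with columns `value`, `count` (unweighted),
#'   `weighted_count`; suppressed bins are dropped and listed in the
#'   attribute `"suppressed"` (their values)
#' @export
degree_distribution <- function(values, weights = NULL, min_cell = 10) {
  stopifnot(min_cell >= 0)
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values)) {
    stop("weights must match values in length", call. = FALSE)
  }
  if (anyNA(weights) || any(weights < 0)) {
    stop("weights must be non-missing and non-negative", call. = FALSE)
  }
  if (length(values) == 0) {
    out <- data.frame(value = integer(), count = integer(),
                      weighted_count = numeric())
    attr(out, "suppressed") <- integer()
    return(out)
  }
  f <- factor(values)
  count <- as.integer(table(f))
  wcount <- as.numeric(tapply(weights, f, sum))
  out <- data.frame(value = as.integer(levels(f)), count = count,
                    weighted_count = wcount)
  keep <- out$count >= min_cell
  suppressed <- out$value[!keep]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "suppressed") <- suppressed
  out
}

#' Inverse cumulative degree distribution and tail slope
#'
#' Computes the empirical CCDF `P(K >= k)` over the distinct positive values
#' and a descriptive tail-slope estimate on double-logarithmic axes. The tail
#' is the set of observations above the empirical `1 - tail_fraction`
#' quantile. The default estimator is OLS of `log CCDF` on `log k` over the
#' distinct tail values (slope reported positive); a Hill-type estimator is
#' available as an alternative. The slope is descriptive only — no
#' distributional model is fitted or selected.
#'
#' @param values positive integer (or numeric) observations
#' @param tail_fraction fraction of the largest observations forming the tail
#'   (default 0.1)
#' @param method `"ols"` (default) or `"hill"`
#' @return list with `ccdf` (data.frame `k`, `p`) and `slope` (positive
#'   number, or `NaN` with a warning when the tail is degenerate: fewer than
#'   10 distinct positive tail values)
#' @export
ccdf_tail_slope <- function(values, tail_fraction = 0.1, method = c("ols", "hill")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  pos <- values[values > 0]
  ks <- sort(unique(pos))
  p <- vapply(ks, function(k) mean(pos >= k), numeric(1))
  ccdf <- data.frame(k = ks, p = p)
  thr <- stats::quantile(pos, probs = 1 - tail_fraction, names = FALSE,
                         type = 1)
  tail_ks <- ks[ks >= thr]
  if (length(tail_ks) < 10) {
    warning("degenerate tail: fewer than 10 distinct positive values")
    return(list(ccdf = ccdf, slope = NaN))
  }
  slope <- if (method == "ols") {
    sel <- ccdf$k %in% tail_ks & ccdf$p > 0
    fit <- stats::lm(log(p) ~ log(k), data = ccdf[sel, , drop = FALSE])
    -unname(stats::coef(fit)[2])
  } else {
    x <- pos[pos >= thr]
    excess <- log(x / thr)
    excess <- excess[excess > 0]
    1 / mean(excess)
  }
  list(ccdf = ccdf, slope = slope)
}

#' Missing-family inverse-probability weights
#'
#' Family layers derived from a parent-child register with a cutoff date miss
#' links for people whose parents were never registered. The weighting scheme
#' sets `w = 1` for the strata whose family information is complete by
#' construction — first-generation migrants (their parents live abroad, so
#' nothing is missing *within* the register's scope) and anyone born after
#' the register cutoff — and reweights the remaining people within 10-year
#' age groups by `w_g = p_pop / p_g`, the ratio of the population fraction of
#' complete-parent-information people to the same fraction within the age
#' group. Under-observed age groups are thereby up-weighted.
#'
#' @param nodes node table with columns `age`, `family_info_complete`,
#'   `migration_generation` (see [read_node_table()])
#' @param age_bin_width width of the age groups in years (default 10)
#' @param cutoff_age age below which people are born after the register
#'   cutoff (default 23: a 2018 reference date with a 1995 cutoff)
#' @return named non-negative numeric vector of weights, names = `node_id`
#' @export
missing_family_weights <- function(nodes, age_bin_width = 10, cutoff_age = 23) {
  required <- c("node_id", "age", "family_info_complete",
                "migration_generation")
  miss <- setdiff(required, names(nodes))
  if (length(miss) > 0) {
    stop("node table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !stats::complete.cases(nodes[, required])
  if (any(bad)) {
    stop("missing attributes for node(s): ",
         paste(utils::head(nodes$node_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  w <- rep(NA_real_, nrow(nodes))
  unit <- nodes$migration_generation == "first" | nodes$age < cutoff_age
  w[unit] <- 1
  rest <- !unit
  if (any(rest)) {
    p_pop <- mean(nodes$family_info_complete)
    grp <- nodes$age %/% age_bin_width
    p_g <- stats::ave(as.numeric(nodes$family_info_complete), grp)
    wg <- ifelse(p_g > 0, p_pop / p_g, NA_real_)
    if (anyNA(wg[rest])) {
      # a group without any complete-information person has an undefined
      # group completeness; fall back to the pooled completeness of all
      # reweighted strata rather than emitting infinite weights
      p_rest <- mean(nodes$family_info_complete[rest])
      if (p_rest > 0) {
        warning("age group(s) with no complete-information people: ",
                "falling back to pooled completeness")
        wg[is.na(wg)] <- p_pop / p_rest
      } else {
        warning("no complete-information people outside the unit-weight ",
                "strata: NA weights")
      }
    }
    w[rest] <- wg[rest]
  }
  stats::setNames(w, nodes$node_id)
}

# Weighted Pearson correlation of two numeric vectors.
weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2)
  cyy <- sum(w * (y - my)^2)
  if (cxx <= 0 || cyy <= 0) return(NaN)
  cxy / sqrt(cxx * cyy)
}

#' Weighted correlation matrix between layer degrees
#'
#' Pearson correlations between the per-layer degrees of nodes, optionally
#' weighted (e.g. by missing-family weights) and restricted to nodes with
#' complete family information. Confidence intervals use the Fisher
#' z-transform with the effective sample size `(sum w)^2 / sum(w^2)`.
#'
#' @param g an `mln_graph`
#' @param weights optional named weight vector (names = node ids); unit
#'   weights when `NULL`, in which case the result is the ordinary Pearson
#'   correlation matrix
#' @param node_table optional node table; when it has a
#'   `family_info_complete` column the correlation is computed over complete
#'   nodes only
#' @param alpha two-sided confidence level parameter (default 0.01, i.e. 99%
#'   intervals)
#' @return list with matrices `r`, `lower`, `upper` (layers x layers,
#'   diagonal 1) and the effective sample size `n_eff`; zero-variance layers
#'   give `NaN` entries with a warning
#' @export
weighted_degree_correlation <- function(g, weights = NULL, node_table = NULL,
                                        alpha = 0.01) {
  deg <- node_degrees(g)
  keep <- rep(TRUE, nrow(deg))
  if (!is.null(node_table) && "family_info_complete" %in% names(node_table)) {
    complete <- node_table$node_id[node_table$family_info_complete %in% TRUE]
    keep <- deg$node %in% complete
  }
  deg <- deg[keep, , drop = FALSE]
  if (is.null(weights)) {
    w <- rep(1, nrow(deg))
  } else {
    w <- unname(weights[deg$node])
    if (anyNA(w)) stop("weights missing for some included nodes", call. = FALSE)
  }
  layers <- g$layers
  kcols <- paste0("k_", layers)
  nl <- length(layers)
  r <- matrix(NA_real_, nl, nl, dimnames = list(layers, layers))
  n_eff <- sum(w)^2 / sum(w^2)
  for (i in seq_len(nl)) {
    r[i, i] <- 1
    for (j in seq_len(nl)) {
      if (j <= i) next
      r[i, j] <- r[j, i] <- weighted_pearson(deg[[kcols[i]]], deg[[kcols[j]]], w)
    }
  }
  if (any(is.nan(r))) warning("zero-variance layer: NaN correlation entries")
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(max(n_eff - 3, 1))
  q <- stats::qnorm(1 - alpha / 2)
  lower <- tanh(z - q * se); diag(lower) <- 1
  upper <- tanh(z + q * se); diag(upper) <- 1
  list(r = r, lower = lower, upper = upper, n_eff = n_eff)
}

#' Edge-overlap percentages between layers
#'
#' Entry `(a, b)` is `100 * |E_a intersect E_b| / |E_a|`: the percentage of
#' layer `a`'s edges that also appear in layer `b` (each off-diagonal entry
#' is normalised by its row layer, so the two entries of a pair share the
#' same numerator but different denominators). Diagonal entries are 100.
#'
#' @param g an `mln_graph`
#' @return layers x layers numeric matrix of percentages; empty layers give
#'   `NaN` rows/columns with a warning. The raw intersection counts are
#'   attached as attribute `"intersections"`.
#' @export
layer_overlap_matrix <- function(g) {
  n <- length(g$nodes)
  layers <- g$layers
  nl <- length(layers)
  keys <- lapply(layers, function(l) {
    e <- g$edges[g$edges$layer == l, , drop = FALSE]
    idx <- edge_indices(g, e)
    pair_key(idx$ui, idx$vi, n)
  })
  sizes <- lengths(keys)
  inter <- matrix(0, nl, nl, dimnames = list(layers, layers))
  M <- matrix(NA_real_, nl, nl, dimnames = list(layers, layers))
  for (i in seq_len(nl)) {
    inter[i, i] <- sizes[i]
    M[i, i] <- 100
    for (j in seq_len(nl)) {
      if (j <= i) next
      ov <- length(intersect(keys[[i]], keys[[j]]))
      inter[i, j] <- inter[j, i] <- ov
      M[i, j] <- if (sizes[i] > 0) 100 * ov / sizes[i] else NaN
      M[j, i] <- if (sizes[j] > 0) 100 * ov / sizes[j] else NaN
    }
  }
  if (any(sizes == 0)) {
    warning("empty layer(s): NaN overlap entries")
    M[sizes == 0, ] <- NaN
    for (i in which(sizes == 0)) M[, i] <- NaN
    diag(M)[sizes == 0] <- NaN
  }
  attr(M, "intersections") <- inter
  M
}
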