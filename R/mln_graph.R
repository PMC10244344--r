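# Canonical layer codes of a register-derived population network:
# close family, extended family, household, next-door neighbours, school, work.
LAYER_CODES <- c("C", "E", "H", "N", "S", "W")

# Built-in sublayer filters: code -> parent layer + tag predicate.
# Cp: parent-child edges of C; Sp/Ss: primary/secondary school groups;
# Ws: small workplaces (size <= threshold, default 50).
SUBLAYER_PARENT <- c(Cp = "C", Sp = "S", Ss = "S", Ws = "W")

#' Construct a node-aligned multilayer graph
#'
#' A multilayer graph holds a single shared node set and one simple undirected
#' edge set per layer (no self-loops, each unordered pair stored at most once
#' per layer). Edge rows may carry extra tag columns (e.g. `rel` for
#' close-family relationship type, `workplace_size` for work edges,
#' `school_level` for school edges); tags travel with the edges and enable
#' sublayer filters such as parent-child-only or small-workplace views.
#'
#' @param edges data.frame with character columns `u`, `v`, `layer`, plus
#'   optional tag columns. May have zero rows.
#' @param nodes character vector of node identifiers. Defaults to the nodes
#'   appearing in `edges`; may be a superset (isolated nodes are legitimate
#'   and show up as zero-degree in every layer).
#' @param layers ordered character vector of layer codes. Defaults to the
#'   canonical register codes `C, E, H, N, S, W` restricted/extended by the
#'   codes present in `edges`.
#' @return An object of class `mln_graph`: a list with elements `nodes`,
#'   `layers` and `edges` (canonicalised: `u` precedes `v` in node order,
#'   duplicates within a layer collapsed).
#' @examples
#' g <- mln_graph(data.frame(u = c("a", "a"), v = c("b", "c"),
#'                           layer = c("C", "H")))
#' layer_sizes(g)
#' @export
mln_graph <- function(edges, nodes = NULL, layers = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("u", "v", "layer")
  if (!all(required %in% names(edges))) {
    stop("`edges` must have columns u, v, layer", call. = FALSE)
  }
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  edges$layer <- as.character(edges$layer)
  if (anyNA(edges$u) || anyNA(edges$v) || anyNA(edges$layer)) {
    stop("edge endpoints and layer codes must be non-missing", call. = FALSE)
  }
  if (any(edges$u == edges$v)) {
    stop("self-loops are not allowed in a multilayer social network",
         call. = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- unique(c(edges$u, edges$v))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node identifiers", call. = FALSE)
    missing_nodes <- setdiff(unique(c(edges$u, edges$v)), nodes)
    if (length(missing_nodes) > 0) {
      stop("edges reference nodes absent from `nodes`: ",
           paste(utils::head(missing_nodes, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(layers)) {
    layers <- c(LAYER_CODES, setdiff(unique(edges$layer), LAYER_CODES))
  } else {
    layers <- as.character(layers)
    bad <- setdiff(unique(edges$layer), layers)
    if (length(bad) > 0) {
      stop("unknown layer code(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  g <- structure(list(nodes = nodes, layers = layers, edges = edges),
                 class = "mln_graph")
  canonicalise_edges(g)
}

# Orders each pair (u, v) by node index and drops duplicate rows within a
# layer (first row's tags win). Returns the graph; the number of collapsed
# duplicates is attached as attribute "n_duplicates".
canonicalise_edges <- function(g) {
  e <- g$edges
  if (nrow(e) > 0) {
    ui <- match(e$u, g$nodes)
    vi <- match(e$v, g$nodes)
    flip <- ui > vi
    if (any(flip)) {
      tmp <- e$u[flip]; e$u[flip] <- e$v[flip]; e$v[flip] <- tmp
      tmp <- ui[flip]; ui[flip] <- vi[flip]; vi[flip] <- tmp
    }
    key <- paste(e$layer, ui, vi)
    dup <- duplicated(key)
    n_dup <- sum(dup)
    if (n_dup > 0) e <- e[!dup, , drop = FALSE]
    ord <- order(match(e$layer, g$layers),
                 match(e$u, g$nodes), match(e$v, g$nodes))
    e <- e[ord, , drop = FALSE]
    rownames(e) <- NULL
    g$edges <- e
    attr(g, "n_duplicates") <- n_dup
  } else {
    attr(g, "n_duplicates") <- 0L
  }
  g
}

#' @export
print.mln_graph <- function(x, ...) {
  cat(sprintf("Node-aligned multilayer graph: %d nodes, %d edges, %d layers\n",
              length(x$nodes), nrow(x$edges), length(x$layers)))
  ls <- layer_sizes(x)
  for (l in names(ls)) cat(sprintf("  %-3s %d edges\n", l, ls[[l]]))
  invisible(x)
}

#' Number of nodes / edges of a multilayer graph
#' @param g an `mln_graph`
#' @return integer count
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' Per-layer edge counts
#' @param g an `mln_graph`
#' @return named integer vector `m_l`, one entry per layer (zero for empty
#'   layers), in layer order
#' @export
layer_sizes <- function(g) {
  counts <- table(factor(g$edges$layer, levels = g$layers))
  stats::setNames(as.integer(counts), g$layers)
}

# Integer edge index representation: list(ui, vi) 1-based into g$nodes.
edge_indices <- function(g, edges = g$edges) {
  list(ui = match(edges$u, g$nodes), vi = match(edges$v, g$nodes))
}

# Unique numeric key per unordered pair; requires canonical ui < vi.
pair_key <- function(ui, vi, n) (ui - 1) * n + vi

#' Flatten a multilayer graph to a simple graph with edge multiplicities
#'
#' The flattened view keeps one edge per pair of nodes connected in at least
#' one layer, together with the multiplicity `m_uv` (number of layers
#' containing the pair). It is the substrate for path-based measures and for
#' the unique-neighbour degree.
#'
#' @param g an `mln_graph`
#' @return An object of class `mln_flat`: list with `nodes` (shared node set)
#'   and `edges` (data.frame `u`, `v`, `m`).
#' @examples
#' g <- mln_graph(data.frame(u = c("a", "a"), v = c("b", "b"),
#'                           layer = c("C", "H")))
#' flatten(g)$edges  # one pair, multiplicity 2
#' @export
flatten <- function(g) {
  stopifnot(inherits(g, "mln_graph"))
  n <- length(g$nodes)
  if (nrow(g$edges) == 0) {
    flat <- data.frame(u = character(), v = character(), m = integer())
  } else {
    idx <- edge_indices(g)
    key <- pair_key(idx$ui, idx$vi, n)
    first <- !duplicated(key)
    m <- as.integer(table(factor(key, levels = key[first])))
    flat <- data.frame(u = g$edges$u[first], v = g$edges$v[first], m = m,
                       stringsAsFactors = FALSE)
  }
  structure(list(nodes = g$nodes, edges = flat), class = "mln_flat")
}

#' @export
print.mln_flat <- function(x, ...) {
  cat(sprintf("Flattened multilayer graph: %d nodes, %d unique pairs (%d layer edges)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$m)))
  invisible(x)
}

#' Convert a multilayer graph (or its flattened view) to an igraph object
#'
#' All nodes become vertices (isolated nodes included), so degree and
#' component computations see the full aligned node set.
#'
#' @param g an `mln_graph` or `mln_flat`
#' @param layers optional subset of layers (only for `mln_graph` input)
#' @return an undirected simple `igraph` graph; for flattened input the edge
#'   attribute `m` holds layer multiplicities
#' @export
as_igraph <- function(g, layers = NULL) {
  if (inherits(g, "mln_graph")) {
    e <- g$edges
    if (!is.null(layers)) e <- e[e$layer %in% layers, , drop = FALSE]
    el <- unique(cbind(e$u, e$v))
    igraph::graph_from_data_frame(
      as.data.frame(el, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
  } else if (inherits(g, "mln_flat")) {
    ig <- igraph::graph_from_data_frame(
      g$edges[, c("u", "v")], directed = FALSE,
      vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
    igraph::E(ig)$m <- g$edges$m
    ig
  } else {
    stop("not an mln_graph or mln_flat", call. = FALSE)
  }
}

#' Select layers and sublayers of a multilayer graph
#'
#' Returns a multilayer graph with the same (node-aligned) node set and only
#' the selected edges. Besides whole-layer codes, the selection understands
#' sublayer codes backed by edge tags:
#' \describe{
#'   \item{`Cp`}{parent-child edges of the close-family layer (tag
#'     `rel == "parent_child"`)}
#'   \item{`Sp`, `Ss`}{primary / secondary school groups (tag `school_level`)}
#'   \item{`Ws`}{work edges whose workplace-size tag is at most
#'     `small_work` (default 50)}
#' }
#'
#' @param g an `mln_graph`
#' @param selection non-empty character vector of layer / sublayer codes
#' @param small_work workplace-size threshold used by the `Ws` filter
#' @return an `mln_graph` on the unchanged node set
#' @examples
#' \dontrun{subgraph_layers(g, c("C", "E", "H"))}
#' @export
subgraph_layers <- function(g, selection, small_work = 50) {
  stopifnot(inherits(g, "mln_graph"))
  if (length(selection) == 0) stop("empty layer selection", call. = FALSE)
  known <- c(g$layers, names(SUBLAYER_PARENT))
  bad <- setdiff(selection, known)
  if (length(bad) > 0) {
    stop("unknown layer/sublayer code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  keep <- rep(FALSE, nrow(g$edges))
  e <- g$edges
  for (code in selection) {
    if (code %in% g$layers) {
      keep <- keep | (e$layer == code)
    } else {
      parent <- SUBLAYER_PARENT[[code]]
      in_parent <- e$layer == parent
      pred <- switch(code,
        Cp = {
          if (is.null(e$rel)) stop("sublayer Cp requires edge tag `rel`",
                                   call. = FALSE)
          in_parent & !is.na(e$rel) & e$rel == "parent_child"
        },
        Sp = ,
        Ss = {
          if (is.null(e$school_level)) {
            stop("sublayer ", code, " requires edge tag `school_level`",
                 call. = FALSE)
          }
          lev <- if (code == "Sp") "primary" else "secondary"
          in_parent & !is.na(e$school_level) & e$school_level == lev
        },
        Ws = {
          if (is.null(e$workplace_size)) {
            stop("sublayer Ws requires edge tag `workplace_size`",
                 call. = FALSE)
          }
          in_parent & !is.na(e$workplace_size) & e$workplace_size <= small_work
        })
      keep <- keep | pred
    }
  }
  out <- g
  out$edges <- e[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  attr(out, "n_duplicates") <- NULL
  out
}
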