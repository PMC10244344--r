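# Fixture builders and independent brute-force oracles shared by the tests.
# Oracles enumerate directly over the edge table and never touch the
# package's vectorised implementations.

edges_df <- function(...) {
  rows <- list(...)
  data.frame(u = vapply(rows, `[[`, character(1), 1),
             v = vapply(rows, `[[`, character(1), 2),
             layer = vapply(rows, `[[`, character(1), 3),
             stringsAsFactors = FALSE)
}

# random multilayer graph: each of `n_layers` layers is an independent
# G(n, p) draw; node ids "1".."n"
random_mln <- function(n, n_layers = 3, p = 0.12, seed = 1) {
  set.seed(seed)
  ids <- as.character(seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  rows <- list()
  for (l in seq_len(n_layers)) {
    sel <- stats::runif(nrow(pairs)) < p
    if (any(sel)) {
      rows[[l]] <- data.frame(u = pairs[sel, 1], v = pairs[sel, 2],
                              layer = LETTERS[l], stringsAsFactors = FALSE)
    }
  }
  e <- do.call(rbind, rows)
  if (is.null(e)) e <- data.frame(u = character(), v = character(),
                                  layer = character())
  mln_graph(e, nodes = ids, layers = LETTERS[seq_len(n_layers)])
}

# multiplicity of a pair over layers, straight from the edge table
mult_of <- function(g, a, b) {
  e <- g$edges
  sum((e$u == a & e$v == b) | (e$u == b & e$v == a))
}

# neighbours of u in the flattened graph, from the edge table
alters_of <- function(g, u) {
  e <- g$edges
  sort(unique(c(e$v[e$u == u], e$u[e$v == u])))
}

brute_embeddedness <- function(g, u, v) {
  ws <- setdiff(intersect(alters_of(g, u), alters_of(g, v)), c(u, v))
  if (length(ws) == 0) return(0)
  sum(vapply(ws, function(w) mult_of(g, u, w) * mult_of(g, w, v), numeric(1)))
}

# exhaustive per-ego closure quantities
brute_ego <- function(g, u) {
  al <- alters_of(g, u)
  m <- vapply(al, function(v) mult_of(g, u, v), numeric(1))
  k <- sum(m)
  p_u <- choose(k, 2) - sum(choose(m, 2))
  t_pure <- 0L; t_unique <- 0L
  if (length(al) >= 2) {
    prs <- utils::combn(al, 2)
    for (i in seq_len(ncol(prs))) {
      a <- prs[1, i]; b <- prs[2, i]
      if (mult_of(g, a, b) == 0) next
      t_unique <- t_unique + 1L
      e <- g$edges
      lay_of <- function(x, y) {
        e$layer[(e$u == x & e$v == y) | (e$u == y & e$v == x)]
      }
      pure <- length(intersect(intersect(lay_of(u, a), lay_of(u, b)),
                               lay_of(a, b))) > 0
      if (pure) t_pure <- t_pure + 1L
    }
  }
  c_pure <- if (p_u > 0) t_pure / p_u else NA_real_
  c_actual <- if (p_u > 0) t_unique / p_u else NA_real_
  c_excess <- if (p_u > 0 && !is.na(c_pure) && c_pure < 1) {
    (c_actual - c_pure) / (1 - c_pure)
  } else NA_real_
  list(k = k, p_u = p_u, t_pure = t_pure, t_unique = t_unique,
       c_pure = c_pure, c_actual = c_actual, c_excess = c_excess)
}

# second-shortest-path length via igraph on the edge-deleted flattened graph
brute_tie_range <- function(g, u, v) {
  ig <- as_igraph(flatten(g))
  eid <- igraph::get_edge_ids(ig, c(u, v))
  ig2 <- igraph::delete_edges(ig, eid)
  as.numeric(igraph::distances(ig2, v = u, to = v))
}

# register primitives built by hand (no generator) for layer-builder tests
manual_primitives <- function(people, parent_child = NULL, partners = NULL,
                              households = NULL, school_groups = NULL,
                              employment = NULL, workplaces = NULL,
                              config = population_config(n_people = 0,
                                                         seed = 1)) {
  empty <- popmln:::empty_primitives(config)
  prim <- empty
  prim$people <- people
  if (!is.null(parent_child)) prim$parent_child <- parent_child
  if (!is.null(partners)) prim$partners <- partners
  if (!is.null(households)) prim$households <- households
  if (!is.null(school_groups)) prim$school_groups <- school_groups
  if (!is.null(employment)) prim$employment <- employment
  if (!is.null(workplaces)) prim$workplaces <- workplaces
  prim
}

people_df <- function(ids, household = ids, age = 30) {
  data.frame(id = ids, age = age, generation = "G1",
             migration_generation = "native", household = household,
             family_info_complete = TRUE, income_decile = 5L,
             education_level = 2L, urbanization_level = 3L,
             stringsAsFactors = FALSE)
}

households_df <- function(ids, x, y, institutional = FALSE) {
  data.frame(household_id = ids, institutional = institutional,
             x = x, y = y, stringsAsFactors = FALSE)
}
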