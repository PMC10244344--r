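test_that("layer, total and unique degrees follow the multilayer rules", {
  # triangle in C plus a C+H double edge and an H household clique of 4
  g <- mln_graph(edges_df(
    c("1", "2", "C"), c("2", "3", "C"), c("1", "3", "C"),
    c("1", "2", "H"),
    c("5", "6", "H"), c("5", "7", "H"), c("5", "8", "H"),
    c("6", "7", "H"), c("6", "8", "H"), c("7", "8", "H")))
  kC <- layer_degree(g, "C")
  expect_equal(unname(kC[c("1", "2", "3")]), c(2L, 2L, 2L))
  expect_equal(unname(kC["5"]), 0L)                 # absent from layer
  kH <- layer_degree(g, "H")
  expect_equal(unname(kH[c("5", "6", "7", "8")]), rep(3L, 4))
  expect_error(layer_degree(g, "Q"), "unknown")

  deg <- node_degrees(g)
  # pair {1,2} in C and H: contributes 2 to k_total, 1 to k_unique
  expect_equal(deg$k_total[deg$node == "1"], 3L)
  expect_equal(deg$k_unique[deg$node == "1"], 2L)
})

test_that("pair in two layers and multi-layer alters count as specified", {
  g <- mln_graph(edges_df(c("u", "v", "C"), c("u", "v", "H")))
  deg <- node_degrees(g)
  expect_equal(deg$k_total[deg$node == "u"], 2L)
  expect_equal(deg$k_unique[deg$node == "u"], 1L)

  # u with 3 distinct alters, one connected in 2 layers
  g2 <- mln_graph(edges_df(c("u", "a", "C"), c("u", "a", "H"),
                           c("u", "b", "C"), c("u", "c", "W")))
  d2 <- node_degrees(g2)
  expect_equal(d2$k_total[d2$node == "u"], 4L)
  expect_equal(d2$k_unique[d2$node == "u"], 3L)

  # single-layer graph: total equals unique everywhere
  g1 <- random_mln(20, n_layers = 1, p = 0.2, seed = 3)
  d1 <- node_degrees(g1)
  expect_equal(d1$k_total, d1$k_unique)
})

test_that("handshake identities hold on random multilayer graphs", {
  for (seed in 1:5) {
    g <- random_mln(25, n_layers = 4, p = 0.1, seed = seed)
    deg <- node_degrees(g)
    for (l in g$layers) {
      expect_equal(sum(deg[[paste0("k_", l)]]),
                   2L * unname(layer_sizes(g)[l]))
    }
    expect_equal(sum(deg$k_total), 2L * n_edges(g))
  }
})

test_that("zero-degree census and active-layer histogram are exact", {
  # 10 nodes; layer C has edges among 6 of them
  e <- edges_df(c("1", "2", "C"), c("3", "4", "C"), c("5", "6", "C"),
                c("1", "2", "H"))
  g <- mln_graph(e, nodes = as.character(1:10))
  zc <- zero_degree_census(g)
  expect_equal(unname(zc["C"]), 4L)
  expect_equal(unname(zc["E"]), 10L)     # empty layer: everyone at zero
  lad <- layers_active_distribution(g)
  expect_equal(unname(lad["0"]), 4L)     # isolated nodes
  expect_equal(unname(lad["2"]), 2L)     # nodes 1,2 active in C and H
  expect_equal(unname(lad["1"]), 4L)
  expect_equal(sum(lad), 10L)
})

test_that("degree histograms apply the disclosure suppression rule", {
  vals <- c(rep(5L, 9), rep(2L, 12))
  h <- degree_distribution(vals, min_cell = 10)
  expect_false(5L %in% h$value)          # 9 < 10: suppressed
  expect_true(2L %in% h$value)
  expect_equal(attr(h, "suppressed"), 5L)
  expect_true(all(h$count >= 10))

  h0 <- degree_distribution(vals, min_cell = 0)
  expect_equal(sum(h0$count), length(vals))

  w <- rep(1, length(vals))
  h1 <- degree_distribution(vals, weights = w, min_cell = 0)
  expect_equal(h1$weighted_count, as.numeric(h1$count))
  expect_error(degree_distribution(vals, weights = -w), "negative")
})

test_that("CCDF tail slope recovers a Pareto exponent and flags degeneracy", {
  set.seed(99)
  alpha <- 2.5
  x <- 1 * stats::runif(1e5)^(-1 / alpha)      # Pareto(k_min = 1, alpha)
  res <- ccdf_tail_slope(x, tail_fraction = 0.1)
  expect_lt(abs(res$slope - alpha), 0.2)
  expect_equal(res$ccdf$p[1], 1)               # CCDF starts at 1
  expect_true(all(diff(res$ccdf$p) <= 0))      # non-increasing

  hill <- ccdf_tail_slope(x, tail_fraction = 0.1, method = "hill")
  expect_lt(abs(hill$slope - alpha), 0.2)

  expect_warning(cst <- ccdf_tail_slope(rep(4, 50)), "degenerate")
  expect_true(is.nan(cst$slope))
})

test_that("a geometric degree distribution is not mistaken for a power law", {
  set.seed(7)
  x <- stats::rgeom(1e5, prob = 0.05) + 1
  # local log-log slope grows with k for a geometric tail: the estimate over
  # a deep tail exceeds the estimate over a shallow one
  shallow <- ccdf_tail_slope(x, tail_fraction = 0.5)$slope
  deep <- ccdf_tail_slope(x, tail_fraction = 0.02)$slope
  expect_gt(deep, shallow)
})

test_that("missing-family weights implement the stratified IPW scheme", {
  nt <- data.frame(
    node_id = as.character(1:8),
    age = c(10L, 20L, 30L, 35L, 38L, 70L, 75L, 50L),
    family_info_complete = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE,
                             TRUE),
    migration_generation = c("native", "second", "native", "native",
                             "native", "native", "first", "native"),
    stringsAsFactors = FALSE)
  expect_warning(w <- missing_family_weights(nt), "pooled completeness")
  expect_equal(unname(w[c("1", "2")]), c(1, 1))   # born after the cutoff
  expect_equal(unname(w["7"]), 1)                  # first-generation migrant
  p_pop <- mean(nt$family_info_complete)           # 5/8
  # ages 30-39: nodes 3,4,5, completeness 2/3
  expect_equal(unname(w["3"]), p_pop / (2 / 3))
  expect_equal(unname(w["4"]), p_pop / (2 / 3))
  # age 70-79 has no complete-information people: pooled fallback over the
  # reweighted strata (nodes 3,4,5,6,8 -> completeness 3/5)
  expect_equal(unname(w["6"]), p_pop / (3 / 5))
  expect_error(missing_family_weights(nt[, 1:2]), "lacks column")
  nt$age[1] <- NA
  expect_error(missing_family_weights(nt), "missing attributes")
})

test_that("weighted degree correlation matches direct formulas", {
  g <- random_mln(200, n_layers = 3, p = 0.05, seed = 11)
  res <- weighted_degree_correlation(g)
  deg <- node_degrees(g)
  plain <- stats::cor(deg[, paste0("k_", g$layers)])
  dimnames(plain) <- dimnames(res$r)
  expect_equal(res$r, plain, tolerance = 1e-12)
  expect_true(all(diag(res$r) == 1))
  expect_true(all(res$lower <= res$r + 1e-12 & res$r <= res$upper + 1e-12))

  # hand-computed 5-node toy with weights {1,1,2,1,1}
  gt <- mln_graph(edges_df(c("1", "2", "A"), c("2", "3", "A"),
                           c("1", "2", "B"), c("3", "4", "B"),
                           c("4", "5", "B")),
                  nodes = as.character(1:5), layers = c("A", "B"))
  w <- stats::setNames(c(1, 1, 2, 1, 1), as.character(1:5))
  res_w <- weighted_degree_correlation(gt, weights = w)
  dt <- node_degrees(gt)
  x <- dt$k_A; y <- dt$k_B; ww <- unname(w[dt$node])
  mx <- sum(ww * x) / sum(ww); my <- sum(ww * y) / sum(ww)
  r_direct <- sum(ww * (x - mx) * (y - my)) /
    sqrt(sum(ww * (x - mx)^2) * sum(ww * (y - my)^2))
  expect_equal(res_w$r["A", "B"], r_direct, tolerance = 1e-12)

  # identical degrees across layers: off-diagonal r = 1
  gi <- mln_graph(edges_df(c("1", "2", "A"), c("1", "2", "B"),
                           c("3", "4", "A"), c("3", "4", "B"),
                           c("4", "5", "A"), c("4", "5", "B")),
                  layers = c("A", "B"))
  expect_equal(weighted_degree_correlation(gi)$r["A", "B"], 1)
})

test_that("independent layer degrees correlate near zero", {
  g <- random_mln(2000, n_layers = 2, p = 0.004, seed = 21)
  r <- weighted_degree_correlation(g)$r["A", "B"]
  expect_lt(abs(r), 0.05)
})

test_that("layer overlap percentages are row-normalised with shared numerators", {
  # A strictly inside B: |A| = 5, |B| = 10
  pairs <- cbind(as.character(1:10), as.character(2:11))
  e <- rbind(data.frame(u = pairs[1:5, 1], v = pairs[1:5, 2], layer = "A"),
             data.frame(u = pairs[, 1], v = pairs[, 2], layer = "B"))
  g <- mln_graph(e, layers = c("A", "B"))
  M <- layer_overlap_matrix(g)
  expect_equal(M["A", "B"], 100)
  expect_equal(M["B", "A"], 50)
  inter <- attr(M, "intersections")
  expect_equal(inter["A", "B"], inter["B", "A"])
  # reconstruction: entry * |row layer| / 100 gives the shared numerator
  expect_equal(M["A", "B"] * 5 / 100, M["B", "A"] * 10 / 100)

  # disjoint layers: 0; identical layers: 100 both ways
  gd <- mln_graph(edges_df(c("1", "2", "A"), c("3", "4", "B")),
                  layers = c("A", "B"))
  expect_equal(layer_overlap_matrix(gd)["A", "B"], 0)
  gi <- mln_graph(edges_df(c("1", "2", "A"), c("1", "2", "B")),
                  layers = c("A", "B"))
  Mi <- layer_overlap_matrix(gi)
  expect_equal(unname(Mi["A", "B"]), 100)
  expect_equal(unname(Mi["B", "A"]), 100)
  # empty layer: NaN with a warning
  ge <- mln_graph(edges_df(c("1", "2", "A")), layers = c("A", "B"))
  expect_warning(Me <- layer_overlap_matrix(ge), "empty")
  expect_true(is.nan(Me["B", "A"]))
})
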