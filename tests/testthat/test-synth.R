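test_that("generation is deterministic given the seed and handles n = 0", {
  cfg <- population_config(n_people = 800, seed = 7)
  p1 <- generate_primitives(cfg)
  p2 <- generate_primitives(cfg)
  expect_identical(p1, p2)
  g1 <- assemble(p1)$graph
  g2 <- assemble(p2)$graph
  expect_identical(g1$edges, g2$edges)
  p3 <- generate_primitives(population_config(n_people = 800, seed = 8))
  expect_false(identical(p1$people$age, p3$people$age))

  p0 <- generate_primitives(population_config(n_people = 0, seed = 1))
  expect_equal(nrow(p0$people), 0L)
  expect_equal(n_edges(assemble(p0)$graph), 0L)
  expect_error(population_config(n_people = 100), "seed")
})

test_that("register invariants hold on a generated population", {
  prim <- generate_primitives(population_config(n_people = 3000, seed = 11))
  expect_equal(nrow(prim$people), 3000L)
  expect_true(all(table(prim$parent_child$child) <= 2))
  expect_false(anyDuplicated(prim$employment$person) > 0)
  expect_true(all(prim$people$household %in% prim$households$household_id))
  # parents are at least 18 years older than their registered children
  ages <- stats::setNames(prim$people$age, prim$people$id)
  expect_true(all(ages[prim$parent_child$parent] -
                    ages[prim$parent_child$child] >= 18))
  # institutional households are larger than regular ones
  sizes <- table(prim$people$household)
  inst <- prim$households$household_id[prim$households$institutional]
  if (length(inst) > 0) {
    expect_gte(min(sizes[inst]), 10)
  }
})

test_that("close family composes parent-child, partner and sibling links", {
  # two children of one registered parent: sibling edge appears
  ppl <- people_df(c("p", "c1", "c2", "q"), age = c(60L, 30L, 28L, 58L))
  prim <- manual_primitives(
    ppl,
    parent_child = data.frame(child = c("c1", "c2"), parent = c("p", "p")),
    partners = data.frame(a = "p", b = "q"))
  e <- derive_close_family(prim)
  key <- paste(pmin(e$u, e$v), pmax(e$u, e$v))
  expect_true("c1 c2" %in% key)                       # siblings
  expect_true("p q" %in% key)                         # partners
  expect_true(all(c("c1 p", "c2 p") %in% key))        # parent-child
  expect_equal(sum(key == "p q"), 1L)                 # partner edge once
  expect_equal(e$rel[key == "c1 c2"], "sibling")
  # person with no registered kin has zero close-family degree
  g <- mln_graph(e, nodes = c(ppl$id, "zz"))
  expect_equal(unname(layer_degree(g, "C")["zz"]), 0L)
})

test_that("extended family enumerates the composed kin relations", {
  # grandparent gpa has children f and a (siblings); f partnered with m,
  # their child is x; a partnered with au, a's child is cz; sj is m's child
  # from former partner pj (no partner link m-pj), so sj and x share m and
  # are half-siblings in close family
  pc <- data.frame(
    child  = c("f", "a", "x", "x", "cz", "sj", "sj"),
    parent = c("gpa", "gpa", "f", "m", "a", "m", "pj"),
    stringsAsFactors = FALSE)
  pt <- data.frame(a = c("f", "a"), b = c("m", "au"),
                   stringsAsFactors = FALSE)
  ids <- unique(c(pc$child, pc$parent, pt$a, pt$b))
  prim <- manual_primitives(people_df(ids), parent_child = pc, partners = pt)
  e <- derive_extended_family(prim)
  key <- paste(pmin(e$u, e$v), pmax(e$u, e$v))
  has <- function(a, b) paste(min(a, b), max(a, b)) %in% key
  expect_true(has("x", "gpa"))    # grandparent
  expect_true(has("x", "a"))      # aunt
  expect_true(has("x", "cz"))     # first cousin
  expect_true(has("m", "gpa"))    # parent-in-law of f's partner
  expect_true(has("m", "a"))      # sibling-in-law: partner's sibling
  expect_true(has("f", "au"))     # sibling-in-law: sibling's partner
  expect_true(has("sj", "f"))     # stepparent: mother's current partner
  expect_false(has("x", "pj"))    # no partner link, no step relation
  expect_false(has("x", "sj"))    # half-siblings are close, not extended
  # close-family pairs never leak into the extended layer
  cf <- derive_close_family(prim)
  cfk <- paste(pmin(cf$u, cf$v), pmax(cf$u, cf$v))
  expect_length(intersect(key, cfk), 0)
})

test_that("step relations require the parent-partner link", {
  # parent m re-partnered with sp; sp's own child sc
  pc <- data.frame(child = c("x", "sc"), parent = c("m", "sp"),
                   stringsAsFactors = FALSE)
  pt <- data.frame(a = "m", b = "sp", stringsAsFactors = FALSE)
  prim <- manual_primitives(people_df(c("x", "m", "sp", "sc")),
                            parent_child = pc, partners = pt)
  e <- derive_extended_family(prim)
  key <- paste(pmin(e$u, e$v), pmax(e$u, e$v))
  expect_true("sp x" %in% key)   # stepparent
  expect_true("sc x" %in% key)   # step-sibling
  rels <- stats::setNames(e$rel, key)
  expect_equal(unname(rels["sp x"]), "stepparent")
  expect_equal(unname(rels["sc x"]), "step_sibling")
})

test_that("household layer is a clique per household", {
  ppl <- people_df(as.character(1:7),
                   household = c("h1", "h1", "h1", "h1", "h2", "h3", "h3"))
  prim <- manual_primitives(ppl, households = households_df(
    c("h1", "h2", "h3"), x = c(0, 100, 200), y = c(0, 0, 0)))
  e <- build_household_layer(prim)
  expect_equal(nrow(e), choose(4, 2) + choose(2, 2))  # 6 + 1
  g <- mln_graph(e, nodes = ppl$id)
  expect_equal(unname(layer_degree(g, "H")[c("1", "5", "6")]), c(3L, 0L, 1L))
  # an institutional household of 40 gives C(40,2) edges
  big <- people_df(paste0("i", 1:40), household = "inst")
  prim_big <- manual_primitives(big, households = households_df(
    "inst", x = 0, y = 0, institutional = TRUE))
  expect_equal(nrow(build_household_layer(prim_big)), choose(40, 2))
})

test_that("next-door rule: radius, cap and union semantics", {
  # focal household at origin; 15 single-person households on a 40 m ring;
  # one isolated farmhouse far away
  ang <- 2 * pi * (1:15) / 15
  hh <- households_df(c("f", paste0("r", 1:15), "far"),
                      x = c(0, 40 * cos(ang), 5000),
                      y = c(0, 40 * sin(ang), 5000))
  ppl <- people_df(c("pf", paste0("pr", 1:15), "pfar"),
                   household = c("f", paste0("r", 1:15), "far"))
  prim <- manual_primitives(ppl, households = hh)
  sel <- build_next_door_layer(prim, seed = 5, directed = TRUE)
  # focal person has 15 candidates -> exactly 10 selected households
  expect_equal(sum(sel$u == "pf"), 10L)
  # isolated farmhouse: no candidates within 50 m
  expect_equal(sum(sel$u == "pfar"), 0L)
  und <- build_next_door_layer(prim, seed = 5)
  g <- mln_graph(und, nodes = ppl$id)
  expect_equal(unname(layer_degree(g, "N")["pfar"]), 0L)
  # when fewer candidates than the cap, all are linked
  hh3 <- households_df(c("a", "b", "c"), x = c(0, 10, 20), y = 0)
  ppl3 <- people_df(c("pa", "pb", "pc"), household = c("a", "b", "c"))
  sel3 <- build_next_door_layer(manual_primitives(ppl3, households = hh3),
                                seed = 1, directed = TRUE)
  expect_equal(sum(sel3$u == "pa"), 2L)
  # determinism: same seed, same selection
  expect_identical(build_next_door_layer(prim, seed = 5),
                   build_next_door_layer(prim, seed = 5))
})

test_that("school layer: cliques within groups, tagged by level", {
  sg <- data.frame(
    person = c(paste0("k", 1:21), paste0("s", 1:5)),
    group = c(rep("P1|7|primary|-|c1", 21), rep("S1|14|secondary|-|c1", 5)),
    level = c(rep("primary", 21), rep("secondary", 5)),
    stringsAsFactors = FALSE)
  ppl <- people_df(sg$person, age = c(rep(7L, 21), rep(14L, 5)))
  prim <- manual_primitives(ppl, school_groups = sg)
  e <- build_school_layer(prim)
  g <- mln_graph(e, nodes = ppl$id)
  expect_equal(unname(layer_degree(g, "S")["k1"]), 20L)   # class of 21
  expect_equal(unname(layer_degree(g, "S")["s1"]), 4L)
  expect_equal(nrow(e), choose(21, 2) + choose(5, 2))
  expect_setequal(unique(e$school_level), c("primary", "secondary"))
  # sublayer filters ride on the tag
  expect_equal(n_edges(subgraph_layers(g, "Sp")), choose(21, 2))
  expect_equal(n_edges(subgraph_layers(g, "Ss")), choose(5, 2))
})

test_that("work layer: clique below threshold, k-nearest above", {
  # small workplace of 12: full clique
  ppl <- people_df(paste0("w", 1:12), household = paste0("hw", 1:12))
  hh <- households_df(paste0("hw", 1:12), x = stats::runif(12) * 100, y = 0)
  prim <- manual_primitives(ppl, households = hh,
                            employment = data.frame(person = ppl$id,
                                                    workplace = "A"))
  e <- build_work_layer(prim, clique_threshold = 100, k_nearest = 100)
  expect_equal(nrow(e), choose(12, 2))
  expect_true(all(e$workplace_size == 12L))

  # workplace of 30 with threshold 20 and k = 5: each member selects 5
  set.seed(2)
  ppl2 <- people_df(sprintf("e%02d", 1:30), household = sprintf("h%02d", 1:30))
  hh2 <- households_df(sprintf("h%02d", 1:30),
                       x = stats::runif(30) * 1000,
                       y = stats::runif(30) * 1000)
  prim2 <- manual_primitives(ppl2, households = hh2,
                             employment = data.frame(person = ppl2$id,
                                                     workplace = "B"))
  sel <- build_work_layer(prim2, clique_threshold = 20, k_nearest = 5,
                          directed = TRUE)
  expect_true(all(table(sel$u) == 5L))
  und <- build_work_layer(prim2, clique_threshold = 20, k_nearest = 5)
  g <- mln_graph(und, nodes = ppl2$id)
  kW <- layer_degree(g, "W")
  # own selection gives at least k, the union at most size - 1
  expect_true(all(kW >= 5L & kW <= 29L))
  # selections are deterministic (pure geometry + id tie-break)
  expect_identical(sel, build_work_layer(prim2, clique_threshold = 20,
                                         k_nearest = 5, directed = TRUE))
})

test_that("assembled population shows the mechanistic layer signatures", {
  pop <- synth_population(population_config(n_people = 2500, seed = 23))
  g <- pop$graph
  prim <- pop$primitives
  deg <- node_degrees(g)
  # H-degree = household size - 1
  hh_size <- table(prim$people$household)
  expected_h <- as.integer(hh_size[prim$people$household] - 1L)
  expect_equal(deg$k_H[match(prim$people$id, deg$node)], expected_h)
  # next-door degree from own selection is bounded by cap * max household
  # size, and every N edge connects people from nearby households
  expect_true(all(deg$k_N >= 0))
  # small workplaces are cliques: W-degree = size - 1 for their members
  emp <- merge(prim$employment, prim$workplaces, by = "workplace")
  small <- emp[emp$size < prim$config$work_clique_threshold &
                 emp$size >= 2, ]
  if (nrow(small) > 0) {
    expect_equal(deg$k_W[match(small$person, deg$node)],
                 as.integer(small$size - 1L))
  }
  # hardly any isolated nodes (the tight <1% bound is checked on the
  # full-size default population in the acceptance suite)
  fl_deg <- deg$k_unique
  expect_lt(mean(fl_deg == 0), 0.02)
  # bounded support: no degree beyond the structural maximum
  expect_true(max(deg$k_total) < 2500)
  # node table is aligned and typed
  expect_setequal(pop$nodes$node_id, g$nodes)
  expect_true(all(pop$nodes$income_decile %in% 1:10))
  expect_true(all(pop$nodes$education_level %in% 1:5))
})
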