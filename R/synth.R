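#' Configuration of the synthetic register-style population
#'
#' Parameters of the generative model standing in for the administrative
#' registers. The *mechanistic* rules are fixed by the layer construction
#' logic (household cliques, 50-metre next-door assignment capped at 10,
#' school-group cliques, small-workplace cliques with geographic 100-nearest
#' sampling above the threshold, register-cutoff completeness); the
#' *distributional* choices (age mix, household composition, town geometry,
#' workplace-size distribution) are configuration with documented defaults.
#'
#' @param n_people number of persons to generate
#' @param seed integer seed (mandatory; the generator is fully deterministic
#'   given the configuration)
#' @param frac_elderly,frac_adult fraction of the population in the oldest
#'   (60+) and middle (25-59) generations; the remainder are children/young
#'   adults descended from the middle generation
#' @param couple_frac_elderly,couple_frac_adult fraction of each adult
#'   generation living in a partnership
#' @param mean_adult_children mean sibship size linking the middle to the
#'   oldest generation
#' @param mean_children mean number of children per adult couple
#' @param frac_institutional target fraction of people living in
#'   institutional households (care homes etc.)
#' @param inst_size_range size range of institutional households
#' @param n_towns number of town centres; households are placed around them
#'   (`town_sd` metres Gaussian scatter) except for a `rural_frac` placed
#'   uniformly over the `extent_m` square
#' @param town_sd,rural_frac,extent_m spatial placement parameters (metres)
#' @param next_door_radius_m,next_door_cap next-door neighbour rule: radius
#'   (default 50 m) and maximum number of assigned households (default 10)
#' @param class_size school groups larger than this are split into parallel
#'   groups
#' @param n_programmes number of university study programmes
#' @param workplace_meanlog,workplace_sdlog,max_workplace log-normal
#'   workplace-size distribution and cap
#' @param work_clique_threshold workplaces below this size become full
#'   cliques (default 100)
#' @param work_k_nearest number of geographically closest colleagues linked
#'   in larger workplaces (default 100)
#' @param employment_rate employment probability for working-age adults
#' @param cutoff_age people younger than this are born after the register
#'   cutoff (default 23: 2018 reference with 1995 cutoff) and have complete
#'   family information by construction
#' @return a `population_config` list
#' @export
population_config <- function(n_people = 10000,
                              seed,
                              frac_elderly = 0.24,
                              frac_adult = 0.48,
                              couple_frac_elderly = 0.55,
                              couple_frac_adult = 0.62,
                              mean_adult_children = 2.6,
                              mean_children = 1.8,
                              frac_institutional = 0.012,
                              inst_size_range = c(15, 50),
                              n_towns = max(1L, round(n_people / 2500)),
                              town_sd = 250,
                              rural_frac = 0.15,
                              extent_m = 20000,
                              next_door_radius_m = 50,
                              next_door_cap = 10,
                              class_size = 25,
                              n_programmes = 3,
                              workplace_meanlog = 2.7,
                              workplace_sdlog = 1.2,
                              max_workplace = 400,
                              work_clique_threshold = 100,
                              work_k_nearest = 100,
                              employment_rate = 0.78,
                              cutoff_age = 23) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  if (cfg$n_people < 0) stop("n_people must be non-negative", call. = FALSE)
  stopifnot(cfg$next_door_radius_m > 0, cfg$next_door_cap > 0,
            cfg$work_clique_threshold > 0, cfg$work_k_nearest > 0,
            cfg$class_size > 1, cfg$max_workplace >= 1)
  probs <- c(cfg$frac_elderly, cfg$frac_adult, cfg$couple_frac_elderly,
             cfg$couple_frac_adult, cfg$rural_frac, cfg$frac_institutional,
             cfg$employment_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]",
                                       call. = FALSE)
  structure(cfg, class = "population_config")
}

empty_primitives <- function(config) {
  structure(list(
    people = data.frame(id = character(), age = integer(),
                        generation = character(),
                        migration_generation = character(),
                        household = character(),
                        family_info_complete = logical(),
                        income_decile = integer(),
                        education_level = integer(),
                        urbanization_level = integer()),
    parent_child = data.frame(child = character(), parent = character()),
    partners = data.frame(a = character(), b = character()),
    households = data.frame(household_id = character(),
                            institutional = logical(),
                            x = numeric(), y = numeric()),
    school_groups = data.frame(person = character(), group = character(),
                               level = character()),
    employment = data.frame(person = character(), workplace = character()),
    workplaces = data.frame(workplace = character(), size = integer(),
                            x = numeric(), y = numeric()),
    config = config), class = "register_primitives")
}

#' Generate register primitives for a synthetic population
#'
#' Draws a three-generation population (elderly units, their adult children
#' with partners, and the grandchild generation), registered parent-child
#' and partner links with a register-cutoff completeness model, household
#' assignments with coordinates (including institutional households),
#' school-group and employer affiliations, and demographic attributes.
#' Everything downstream (the six layers) is derived deterministically from
#' these primitives.
#'
#' @param config a [population_config()]
#' @return object of class `register_primitives`: list with `people`
#'   (incl. demographic columns), `parent_child` (directed registered
#'   links), `partners`, `households` (with coordinates and institutional
#'   flag), `school_groups`, `employment`, `workplaces`, `config`
#' @export
generate_primitives <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_people
  if (n == 0) return(empty_primitives(config))
  set.seed(config$seed)

  n0 <- round(n * config$frac_elderly)
  n1 <- round(n * config$frac_adult)
  if (n0 + n1 > n) { n1 <- max(0, n - n0) }

  ## --- persons: ages per generation -------------------------------------
  age0 <- if (n0 > 0) sample(60:94, n0, replace = TRUE,
                             prob = seq(1, 0.15, length.out = 35)) else integer()
  age1 <- if (n1 > 0) sample(25:59, n1, replace = TRUE) else integer()
  age <- c(age0, age1)
  generation <- c(rep("G0", n0), rep("G1", n1))

  ## --- elderly partnerships ---------------------------------------------
  partners_a <- integer(); partners_b <- integer()
  i0 <- seq_len(n0)
  n0c <- floor(config$couple_frac_elderly * n0 / 2)
  if (n0c > 0) {
    ord <- i0[order(age0)]
    cpl <- matrix(ord[seq_len(2 * n0c)], ncol = 2, byrow = TRUE)
    partners_a <- c(partners_a, cpl[, 1]); partners_b <- c(partners_b, cpl[, 2])
  }
  # elderly unit = couple or single; used for assigning adult children
  unit_of <- seq_len(n0)
  if (n0c > 0) unit_of[partners_b[seq_len(n0c)]] <- partners_a[seq_len(n0c)]
  units <- unique(unit_of)
  unit_age <- vapply(units, function(u) min(age0[unit_of == u]), numeric(1))

  ## --- adult sibships: G1 children of G0 units --------------------------
  pc_child <- integer(); pc_parent <- integer()
  if (n1 > 0 && length(units) > 0) {
    sizes <- pmin(stats::rpois(length(units), config$mean_adult_children), 5L)
    ord_units <- order(unit_age, decreasing = TRUE)
    unit_seq <- rep(units[ord_units], sizes[ord_units])
    g1_ids <- n0 + seq_len(n1)
    g1_sorted <- g1_ids[order(age1, decreasing = TRUE)]
    n_assign <- min(length(unit_seq), n1)
    if (n_assign > 0) {
      child <- g1_sorted[seq_len(n_assign)]
      punit <- unit_seq[seq_len(n_assign)]
      gap_ok <- age[punit] - age[child] >= 18
      child <- child[gap_ok]; punit <- punit[gap_ok]
      # both members of an elderly couple are registered parents
      pc_child <- c(pc_child, child)
      pc_parent <- c(pc_parent, punit)
      mate <- match(punit, partners_a)
      has_mate <- !is.na(mate)
      pc_child <- c(pc_child, child[has_mate])
      pc_parent <- c(pc_parent, partners_b[mate[has_mate]])
    }
  }

  ## --- adult partnerships ------------------------------------------------
  if (n1 > 1) {
    g1_ids <- n0 + seq_len(n1)
    willing <- g1_ids[stats::runif(n1) < config$couple_frac_adult]
    willing <- willing[order(age[willing])]
    if (length(willing) >= 2) {
      npair <- length(willing) %/% 2
      a <- willing[2 * seq_len(npair) - 1]
      b <- willing[2 * seq_len(npair)]
      # drop sibling pairings (shared registered parent)
      par_of <- split(pc_parent, pc_child)
      shared <- mapply(function(x, y) {
        px <- par_of[[as.character(x)]]; py <- par_of[[as.character(y)]]
        length(intersect(px, py)) > 0
      }, a, b)
      if (length(shared) > 0) { a <- a[!shared]; b <- b[!shared] }
      partners_a <- c(partners_a, a); partners_b <- c(partners_b, b)
    }
  }

  ## --- younger adults as children of older adult couples ------------------
  # the parents of a 25-39 year old are mostly 50-65: without this rung the
  # parent-child backbone would break into shallow two-generation stubs
  if (n1 > 0) {
    g1_ids <- n0 + seq_len(n1)
    unassigned <- setdiff(g1_ids, pc_child)
    young <- unassigned[age[unassigned] <= 37]
    elig <- which(partners_a > n0 & partners_b > n0)
    if (length(elig) > 0 && length(young) > 0) {
      ca <- partners_a[elig]; cb <- partners_b[elig]
      cage <- pmin(age[ca], age[cb])
      elig <- elig[cage >= 47]
      if (length(elig) > 0) {
        ca <- partners_a[elig]; cb <- partners_b[elig]
        cage <- pmin(age[ca], age[cb])
        sizes <- pmin(stats::rpois(length(elig), config$mean_adult_children),
                      4L)
        ord_c <- order(cage, decreasing = TRUE)
        cpl_seq <- rep(ord_c, sizes[ord_c])
        young <- young[order(age[young], decreasing = TRUE)]
        n_assign <- min(length(cpl_seq), length(young))
        if (n_assign > 0) {
          child <- young[seq_len(n_assign)]
          ci <- cpl_seq[seq_len(n_assign)]
          gap_ok <- pmin(age[ca[ci]], age[cb[ci]]) - age[child] >= 18
          child <- child[gap_ok]; ci <- ci[gap_ok]
          pc_child <- c(pc_child, child, child)
          pc_parent <- c(pc_parent, ca[ci], cb[ci])
        }
      }
    }
  }

  ## --- children (G2) ------------------------------------------------------
  n2 <- n - length(age)
  kid_age <- integer(); kid_p1 <- integer(); kid_p2 <- integer()
  if (n2 > 0 && n1 > 0) {
    g1a <- partners_a[partners_a > n0]
    g1b <- partners_b[partners_b > n0]
    nk <- pmin(stats::rpois(length(g1a), config$mean_children), 4L)
    p1 <- rep(g1a, nk); p2 <- rep(g1b, nk)
    g1_ids <- n0 + seq_len(n1)
    single <- setdiff(g1_ids, c(g1a, g1b))
    sk <- stats::rbinom(length(single), 2, 0.07)
    p1 <- c(p1, rep(single, sk)); p2 <- c(p2, rep(NA_integer_, sum(sk)))
    if (length(p1) > 0) {
      ka <- pmin(age[p1], ifelse(is.na(p2), Inf, age[p2])) -
        sample(23:36, length(p1), replace = TRUE)
      ok <- ka >= 0 & ka <= 24
      p1 <- p1[ok]; p2 <- p2[ok]; ka <- ka[ok]
      keep <- seq_len(min(length(p1), n2))
      p1 <- p1[keep]; p2 <- p2[keep]; ka <- as.integer(ka[keep])
      kid_ids <- length(age) + seq_along(p1)
      age <- c(age, ka)
      generation <- c(generation, rep("G2", length(p1)))
      pc_child <- c(pc_child, kid_ids, kid_ids[!is.na(p2)])
      pc_parent <- c(pc_parent, p1, p2[!is.na(p2)])
      kid_age <- ka; kid_p1 <- p1; kid_p2 <- p2
    }
  }
  # pad with unattached adults (mostly recent migrants) to hit n exactly
  n_pad <- n - length(age)
  if (n_pad > 0) {
    age <- c(age, sample(25:60, n_pad, replace = TRUE))
    generation <- c(generation, rep("pad", n_pad))
  }
  n_total <- length(age)
  stopifnot(n_total == n)

  ## --- migration generation ----------------------------------------------
  has_parents <- seq_len(n_total) %in% pc_child
  migr <- rep("native", n_total)
  no_par <- !has_parents
  is_g0 <- generation == "G0"; is_g1 <- generation == "G1"
  is_pad <- generation == "pad"
  migr[is_g0 & no_par & stats::runif(n_total) < 0.08] <- "first"
  migr[is_g1 & no_par & stats::runif(n_total) < 0.45] <- "first"
  migr[is_pad & stats::runif(n_total) < 0.7] <- "first"
  # children of a first-generation migrant are second generation
  if (length(pc_child) > 0) {
    first_par <- pc_parent[migr[pc_parent] == "first"]
    kids2 <- unique(pc_child[pc_parent %in% first_par])
    migr[kids2[migr[kids2] != "first"]] <- "second"
  }

  ## --- register completeness ----------------------------------------------
  n_par <- tabulate(pc_child, nbins = n_total)
  p_extra <- pmax(0.02, 0.9 - 0.012 * pmax(0, age - config$cutoff_age + 1))
  complete <- n_par >= 2 |
    (n_par >= 1 & stats::runif(n_total) < 0.5) |
    stats::runif(n_total) < p_extra
  complete[migr == "first" & n_par == 0] <- FALSE

  ## --- households ----------------------------------------------------------
  # each person starts in their own unit; couples merge; children <=18 (and
  # about half of 19-24 year olds) live with their parents
  hh_of <- seq_len(n_total)
  pa <- partners_a; pb <- partners_b
  hh_of[pb] <- hh_of[pa]
  if (length(kid_p1) > 0) {
    kid_ids <- which(generation == "G2")
    at_home <- kid_age <= 18 | stats::runif(length(kid_age)) < 0.55
    hh_of[kid_ids[at_home]] <- hh_of[kid_p1[at_home]]
  }
  # institutional households: mostly the very old living alone
  hh_sizes <- table(hh_of)
  alone <- names(hh_sizes)[hh_sizes == 1]
  alone <- as.integer(alone)
  cand <- alone[age[alone] >= 70]
  p_inst <- pmin(1, (age[cand] - 69) / 25)
  target_inst <- round(config$frac_institutional * n_total)
  chosen <- cand[stats::runif(length(cand)) < p_inst]
  if (length(chosen) > target_inst) chosen <- chosen[seq_len(target_inst)]
  inst_flag_members <- chosen
  inst_hh <- integer(0)
  if (length(chosen) > 0) {
    sz <- sample(config$inst_size_range[1]:config$inst_size_range[2], 1)
    n_grp <- max(1L, length(chosen) %/% sz)
    grp <- rep_len(seq_len(n_grp), length(chosen))  # even split, no stubs
    # reuse the first member's id as the institutional household label
    first_of_grp <- chosen[!duplicated(grp)]
    hh_of[chosen] <- first_of_grp[grp]
    inst_hh <- first_of_grp
  }
  hh_ids <- sort(unique(hh_of))
  hh_index <- match(hh_of, hh_ids)
  n_hh <- length(hh_ids)

  ## --- geography ------------------------------------------------------------
  towns <- cbind(x = stats::runif(config$n_towns, 0.15, 0.85) * config$extent_m,
                 y = stats::runif(config$n_towns, 0.15, 0.85) * config$extent_m)
  rural <- stats::runif(n_hh) < config$rural_frac
  town_of <- sample.int(config$n_towns, n_hh, replace = TRUE)
  hx <- ifelse(rural, stats::runif(n_hh) * config$extent_m,
               towns[town_of, "x"] + stats::rnorm(n_hh, sd = config$town_sd))
  hy <- ifelse(rural, stats::runif(n_hh) * config$extent_m,
               towns[town_of, "y"] + stats::rnorm(n_hh, sd = config$town_sd))
  dist_town <- sqrt(outer(hx, towns[, "x"], "-")^2 +
                      outer(hy, towns[, "y"], "-")^2)
  d_near <- apply(dist_town, 1, min)
  nearest_town <- apply(dist_town, 1, which.min)
  urb_hh <- cut(d_near, breaks = c(-Inf, 300, 800, 2000, 5000, Inf),
                labels = FALSE)
  urb_hh <- 6L - urb_hh  # 5 = town core ... 1 = rural

  ## --- schooling -------------------------------------------------------------
  person_town <- nearest_town[hh_index]
  lev <- rep(NA_character_, n_total)
  school <- rep(NA_character_, n_total)
  programme <- rep(NA_character_, n_total)
  young <- age >= 4 & age <= 11
  lev[young] <- "primary"; school[young] <- paste0("P", person_town[young])
  teen <- age >= 12 & age <= 17
  special <- teen & stats::runif(n_total) < 0.03
  lev[teen] <- "secondary"; school[teen] <- paste0("S", person_town[teen])
  lev[special] <- "secondary_special"; school[special] <- "X1"
  ya <- age >= 18 & age <= 24
  u <- stats::runif(n_total)
  higher <- ya & u < 0.45
  voc <- ya & u >= 0.45 & u < 0.70
  lev[higher] <- "higher"; school[higher] <- "U1"
  programme[higher] <- paste0("prog", sample.int(config$n_programmes,
                                                 n_total, replace = TRUE)[higher])
  lev[voc] <- "vocational"; school[voc] <- paste0("V", 1 + person_town[voc] %% 2)
  enrolled <- !is.na(lev)
  group <- ifelse(enrolled,
                  paste(school, age, lev,
                        ifelse(is.na(programme), "-", programme), sep = "|"),
                  NA_character_)
  # split oversized groups into parallel class groups ("location" tag)
  if (any(enrolled)) {
    idx <- which(enrolled)
    cls <- integer(length(idx))
    grp_f <- factor(group[idx])
    for (lvl in levels(grp_f)) {
      members <- which(grp_f == lvl)
      ncls <- ceiling(length(members) / config$class_size)
      cls[members] <- sample(rep_len(seq_len(ncls), length(members)))
    }
    group[idx] <- paste0(group[idx], "|c", cls)
  }

  ## --- employment -------------------------------------------------------------
  working_age <- age >= 19 & age <= 66
  emp_p <- ifelse(age >= 60, 0.45, config$employment_rate)
  emp_p[enrolled] <- 0.3  # student side jobs
  employed <- working_age & stats::runif(n_total) < emp_p
  n_emp <- sum(employed)
  wp_sizes <- integer(0)
  while (sum(wp_sizes) < n_emp) {
    draw <- pmax(1L, pmin(config$max_workplace,
                          round(stats::rlnorm(200, config$workplace_meanlog,
                                              config$workplace_sdlog))))
    wp_sizes <- c(wp_sizes, as.integer(draw))
  }
  wp_sizes <- wp_sizes[cumsum(wp_sizes) - wp_sizes < n_emp]
  if (sum(wp_sizes) > n_emp) wp_sizes[length(wp_sizes)] <-
    wp_sizes[length(wp_sizes)] - (sum(wp_sizes) - n_emp)
  wp_sizes <- wp_sizes[wp_sizes > 0]
  wp_id <- rep(seq_along(wp_sizes), wp_sizes)
  worker <- sample(which(employed))
  wp_of <- rep(NA_integer_, n_total)
  wp_of[worker] <- wp_id
  wp_town <- sample.int(config$n_towns, length(wp_sizes), replace = TRUE)
  wpx <- towns[wp_town, "x"] + stats::rnorm(length(wp_sizes), sd = 400)
  wpy <- towns[wp_town, "y"] + stats::rnorm(length(wp_sizes), sd = 400)

  ## --- income and education ----------------------------------------------------
  edu <- rep(NA_integer_, n_total)
  adult <- age >= 25
  edu[adult] <- sample.int(5, sum(adult), replace = TRUE,
                           prob = c(0.08, 0.3, 0.04, 0.33, 0.25))
  edu[age < 4] <- 1L
  edu[young] <- 1L
  edu[teen] <- 2L; edu[special] <- 3L
  edu[higher] <- 5L; edu[voc] <- 4L
  edu[is.na(edu)] <- 2L
  wage <- ifelse(employed, 1 + log1p(wp_sizes[wp_of]) / 3, 0.3) +
    0.25 * edu + 0.01 * pmin(age, 60) + stats::rnorm(n_total, sd = 0.3)
  wage[age < 19] <- 0
  hh_income <- tapply2(wage, hh_index, n_hh) + stats::rnorm(n_hh, sd = 0.1)
  dec_hh <- ceiling(10 * rank(hh_income, ties.method = "first") / n_hh)
  income <- as.integer(dec_hh[hh_index])

  ## --- assemble primitive tables ------------------------------------------------
  ids <- as.character(seq_len(n_total) - 1L)  # 0-based opaque labels
  people <- data.frame(
    id = ids, age = as.integer(age), generation = generation,
    migration_generation = migr,
    household = as.character(hh_ids[hh_index] - 1L),
    family_info_complete = complete,
    income_decile = income,
    education_level = as.integer(edu),
    urbanization_level = as.integer(urb_hh[hh_index]),
    stringsAsFactors = FALSE)
  prim <- structure(list(
    people = people,
    parent_child = data.frame(child = ids[pc_child], parent = ids[pc_parent],
                              stringsAsFactors = FALSE),
    partners = data.frame(a = ids[partners_a], b = ids[partners_b],
                          stringsAsFactors = FALSE),
    households = data.frame(household_id = as.character(hh_ids - 1L),
                            institutional = hh_ids %in% inst_hh,
                            x = hx, y = hy, stringsAsFactors = FALSE),
    school_groups = data.frame(person = ids[enrolled],
                               group = group[enrolled],
                               level = lev[enrolled],
                               stringsAsFactors = FALSE),
    employment = data.frame(person = ids[!is.na(wp_of)],
                            workplace = as.character(wp_of[!is.na(wp_of)]),
                            stringsAsFactors = FALSE),
    workplaces = data.frame(workplace = as.character(seq_along(wp_sizes)),
                            size = wp_sizes, x = wpx, y = wpy,
                            stringsAsFactors = FALSE),
    config = config), class = "register_primitives")
  validate_primitives(prim)
  prim
}

validate_primitives <- function(prim) {
  pc <- prim$parent_child
  if (nrow(pc) > 0) {
    npar <- table(pc$child)
    if (any(npar > 2)) stop("person with more than 2 registered parents")
  }
  if (anyDuplicated(prim$employment$person)) {
    stop("person with more than one employer")
  }
  if (anyDuplicated(prim$people$id)) stop("duplicate person ids")
  if (!all(prim$people$household %in% prim$households$household_id) &&
      nrow(prim$people) > 0) {
    stop("person assigned to unknown household")
  }
  invisible(prim)
}

#' @export
print.register_primitives <- function(x, ...) {
  cat(sprintf(paste0(
    "Register primitives: %d people, %d parent-child links, %d partner\n",
    "links, %d households (%d institutional), %d school enrolments, %d jobs\n"),
    nrow(x$people), nrow(x$parent_child), nrow(x$partners),
    nrow(x$households), sum(x$households$institutional),
    nrow(x$school_groups), nrow(x$employment)))
  invisible(x)
}

# expand a list of member-id vectors into unique unordered pairs
clique_edges <- function(groups) {
  us <- vector("list", length(groups)); vs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    m <- groups[[i]]
    if (length(m) >= 2) {
      cmb <- utils::combn(m, 2)
      us[[i]] <- cmb[1, ]; vs[[i]] <- cmb[2, ]
    }
  }
  data.frame(u = unlist(us), v = unlist(vs), stringsAsFactors = FALSE)
}

#' Derive the close-family layer
#'
#' Close family (layer `C`) is the undirected union of registered
#' parent-child links, partner links, and sibling links (two people sharing
#' at least one registered parent — observable even when the parent is no
#' longer in the population register, as long as the links were recorded).
#' Edge tag `rel` records the relationship (`parent_child` taking precedence
#' over `partner` over `sibling` when a pair qualifies several ways).
#'
#' @param prim a `register_primitives` object
#' @return data.frame `u`, `v`, `layer = "C"`, `rel`
#' @export
derive_close_family <- function(prim) {
  pc <- prim$parent_child
  sib <- sibling_pairs(pc)
  e <- rbind(
    if (nrow(pc) > 0) data.frame(u = pc$child, v = pc$parent,
                                 rel = "parent_child",
                                 stringsAsFactors = FALSE),
    if (nrow(prim$partners) > 0) data.frame(u = prim$partners$a,
                                            v = prim$partners$b,
                                            rel = "partner",
                                            stringsAsFactors = FALSE),
    if (nrow(sib) > 0) data.frame(u = sib$a, v = sib$b, rel = "sibling",
                                  stringsAsFactors = FALSE))
  if (is.null(e)) e <- data.frame(u = character(), v = character(),
                                  rel = character())
  data.frame(u = e$u, v = e$v, layer = rep("C", nrow(e)), rel = e$rel,
             stringsAsFactors = FALSE)
}

# all unordered pairs of children sharing a registered parent
sibling_pairs <- function(pc) {
  if (nrow(pc) == 0) return(data.frame(a = character(), b = character()))
  kids_by_parent <- split(pc$child, pc$parent)
  pairs <- clique_edges(kids_by_parent)
  if (nrow(pairs) == 0) return(data.frame(a = character(), b = character()))
  a <- pmin(pairs$u, pairs$v); b <- pmax(pairs$u, pairs$v)
  keep <- !duplicated(paste(a, b)) & a != b
  data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
}

#' Derive the extended-family layer
#'
#' Extended family (layer `E`) is deterministically composed from the
#' registered parent-child and partner links: grandparent/grandchild,
#' aunt-uncle/niece-nephew, first cousin, parent-in-law/child-in-law,
#' sibling-in-law, stepparent/stepchild and step-sibling. Pairs that already
#' qualify as close family (parent, partner, sibling) are excluded, the
#' union is deduplicated, and edges are undirected.
#'
#' @param prim a `register_primitives` object
#' @return data.frame `u`, `v`, `layer = "E"`, `rel` (first qualifying
#'   relation in the order above)
#' @export
derive_extended_family <- function(prim) {
  pc <- prim$parent_child
  pt <- prim$partners
  empty <- data.frame(u = character(), v = character(),
                      layer = character(), rel = character())
  if (nrow(pc) == 0 && nrow(pt) == 0) return(empty)
  sib <- sibling_pairs(pc)
  sib2 <- rbind(data.frame(a = sib$a, b = sib$b, stringsAsFactors = FALSE),
                data.frame(a = sib$b, b = sib$a, stringsAsFactors = FALSE))
  pt2 <- rbind(data.frame(a = pt$a, b = pt$b, stringsAsFactors = FALSE),
               data.frame(a = pt$b, b = pt$a, stringsAsFactors = FALSE))
  rel <- list()
  # grandparent: parent of parent
  gp <- merge(pc, pc, by.x = "parent", by.y = "child")
  if (nrow(gp) > 0) rel$grandparent <- data.frame(u = gp$child,
                                                  v = gp$parent.y)
  # aunt/uncle: sibling of parent
  au <- merge(pc, sib2, by.x = "parent", by.y = "a")
  if (nrow(au) > 0) rel$aunt_uncle <- data.frame(u = au$child, v = au$b)
  # first cousin: child of parent's sibling
  if (nrow(au) > 0) {
    cz <- merge(au[, c("child", "b")], pc, by.x = "b", by.y = "parent",
                suffixes = c("", ".c"))
    if (nrow(cz) > 0) rel$first_cousin <- data.frame(u = cz$child,
                                                     v = cz$child.c)
  }
  # parent-in-law: parent of partner
  il <- merge(pt2, pc, by.x = "b", by.y = "child")
  if (nrow(il) > 0) rel$parent_in_law <- data.frame(u = il$a, v = il$parent)
  # sibling-in-law: sibling of partner (and, symmetrically, partner of sibling)
  sl <- merge(pt2, sib2, by.x = "b", by.y = "a")
  if (nrow(sl) > 0) rel$sibling_in_law <- data.frame(u = sl$a, v = sl$b.y)
  # stepparent: partner of parent who is not a parent
  st <- merge(pc, pt2, by.x = "parent", by.y = "a")
  if (nrow(st) > 0) {
    own <- paste(pc$child, pc$parent)
    st <- st[!(paste(st$child, st$b) %in% own), , drop = FALSE]
    if (nrow(st) > 0) rel$stepparent <- data.frame(u = st$child, v = st$b)
  }
  # step-sibling: child of a stepparent who is not a (half) sibling
  if (!is.null(rel$stepparent) && nrow(rel$stepparent) > 0) {
    ss <- merge(rel$stepparent, pc, by.x = "v", by.y = "parent")
    if (nrow(ss) > 0) {
      sib_key <- paste(sib2$a, sib2$b)
      ss <- ss[!(paste(ss$u, ss$child) %in% sib_key), , drop = FALSE]
      if (nrow(ss) > 0) rel$step_sibling <- data.frame(u = ss$u, v = ss$child)
    }
  }
  if (length(rel) == 0) return(empty)
  e <- do.call(rbind, Map(function(d, nm) {
    d$rel <- nm; d
  }, rel, names(rel)))
  e <- e[e$u != e$v, , drop = FALSE]
  # drop pairs that are already close family
  cf <- derive_close_family(prim)
  cf_key <- c(paste(cf$u, cf$v), paste(cf$v, cf$u))
  e <- e[!(paste(e$u, e$v) %in% cf_key), , drop = FALSE]
  e <- e[!duplicated(paste(pmin(e$u, e$v), pmax(e$u, e$v))), , drop = FALSE]
  rownames(e) <- NULL
  if (nrow(e) == 0) return(empty)
  data.frame(u = e$u, v = e$v, layer = "E", rel = e$rel,
             stringsAsFactors = FALSE)
}

#' Build the household layer
#'
#' Housemate links connect all people assigned to the same household
#' (including institutional households, which are simply large households).
#'
#' @param prim a `register_primitives` object
#' @return data.frame `u`, `v`, `layer = "H"`
#' @export
build_household_layer <- function(prim) {
  groups <- split(prim$people$id, prim$people$household)
  e <- clique_edges(groups)
  if (nrow(e) == 0) return(data.frame(u = character(), v = character(),
                                      layer = character()))
  data.frame(u = e$u, v = e$v, layer = "H", stringsAsFactors = FALSE)
}

#' Build the next-door neighbour layer
#'
#' For each person, the households within `radius` metres of their own
#' address (excluding their own) are neighbour candidates; if there are more
#' than `cap` of them they are randomly sampled down to `cap`. The person is
#' linked to every member of the selected households; an undirected edge
#' exists when either side selects the other.
#'
#' @param prim a `register_primitives` object
#' @param radius neighbour radius in metres (default 50)
#' @param cap maximum number of neighbour households per person (default 10)
#' @param seed seed for the down-sampling (defaults to the config seed + 1)
#' @param directed return the raw per-person selections (`u` = selecting
#'   person) instead of the undirected union
#' @return data.frame `u`, `v`, `layer = "N"`
#' @export
build_next_door_layer <- function(prim, radius = 50, cap = 10, seed = NULL,
                                  directed = FALSE) {
  hh <- prim$households
  empty <- data.frame(u = character(), v = character(), layer = character())
  if (nrow(hh) == 0 || nrow(prim$people) == 0) return(empty)
  if (anyNA(hh$x) || anyNA(hh$y)) stop("household coordinates missing",
                                       call. = FALSE)
  if (is.null(seed)) seed <- prim$config$seed + 1L
  set.seed(seed)
  nh <- nrow(hh)
  # households within radius, chunked pairwise distances
  nbr <- vector("list", nh)
  block <- 512L
  for (s in seq(1L, nh, by = block)) {
    sel <- s:min(s + block - 1L, nh)
    d2 <- outer(hh$x[sel], hh$x, "-")^2 + outer(hh$y[sel], hh$y, "-")^2
    within <- d2 <= radius^2
    for (i in seq_along(sel)) {
      cand <- which(within[i, ])
      nbr[[sel[i]]] <- cand[cand != sel[i]]
    }
  }
  members <- split(prim$people$id, match(prim$people$household,
                                         hh$household_id))
  hh_of_person <- match(prim$people$household, hh$household_id)
  us <- vector("list", nrow(prim$people)); vs <- us
  for (p in seq_len(nrow(prim$people))) {
    cand <- nbr[[hh_of_person[p]]]
    if (length(cand) == 0) next
    if (length(cand) > cap) cand <- sort(sample(cand, cap))
    linked <- unlist(members[as.character(cand)], use.names = FALSE)
    us[[p]] <- rep(prim$people$id[p], length(linked))
    vs[[p]] <- linked
  }
  u <- unlist(us); v <- unlist(vs)
  if (length(u) == 0) return(empty)
  if (directed) {
    return(data.frame(u = u, v = v, layer = "N", stringsAsFactors = FALSE))
  }
  keep <- !duplicated(paste(pmin(u, v), pmax(u, v))) & u != v
  data.frame(u = u[keep], v = v[keep], layer = "N", stringsAsFactors = FALSE)
}

#' Build the school layer
#'
#' Cliques within each school group (same school, year, class location,
#' level of education, and study programme for universities). The edge tag
#' `school_level` carries the level for sublayer filters (`Sp`, `Ss`).
#'
#' @param prim a `register_primitives` object
#' @return data.frame `u`, `v`, `layer = "S"`, `school_level`
#' @export
build_school_layer <- function(prim) {
  sg <- prim$school_groups
  empty <- data.frame(u = character(), v = character(), layer = character(),
                      school_level = character())
  if (nrow(sg) == 0) return(empty)
  groups <- split(sg$person, sg$group)
  level_of <- vapply(split(sg$level, sg$group), `[`, character(1), 1)
  es <- lapply(names(groups), function(gname) {
    e <- clique_edges(groups[gname])
    if (nrow(e) > 0) e$school_level <- level_of[[gname]]
    e
  })
  e <- do.call(rbind, es[vapply(es, nrow, integer(1)) > 0])
  if (is.null(e) || nrow(e) == 0) return(empty)
  data.frame(u = e$u, v = e$v, layer = "S", school_level = e$school_level,
             stringsAsFactors = FALSE)
}

#' Build the work layer
#'
#' Workplaces with fewer than `clique_threshold` employees become full
#' cliques; in larger workplaces every employee is linked to their
#' `k_nearest` geographically closest colleagues (Euclidean distance between
#' home addresses, ties broken by person id), and an undirected edge exists
#' when either side selects the other. The edge tag `workplace_size` enables
#' the small-workplace sublayer filter (`Ws`).
#'
#' @param prim a `register_primitives` object
#' @param clique_threshold workplace size below which the clique rule
#'   applies (default 100)
#' @param k_nearest number of closest colleagues linked above the threshold
#'   (default 100)
#' @param directed return the raw per-employee selections (`u` = selecting
#'   employee; small workplaces still appear as undirected cliques) instead
#'   of the undirected union
#' @return data.frame `u`, `v`, `layer = "W"`, `workplace_size`
#' @export
build_work_layer <- function(prim, clique_threshold = 100, k_nearest = 100,
                             directed = FALSE) {
  emp <- prim$employment
  empty <- data.frame(u = character(), v = character(), layer = character(),
                      workplace_size = integer())
  if (nrow(emp) == 0) return(empty)
  hh <- prim$households
  px <- hh$x[match(prim$people$household, hh$household_id)]
  py <- hh$y[match(prim$people$household, hh$household_id)]
  names(px) <- names(py) <- prim$people$id
  out <- list()
  for (wp in split(emp$person, emp$workplace)) {
    s <- length(wp)
    if (s < 2) next
    if (s < clique_threshold) {
      e <- clique_edges(list(wp))
    } else {
      x <- px[wp]; y <- py[wp]
      if (anyNA(x) || anyNA(y)) {
        stop("workplace at/over the clique threshold with missing member ",
             "coordinates", call. = FALSE)
      }
      wp_sorted <- wp[order(wp)]
      x <- x[wp_sorted]; y <- y[wp_sorted]
      us <- vector("list", s); vs <- us
      for (i in seq_len(s)) {
        d2 <- (x - x[i])^2 + (y - y[i])^2
        ord <- order(d2, wp_sorted)    # deterministic tie-break by id
        ord <- ord[ord != i]
        sel <- ord[seq_len(min(k_nearest, s - 1))]
        us[[i]] <- rep(wp_sorted[i], length(sel))
        vs[[i]] <- wp_sorted[sel]
      }
      u <- unlist(us); v <- unlist(vs)
      if (directed) {
        keep <- rep(TRUE, length(u))
      } else {
        keep <- !duplicated(paste(pmin(u, v), pmax(u, v)))
      }
      e <- data.frame(u = u[keep], v = v[keep], stringsAsFactors = FALSE)
    }
    e$workplace_size <- s
    out[[length(out) + 1]] <- e
  }
  e <- do.call(rbind, out)
  if (is.null(e) || nrow(e) == 0) return(empty)
  data.frame(u = e$u, v = e$v, layer = "W",
             workplace_size = as.integer(e$workplace_size),
             stringsAsFactors = FALSE)
}

#' Assemble the six layers into a multilayer graph
#'
#' Derives all six layers from the register primitives and returns the
#' node-aligned multilayer graph together with the node attribute table.
#'
#' @param prim a `register_primitives` object
#' @return list with `graph` (an [mln_graph()]) and `nodes` (node table with
#'   `node_id`, `age`, `income_decile`, `education_level`,
#'   `urbanization_level`, `family_info_complete`, `migration_generation`)
#' @export
assemble <- function(prim) {
  stopifnot(inherits(prim, "register_primitives"))
  cfg <- prim$config
  parts <- list(
    derive_close_family(prim),
    derive_extended_family(prim),
    build_household_layer(prim),
    build_next_door_layer(prim, radius = cfg$next_door_radius_m,
                          cap = cfg$next_door_cap),
    build_school_layer(prim),
    build_work_layer(prim, clique_threshold = cfg$work_clique_threshold,
                     k_nearest = cfg$work_k_nearest))
  cols <- c("u", "v", "layer", "rel", "school_level", "workplace_size")
  parts <- lapply(parts, function(d) {
    for (col in setdiff(cols, names(d))) {
      d[[col]] <- if (col == "workplace_size") {
        rep(NA_integer_, nrow(d))
      } else rep(NA_character_, nrow(d))
    }
    d[, cols, drop = FALSE]
  })
  edges <- do.call(rbind, parts)
  g <- mln_graph(edges, nodes = prim$people$id, layers = LAYER_CODES)
  nodes <- data.frame(
    node_id = prim$people$id,
    age = prim$people$age,
    income_decile = prim$people$income_decile,
    education_level = prim$people$education_level,
    urbanization_level = prim$people$urbanization_level,
    family_info_complete = prim$people$family_info_complete,
    migration_generation = prim$people$migration_generation,
    stringsAsFactors = FALSE)
  list(graph = g, nodes = nodes)
}

#' One-call synthetic population
#'
#' Convenience wrapper: [generate_primitives()] followed by [assemble()].
#'
#' @param config a [population_config()]
#' @return list with `graph`, `nodes` and `primitives`
#' @export
synth_population <- function(config) {
  prim <- generate_primitives(config)
  out <- assemble(prim)
  out$primitives <- prim
  out
}
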