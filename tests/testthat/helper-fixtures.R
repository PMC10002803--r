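# Shared fixtures and independent oracles for the test suite.

# Small hand-built road network:
#
#   n1 --5km--> n2 --5km--> n3      (50 km/h on every edge)
#    \--------12km---------/
#   n4 isolated unless connected
tiny_network <- function() {
  list(
    nodes = data.frame(node_id = c("n1", "n2", "n3", "n4"),
                       x = c(0, 5, 10, 50), y = c(0, 0, 0, 50)),
    edges = data.frame(node_a = c("n1", "n2", "n1"),
                       node_b = c("n2", "n3", "n3"),
                       length_km = c(5, 5, 12),
                       speed_kmh = 50)
  )
}

# Exhaustive shortest-path oracle: enumerate every simple path.
brute_force_minutes <- function(network, from, to) {
  w <- equiscreen::edge_minutes(network$edges$length_km,
                                network$edges$speed_kmh)
  adj <- list()
  for (i in seq_len(nrow(network$edges))) {
    a <- network$edges$node_a[i]; b <- network$edges$node_b[i]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, w = w[i]))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, w = w[i]))
  }
  best <- Inf
  dfs <- function(node, visited, acc) {
    if (acc >= best) return()
    if (node == to) { best <<- acc; return() }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      if (!nb$to[k] %in% visited) dfs(nb$to[k], c(visited, nb$to[k]),
                                      acc + nb$w[k])
    }
  }
  dfs(from, from, 0)
  best
}

random_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  ids <- sprintf("r%02d", seq_len(n_nodes))
  pairs <- t(replicate(n_edges, sample(n_nodes, 2)))
  list(nodes = data.frame(node_id = ids, x = runif(n_nodes, 0, 20),
                          y = runif(n_nodes, 0, 20)),
       edges = data.frame(node_a = ids[pairs[, 1]], node_b = ids[pairs[, 2]],
                          length_km = runif(n_edges, 1, 15),
                          speed_kmh = sample(c(30, 50, 80), n_edges,
                                             replace = TRUE)))
}

random_tracts <- function(n, seed) {
  set.seed(seed)
  data.frame(
    tract_id = sprintf("t%03d", seq_len(n)),
    county = sample(c("urban", "rural"), n, replace = TRUE),
    population = sample(500:8000, n, replace = TRUE),
    women_40_49 = sample(0:600, n, replace = TRUE),
    women_50_74 = sample(0:1500, n, replace = TRUE),
    women_over_74 = sample(0:400, n, replace = TRUE),
    pct_black_women = runif(n),
    deprivation = rnorm(n),
    pct_vehicle = runif(n),
    bus_stops = rpois(n, 10),
    stringsAsFactors = FALSE
  )
}

# Exhaustive CMCLP oracle: best coverage over all p-subsets of candidates.
brute_force_cmclp <- function(problem) {
  cand <- sort(problem$candidates$site_id)
  subsets <- utils::combn(cand, problem$p, simplify = FALSE)
  best <- -Inf
  for (s in subsets) {
    sites <- rbind(problem$required_sites[, c("site_id", "capacity")],
                   problem$candidates[problem$candidates$site_id %in% s,
                                      c("site_id", "capacity")])
    cov <- equiscreen::assign_demand(sites, problem$demand_points,
                                    problem$matrix,
                                    problem$cutoff)$covered_demand
    if (cov > best) best <- cov
  }
  best
}

# Random small CMCLP instance defined directly by a drive-time matrix.
random_cmclp_instance <- function(seed, n_candidates = NULL, p = NULL) {
  set.seed(seed)
  nd <- sample(20:60, 1)
  nc <- n_candidates %||% sample(4:8, 1)
  nr <- 2
  p <- p %||% sample(1:min(3, nc), 1)
  d_ids <- sprintf("d%02d", seq_len(nd))
  r_ids <- sprintf("R%02d", seq_len(nr))
  c_ids <- sprintf("C%02d", seq_len(nc))
  m <- matrix(runif(nd * (nr + nc), 1, 40), nrow = nd,
              dimnames = list(d_ids, c(r_ids, c_ids)))
  equiscreen::allocation_problem(
    demand_points = data.frame(id = d_ids,
                               weight = round(runif(nd, 10, 100))),
    required_sites = data.frame(site_id = r_ids,
                                capacity = round(runif(nr, 100, 400))),
    candidates = data.frame(site_id = c_ids,
                            capacity = round(runif(nc, 150, 600))),
    matrix = m, p = p, cutoff = 20)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A state inventory carrying the published worked-example counts: 30
# facilities / 44 units statewide, 16 facilities, 25 units, 7 BICOE sites and
# 16 BICOE units in the urban county; shares are derived, never stored.
delaware_inventory <- function() {
  tracts <- data.frame(
    tract_id = c("u", "r"), county = c("urban", "rural"),
    population = c(555036, 388696))
  facilities <- rbind(
    data.frame(facility_id = sprintf("u%02d", 1:16), county = "urban",
               units = c(c(2, 2, 2, 3, 3, 2, 2), rep(1, 9)),   # 25 units
               bicoe = rep(c(TRUE, FALSE), c(7, 9))),
    data.frame(facility_id = sprintf("r%02d", 1:14), county = "rural",
               units = c(c(2, 2), rep(1, 9), 2, 2, 2),         # 19 units
               bicoe = rep(c(TRUE, FALSE), c(2, 12)))
  )
  list(tracts = tracts, facilities = facilities)
}

# The default scenario is expensive enough to share across test files.
.scenario_cache <- new.env(parent = emptyenv())
default_scenario <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- equiscreen::generate_scenario(
      equiscreen::scenario_config(seed = seed))
  }
  .scenario_cache[[key]]
}
default_travel_matrix <- function(seed = 1) {
  key <- paste0("tm", seed)
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- equiscreen::scenario_travel_matrix(
      default_scenario(seed))
  }
  .scenario_cache[[key]]
}
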