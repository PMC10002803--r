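#' Scenario configuration for the synthetic-geography generator
#'
#' The defaults emulate a small, three-county US state with one urban county
#' and a rural remainder: 214 populated tracts (129 urban, 85 rural), 30
#' mammography facilities with 1-4 units each and roughly 30% BICOE
#' designation concentrated in the urban county, and a road network on which
#' most tracts are within 15 network-minutes of some facility while a small
#' rural minority exceeds 30 minutes. Demographic means and dispersions come
#' from published tract-level summaries: urban tracts have more women aged
#' 40-49 but fewer aged 50-74 and over 74, a higher fraction of Black women,
#' lower vehicle ownership, and more bus stops than rural tracts.
#'
#' Coordinates are planar kilometres; the analysis only ever needs network
#' minutes, so no projection machinery is involved.
#'
#' @param seed integer RNG seed
#' @param n_tracts_urban,n_tracts_rural tract counts per county group
#' @param demographics per-county named lists of distribution parameters;
#'   see the function body for the fields
#' @param facilities facility placement parameters: counts per county, unit
#'   count distribution, BICOE probability per county, per-unit capacity
#' @param network lattice parameters: county bounding boxes, grid spacing
#'   (km) and free-flow speed (km/h) per county
#' @param blocks_per_tract population blocks per tract (Dirichlet split)
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(seed = 1L,
                            n_tracts_urban = 129L,
                            n_tracts_rural = 85L,
                            demographics = NULL,
                            facilities = NULL,
                            network = NULL,
                            blocks_per_tract = 5L) {
  stop_if_not(n_tracts_urban >= 1 && n_tracts_rural >= 1,
              "tract counts must be positive")
  stop_if_not(blocks_per_tract >= 1, "blocks_per_tract must be positive")
  demographics <- demographics %||% list(
    urban = list(women_40_49 = c(284, 193), women_50_74 = c(649, 328),
                 women_over_74 = c(155, 102), pct_black = c(0.26, 0.25),
                 pct_vehicle = c(0.91, 0.11), bus_stops = c(14, 11)),
    rural = list(women_40_49 = c(266, 181), women_50_74 = c(824, 437),
                 women_over_74 = c(209, 109), pct_black = c(0.16, 0.14),
                 pct_vehicle = c(0.95, 0.04), bus_stops = c(7, 8)),
    # population is women-40+ count scaled up to the full tract population
    pop_multiplier = c(3.76, 0.4)
  )
  facilities <- facilities %||% list(
    n_urban = 16L, n_rural = 14L,
    unit_probs = c(0.65, 0.25, 0.07, 0.03),   # P(1..4 units), mean ~1.48
    bicoe_prob = c(urban = 7 / 16, rural = 2 / 14),
    per_unit_annual = 4500
  )
  network <- network %||% list(
    urban = list(box = c(xmin = 0, xmax = 40, ymin = 110, ymax = 160),
                 spacing_km = 3, speed_kmh = 50,
                 n_centers = 3L, anchor_sd = 4, remote_share = 0,
                 center_margin = 0.15),
    rural = list(box = c(xmin = 0, xmax = 50, ymin = 0, ymax = 110),
                 spacing_km = 8, speed_kmh = 80,
                 n_centers = 5L, anchor_sd = 8, remote_share = 0.15,
                 center_margin = 0.28)
  )
  stop_if_not(all(facilities$unit_probs >= 0) &&
                abs(sum(facilities$unit_probs) - 1) < 1e-8,
              "unit_probs must be a probability vector")
  stop_if_not(all(facilities$bicoe_prob >= 0 & facilities$bicoe_prob <= 1),
              "bicoe_prob values must lie in [0, 1]")
  structure(list(seed = as.integer(seed),
                 n_tracts_urban = as.integer(n_tracts_urban),
                 n_tracts_rural = as.integer(n_tracts_rural),
                 demographics = demographics, facilities = facilities,
                 network = network,
                 blocks_per_tract = as.integer(blocks_per_tract)),
            class = "scenario_config")
}

#' Population-weighted centroid
#'
#' @param blocks data.frame of population blocks with columns `x`, `y`,
#'   `population`
#' @return numeric `c(x, y)`, the population-mass-weighted mean coordinate
#' @export
weighted_centroid <- function(blocks) {
  stop_if_not(nrow(blocks) >= 1, "at least one block is required")
  w <- blocks$population
  stop_if_not(all(w >= 0), "block populations must be non-negative")
  stop_if_not(sum(w) > 0, "centroid undefined: total block population is zero")
  c(x = sum(w * blocks$x) / sum(w), y = sum(w * blocks$y) / sum(w))
}

# Beta draws parameterized by mean and sd, clamped to a proper Beta.
rbeta_ms <- function(n, mean, sd) {
  v <- min(sd^2, mean * (1 - mean) * 0.95)
  s <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * s, (1 - mean) * s)
}

rnbinom_ms <- function(n, mean, sd) {
  v <- max(sd^2, mean + 1e-6)
  if (v <= mean * (1 + 1e-9)) return(stats::rpois(n, mean))
  stats::rnbinom(n, size = mean^2 / (v - mean), mu = mean)
}

county_tracts <- function(n, county, dem, net, id_offset) {
  par <- dem[[county]]
  w4049 <- pmax(0, round(stats::rnorm(n, par$women_40_49[1], par$women_40_49[2])))
  w5074 <- pmax(0, round(stats::rnorm(n, par$women_50_74[1], par$women_50_74[2])))
  w74   <- pmax(0, round(stats::rnorm(n, par$women_over_74[1], par$women_over_74[2])))
  women <- w4049 + w5074 + w74
  mult <- pmax(1.1, stats::rnorm(n, dem$pop_multiplier[1], dem$pop_multiplier[2]))
  population <- pmax(1, round(pmax(women, 1) * mult))
  data.frame(
    tract_id = sprintf("t%03d", id_offset + seq_len(n)),
    county = county,
    population = population,
    women_40_49 = w4049, women_50_74 = w5074, women_over_74 = w74,
    pct_black_women = rbeta_ms(n, par$pct_black[1], par$pct_black[2]),
    deprivation = stats::rnorm(n),
    pct_vehicle = rbeta_ms(n, par$pct_vehicle[1], par$pct_vehicle[2]),
    bus_stops = rnbinom_ms(n, par$bus_stops[1], par$bus_stops[2]),
    stringsAsFactors = FALSE
  )
}

clip <- function(v, lo, hi) pmin(hi, pmax(lo, v))

# Anchor points for tract seeds: clustered around county "town" centers,
# with a remote uniform share (rural) that produces long drive times.
county_anchors <- function(n, net_par, centers) {
  box <- net_par$box
  remote <- stats::runif(n) < net_par$remote_share
  k <- sample.int(nrow(centers), n, replace = TRUE)
  x <- stats::rnorm(n, centers$x[k], net_par$anchor_sd)
  y <- stats::rnorm(n, centers$y[k], net_par$anchor_sd)
  x[remote] <- stats::runif(sum(remote), box["xmin"], box["xmax"])
  y[remote] <- stats::runif(sum(remote), box["ymin"], box["ymax"])
  data.frame(x = clip(x, box["xmin"], box["xmax"]),
             y = clip(y, box["ymin"], box["ymax"]))
}

town_centers <- function(net_par) {
  box <- net_par$box
  # towns sit in the interior so remote tracts near the fringe stay far away
  m <- net_par$center_margin %||% 0.15
  mx <- m * (box["xmax"] - box["xmin"])
  my <- m * (box["ymax"] - box["ymin"])
  data.frame(x = stats::runif(net_par$n_centers, box["xmin"] + mx, box["xmax"] - mx),
             y = stats::runif(net_par$n_centers, box["ymin"] + my, box["ymax"] - my))
}

# Jittered lattice over a county box; edges join 4-neighbours.
county_lattice <- function(net_par, id_offset) {
  box <- net_par$box
  s <- net_par$spacing_km
  xs <- seq(box["xmin"], box["xmax"], by = s)
  ys <- seq(box["ymin"], box["ymax"], by = s)
  grid <- expand.grid(ix = seq_along(xs), iy = seq_along(ys))
  n <- nrow(grid)
  nodes <- data.frame(
    node_id = sprintf("n%04d", id_offset + seq_len(n)),
    x = xs[grid$ix] + stats::runif(n, -0.3 * s, 0.3 * s),
    y = ys[grid$iy] + stats::runif(n, -0.3 * s, 0.3 * s),
    stringsAsFactors = FALSE
  )
  idx <- matrix(seq_len(n), nrow = length(xs))
  right <- cbind(as.vector(idx[-length(xs), ]), as.vector(idx[-1, ]))
  up <- cbind(as.vector(idx[, -length(ys)]), as.vector(idx[, -1]))
  pairs <- rbind(right, up)
  edges <- data.frame(
    node_a = nodes$node_id[pairs[, 1]],
    node_b = nodes$node_id[pairs[, 2]],
    length_km = sqrt((nodes$x[pairs[, 1]] - nodes$x[pairs[, 2]])^2 +
                       (nodes$y[pairs[, 1]] - nodes$y[pairs[, 2]])^2),
    speed_kmh = net_par$speed_kmh,
    stringsAsFactors = FALSE
  )
  list(nodes = nodes, edges = edges)
}

euclid_edge <- function(nodes, i, j, speed) {
  data.frame(node_a = nodes$node_id[i], node_b = nodes$node_id[j],
             length_km = sqrt((nodes$x[i] - nodes$x[j])^2 +
                                (nodes$y[i] - nodes$y[j])^2),
             speed_kmh = speed, stringsAsFactors = FALSE)
}

# Join the county lattices and repair connectivity so the giant component
# carries every snapped tract and facility.
repair_connectivity <- function(network, speed) {
  g <- network_graph(network)
  comp <- igraph::components(g)
  while (comp$no > 1) {
    main <- which(comp$membership == which.max(comp$csize))
    other <- which(comp$membership != which.max(comp$csize))
    nd <- network$nodes
    dmat <- outer(nd$x[main], nd$x[other], "-")^2 +
      outer(nd$y[main], nd$y[other], "-")^2
    hit <- arrayInd(which.min(dmat), dim(dmat))
    network$edges <- rbind(network$edges,
                           euclid_edge(nd, main[hit[1]], other[hit[2]], speed))
    g <- network_graph(network)
    comp <- igraph::components(g)
  }
  network
}

#' Snap points to the nearest road-network node
#'
#' Nearest by Euclidean distance; ties broken by the smallest `node_id`.
#'
#' @param x,y coordinates of the points to snap
#' @param network road network (list with `nodes`)
#' @return character vector of node ids
#' @export
snap_to_network <- function(x, y, network) {
  nd <- network$nodes[order(network$nodes$node_id), ]
  vapply(seq_along(x), function(i) {
    d2 <- (nd$x - x[i])^2 + (nd$y - y[i])^2
    nd$node_id[which.min(d2)]
  }, character(1))
}

#' Generate a seeded synthetic study region
#'
#' Produces tract demographics, population blocks (with population-weighted
#' tract centroids), a facility inventory, and a connected road network, all
#' deterministically from `config$seed`. See [scenario_config()] for what the
#' defaults emulate.
#'
#' @param config a [scenario_config()]
#' @return object of class `equiscreen_scenario`: list with `tracts`,
#'   `blocks`, `facilities`, `network`, `config`
#' @export
generate_scenario <- function(config = scenario_config()) {
  stop_if_not(inherits(config, "scenario_config"),
              "config must be built with scenario_config()")
  set.seed(config$seed)
  dem <- config$demographics
  netp <- config$network
  fac <- config$facilities

  tracts <- rbind(
    county_tracts(config$n_tracts_urban, "urban", dem, netp, 0L),
    county_tracts(config$n_tracts_rural, "rural", dem, netp,
                  config$n_tracts_urban)
  )

  centers <- list(urban = town_centers(netp$urban),
                  rural = town_centers(netp$rural))
  anchors <- rbind(
    county_anchors(config$n_tracts_urban, netp$urban, centers$urban),
    county_anchors(config$n_tracts_rural, netp$rural, centers$rural)
  )

  # blocks: Dirichlet population split around each tract anchor
  nb <- config$blocks_per_tract
  blocks <- do.call(rbind, lapply(seq_len(nrow(tracts)), function(i) {
    box <- netp[[tracts$county[i]]]$box
    share <- stats::rgamma(nb, 1)
    share <- share / sum(share)
    pop <- diff(c(0, round(cumsum(share) * tracts$population[i])))
    data.frame(
      block_id = sprintf("%s_b%d", tracts$tract_id[i], seq_len(nb)),
      tract_id = tracts$tract_id[i],
      x = clip(stats::rnorm(nb, anchors$x[i], 1.5), box["xmin"], box["xmax"]),
      y = clip(stats::rnorm(nb, anchors$y[i], 1.5), box["ymin"], box["ymax"]),
      population = pop, stringsAsFactors = FALSE
    )
  }))

  cent <- t(vapply(split(blocks, blocks$tract_id)[tracts$tract_id],
                   weighted_centroid, numeric(2)))
  tracts$centroid_x <- cent[, "x"]
  tracts$centroid_y <- cent[, "y"]

  # facilities cluster at town centers, like real imaging sites
  place_facilities <- function(n, county, id_offset) {
    ctr <- centers[[county]]
    box <- netp[[county]]$box
    k <- ((seq_len(n) - 1L) %% nrow(ctr)) + 1L   # round-robin over towns
    units <- sample.int(length(fac$unit_probs), n, replace = TRUE,
                        prob = fac$unit_probs)
    data.frame(
      facility_id = sprintf("f%02d", id_offset + seq_len(n)),
      county = county,
      x = clip(stats::rnorm(n, ctr$x[k], 2), box["xmin"], box["xmax"]),
      y = clip(stats::rnorm(n, ctr$y[k], 2), box["ymin"], box["ymax"]),
      units = units,
      bicoe = stats::runif(n) < fac$bicoe_prob[[county]],
      stringsAsFactors = FALSE
    )
  }
  facilities <- rbind(place_facilities(fac$n_urban, "urban", 0L),
                      place_facilities(fac$n_rural, "rural", fac$n_urban))
  facilities$capacity <- facility_capacity(
    facilities$units, capacity_model(fac$per_unit_annual))

  urban_net <- county_lattice(netp$urban, 0L)
  rural_net <- county_lattice(netp$rural, nrow(urban_net$nodes))
  network <- list(nodes = rbind(urban_net$nodes, rural_net$nodes),
                  edges = rbind(urban_net$edges, rural_net$edges))
  network <- repair_connectivity(network, netp$rural$speed_kmh)

  tracts$node_id <- snap_to_network(tracts$centroid_x, tracts$centroid_y,
                                    network)
  facilities$node_id <- snap_to_network(facilities$x, facilities$y, network)

  structure(list(tracts = tracts, blocks = blocks, facilities = facilities,
                 network = network, config = config),
            class = "equiscreen_scenario")
}

#' @export
print.equiscreen_scenario <- function(x, ...) {
  cat(sprintf(
    "<equiscreen_scenario> %d tracts (%d urban / %d rural), %d facilities (%d BICOE), %d road nodes\n",
    nrow(x$tracts), sum(x$tracts$county == "urban"),
    sum(x$tracts$county == "rural"), nrow(x$facilities),
    sum(x$facilities$bicoe), nrow(x$network$nodes)))
  invisible(x)
}

#' Simulate facility counts with known regression structure
#'
#' Draws a per-tract outcome count from a Poisson law whose log-rate is
#' `intercept + Z beta + log(population)`, where `Z` holds the standardized
#' covariates in the canonical order (deprivation, women_40_49, women_50_74,
#' women_over_74, pct_black_women, pct_vehicle, bus_stops). Used to verify
#' that the rate-regression module recovers planted coefficients.
#'
#' @param tracts tract data.frame (needs the seven covariates + `population`)
#' @param beta named numeric vector of per-SD log rate ratios; names must be
#'   a subset of the canonical covariates (others default to 0)
#' @param seed integer seed for the Poisson draws
#' @param intercept log baseline rate per person-year; the default yields a
#'   realistic sparse outcome (~0.13 facilities per tract at typical tract
#'   populations)
#' @return list with `counts`, `mu` (expected counts), `beta`, `intercept`,
#'   and `standardization` (mean/sd per covariate)
#' @export
plant_known_rates <- function(tracts, beta = NULL, seed = 1L,
                              intercept = log(3e-5)) {
  covs <- rate_model_covariates()
  full_beta <- stats::setNames(numeric(length(covs)), covs)
  if (length(beta)) {
    stop_if_not(!is.null(names(beta)) && all(names(beta) %in% covs),
                "beta must be named by covariates: %s",
                paste(covs, collapse = ", "))
    full_beta[names(beta)] <- beta
  }
  stop_if_not(all(tracts$population > 0), "tracts must be populated")
  std <- lapply(covs, function(v) standardize(tracts[[v]], name = v))
  Z <- do.call(cbind, lapply(std, `[[`, "z"))
  eta <- intercept + as.vector(Z %*% full_beta) + log(tracts$population)
  stop_if_not(all(is.finite(eta)), "non-finite log-rate; check beta/covariates")
  set.seed(seed)
  counts <- stats::rpois(nrow(tracts), exp(eta))
  list(counts = counts, mu = exp(eta), beta = full_beta, intercept = intercept,
       standardization = data.frame(
         covariate = covs,
         mean = vapply(std, function(s) s$mean, numeric(1)),
         sd = vapply(std, function(s) s$sd, numeric(1))))
}
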