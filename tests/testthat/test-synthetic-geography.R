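test_that("weighted_centroid matches hand arithmetic and rejects zero mass", {
  b <- function(x, y, w) data.frame(x = x, y = y, population = w)
  expect_equal(weighted_centroid(b(c(0, 2), c(0, 0), c(1, 1))),
               c(x = 1, y = 0))
  expect_equal(weighted_centroid(b(c(0, 4), c(0, 0), c(3, 1))),
               c(x = 1, y = 0))
  expect_equal(weighted_centroid(b(5, 7, 9)), c(x = 5, y = 7))
  expect_error(weighted_centroid(b(c(1, 2), c(1, 2), c(0, 0))), "undefined")
})

test_that("same config and seed reproduce the scenario byte-for-byte", {
  cfg <- scenario_config(seed = 99, n_tracts_urban = 20, n_tracts_rural = 15)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("generated scenarios satisfy the tract and facility invariants", {
  for (seed in c(4, 8)) {
    cfg <- scenario_config(seed = seed,
                           n_tracts_urban = sample(15:40, 1),
                           n_tracts_rural = sample(10:30, 1))
    s <- generate_scenario(cfg)
    tr <- s$tracts
    expect_true(all(tr$population > 0))
    expect_true(all(tr$women_40_49 + tr$women_50_74 + tr$women_over_74 <=
                      tr$population))
    expect_true(all(tr$pct_black_women >= 0 & tr$pct_black_women <= 1))
    expect_true(all(tr$pct_vehicle >= 0 & tr$pct_vehicle <= 1))
    expect_true(all(tr$bus_stops >= 0))
    expect_true(all(s$blocks$population >= 0))
    expect_true(all(s$blocks$tract_id %in% tr$tract_id))
    # block populations aggregate exactly to the tract population
    agg <- tapply(s$blocks$population, s$blocks$tract_id, sum)
    expect_equal(as.vector(agg[tr$tract_id]), tr$population)
    expect_true(all(s$facilities$units >= 1))
    expect_equal(s$facilities$capacity, s$facilities$units * 4500)
  }
})

test_that("urban tracts are more Black, less motorized, better bussed", {
  s <- default_scenario()
  tr <- s$tracts
  u <- tr$county == "urban"
  expect_gt(mean(tr$pct_black_women[u]), mean(tr$pct_black_women[!u]))
  expect_lt(mean(tr$pct_vehicle[u]), mean(tr$pct_vehicle[!u]))
  expect_gt(mean(tr$bus_stops[u]), mean(tr$bus_stops[!u]))
})

test_that("total facility capacity is 4500 x total units", {
  s <- default_scenario()
  expect_equal(sum(s$facilities$capacity), 4500 * sum(s$facilities$units))
})

test_that("the road network giant component holds every snapped point", {
  s <- default_scenario()
  g <- igraph::graph_from_data_frame(
    s$network$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = s$network$nodes$node_id)
  comp <- igraph::components(g)
  giant <- names(comp$membership[comp$membership == which.max(comp$csize)])
  expect_true(all(s$tracts$node_id %in% giant))
  expect_true(all(s$facilities$node_id %in% giant))
})

test_that("infeasible configs are rejected", {
  expect_error(scenario_config(n_tracts_urban = 0), "positive")
  expect_error(
    scenario_config(facilities = list(n_urban = 2, n_rural = 2,
                                      unit_probs = c(0.5, 0.2),
                                      bicoe_prob = c(urban = 0.5, rural = 0.1),
                                      per_unit_annual = 4500)),
    "probability")
})

test_that("plant_known_rates draws from the planted Poisson law", {
  tr <- random_tracts(300, seed = 21)
  # offset contract: doubling population doubles expected counts
  p1 <- plant_known_rates(tr, c(pct_black_women = 0.5), seed = 1)
  tr2 <- tr
  tr2$population <- tr$population * 2
  p2 <- plant_known_rates(tr2, c(pct_black_women = 0.5), seed = 1)
  expect_equal(p2$mu, 2 * p1$mu)
  expect_error(plant_known_rates(tr, c(nope = 1)), "named by covariates")

  # Monte-Carlo: replicate means converge to mu
  tr_small <- random_tracts(40, seed = 3)
  reps <- vapply(1:400, function(i)
    plant_known_rates(tr_small, NULL, seed = i, intercept = log(2e-4))$counts,
    numeric(40))
  mu <- plant_known_rates(tr_small, NULL, seed = 1,
                          intercept = log(2e-4))$mu
  se <- sqrt(mu / 400)
  expect_true(all(abs(rowMeans(reps) - mu) < 5 * se + 1e-9))
})

test_that("a planted negative effect yields fitted RR below 1", {
  tr <- random_tracts(400, seed = 31)
  below <- vapply(1:50, function(i) {
    pl <- plant_known_rates(tr, c(pct_black_women = -1), seed = 1000 + i,
                            intercept = log(1e-4))
    fit <- fit_rate_model(tr, pl$counts)
    fit$rate_ratio[fit$covariate == "pct_black_women"] < 1
  }, logical(1))
  expect_gte(mean(below), 0.95)
})

test_that("snapping is deterministic with smallest-id tie-break", {
  net <- list(nodes = data.frame(node_id = c("b", "a"),
                                 x = c(1, 1), y = c(0, 0)))
  expect_identical(snap_to_network(1, 0, net), "a")
})
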