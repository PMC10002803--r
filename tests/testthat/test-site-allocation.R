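grid_extent <- c(xmin = 0, xmax = 10, ymin = 0, ymax = 10)

test_that("fishnet_candidates lays, snaps and dedups the grid", {
  # a dense dummy network so snapping is near-identity
  nodes <- expand.grid(x = 0:10, y = 0:10)
  net <- list(nodes = data.frame(node_id = sprintf("g%03d", seq_len(nrow(nodes))),
                                 x = nodes$x, y = nodes$y))
  cand <- fishnet_candidates(grid_extent, 5, net)
  expect_equal(nrow(cand), 4)
  expect_equal(cand$capacity, rep(4500, 4))
  # degenerate: cell larger than extent -> single candidate at the center
  c1 <- fishnet_candidates(grid_extent, 25, net)
  expect_equal(nrow(c1), 1)
  expect_equal(c(c1$x, c1$y), c(5, 5))
  # two cells snapping to one node are merged
  tiny <- list(nodes = data.frame(node_id = "only", x = 5, y = 5))
  expect_equal(nrow(fishnet_candidates(grid_extent, 5, tiny)), 1)
  expect_error(fishnet_candidates(grid_extent, -1, net), "positive")
  expect_error(fishnet_candidates(c(xmin = 0, xmax = 0, ymin = 0, ymax = 1),
                                  1, net), "degenerate")
})

simple_matrix <- function(times, d_ids, s_ids) {
  matrix(times, nrow = length(d_ids), byrow = TRUE,
         dimnames = list(d_ids, s_ids))
}

test_that("assign_demand follows nearest-feasible-within-cutoff rules", {
  sites <- data.frame(site_id = "s1", capacity = 100)
  dp <- data.frame(id = "d1", weight = 50)
  m <- simple_matrix(10, "d1", "s1")
  a <- assign_demand(sites, dp, m, cutoff = 20)
  expect_equal(a$assignment$site_id, "s1")
  expect_equal(unname(a$loads["s1"]), 50)
  expect_equal(a$covered_demand, 50)
  # beyond the 20-minute cutoff the point stays unassigned
  a2 <- assign_demand(sites, dp, simple_matrix(25, "d1", "s1"), cutoff = 20)
  expect_true(is.na(a2$assignment$site_id))
  expect_equal(a2$covered_demand, 0)
  # whole-point rule: capacity binds, the farther point loses out
  dp2 <- data.frame(id = c("d1", "d2"), weight = c(60, 60))
  m2 <- simple_matrix(c(5, 9), c("d1", "d2"), "s1")
  a3 <- assign_demand(sites, dp2, m2, cutoff = 20)
  expect_equal(a3$assignment$site_id, c("s1", NA))
  expect_equal(unname(a3$loads["s1"]), 60)
})

test_that("assignment respects capacity and cutoff on random instances", {
  for (seed in c(11, 12, 13)) {
    prob <- random_cmclp_instance(seed)
    sites <- rbind(prob$required_sites, prob$candidates)
    a <- assign_demand(sites, prob$demand_points, prob$matrix, prob$cutoff)
    expect_true(all(a$loads <= sites$capacity[match(names(a$loads),
                                                    sites$site_id)] + 1e-9))
    done <- !is.na(a$assignment$site_id)
    expect_true(all(a$assignment$minutes[done] <= prob$cutoff))
    expect_equal(a$covered_demand, sum(prob$demand_points$weight[done]))
  }
})

test_that("greedy opens the dominant candidate", {
  dp <- data.frame(id = c("d1", "d2"), weight = c(1000, 400))
  req <- data.frame(site_id = "R1", capacity = 0)
  cand <- data.frame(site_id = c("C1", "C2"), capacity = c(2000, 2000))
  m <- simple_matrix(c(50, 5, 50,
                       50, 50, 5), c("d1", "d2"), c("R1", "C1", "C2"))
  prob <- allocation_problem(dp, req, cand, m, p = 1)
  expect_equal(solve_cmclp(prob)$opened, "C1")
})

test_that("greedy+interchange matches exhaustive search on small instances", {
  for (seed in 101:120) {
    prob <- random_cmclp_instance(seed)
    got <- solve_cmclp(prob)$covered_demand
    expect_equal(got, brute_force_cmclp(prob), info = paste("seed", seed))
  }
})

test_that("a saturated baseline yields zero marginal coverage", {
  dp <- data.frame(id = "d1", weight = 100)
  req <- data.frame(site_id = "R1", capacity = 1000)
  cand <- data.frame(site_id = c("C1", "C2"), capacity = c(4500, 4500))
  m <- simple_matrix(c(5, 10, 15), "d1", c("R1", "C1", "C2"))
  res <- solve_cmclp(allocation_problem(dp, req, cand, m, p = 1))
  expect_equal(res$covered_demand, res$baseline_covered_demand)
  expect_error(allocation_problem(dp, req, cand, m, p = 3), "between 1 and")
})

test_that("cumulative siting nests and reduces to single solves", {
  prob <- random_cmclp_instance(7, n_candidates = 8, p = 1)
  nested <- cumulative_siting(prob, p_values = c(1, 3, 5))
  expect_true(all(nested$p1$opened %in% nested$p3$opened))
  expect_true(all(nested$p3$opened %in% nested$p5$opened))
  expect_equal(lengths(lapply(nested, `[[`, "opened")),
               c(p1 = 1L, p3 = 3L, p5 = 5L))
  covs <- vapply(nested, `[[`, numeric(1), "covered_demand")
  expect_true(all(diff(covs) >= -1e-9))
  solo <- solve_cmclp(prob)
  expect_equal(nested$p1$opened, solo$opened)
  expect_error(cumulative_siting(prob, c(3, 1)), "ascending")
})

test_that("drive_time_improvement is a weighted mean reduction, never negative", {
  dp <- data.frame(id = c("d1", "d2"), weight = c(10, 30),
                   county = c("urban", "rural"))
  m <- simple_matrix(c(20, 0,
                       10, 10), c("d1", "d2"), c("S1", "S2"))
  same <- drive_time_improvement("S1", "S1", dp, m)
  expect_equal(same$pct_reduction, 0)
  # new site at d1's node: its 20 minutes collapse to 0
  imp <- drive_time_improvement("S1", c("S1", "S2"), dp, m)
  expect_equal(imp$mean_before, (10 * 20 + 30 * 10) / 40)
  expect_equal(imp$mean_after, (10 * 0 + 30 * 10) / 40)
  expect_gt(imp$pct_reduction, 0)
  expect_equal(imp$by_county$pct_reduction[imp$by_county$county == "urban"],
               100)
  single <- drive_time_improvement("S1", c("S1", "S2"),
                                   dp[1, ], m["d1", , drop = FALSE])
  expect_equal(single$pct_reduction, 100)
  expect_error(drive_time_improvement(c("S1", "S2"), "S1", dp, m), "contain")
})

test_that("bicoe_conversion requires BICOEs and enough candidates", {
  fac <- data.frame(facility_id = c("f1", "f2", "f3"),
                    bicoe = c(TRUE, FALSE, FALSE),
                    units = c(2, 1, 1), capacity = c(9000, 4500, 4500))
  dp <- data.frame(id = "d1", weight = 100)
  m <- simple_matrix(c(5, 10, 15), "d1", c("f1", "f2", "f3"))
  res <- bicoe_conversion(fac, dp, m, p = 1)
  expect_equal(res$opened, "f2")  # ties impossible: nearest viable candidate
  expect_error(bicoe_conversion(fac, dp, m, p = 5), "fewer non-BICOE")
  none <- fac
  none$bicoe <- FALSE
  expect_error(bicoe_conversion(none, dp, m, p = 1), "BICOE site")
  # single-unit flag resets candidate capacity
  res1 <- bicoe_conversion(fac, dp, m, p = 1, single_unit = TRUE)
  expect_equal(res1$covered_demand, 100)
})
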