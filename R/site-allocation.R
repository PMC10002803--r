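#' Fishnet candidate sites
#'
#' Lays a regular grid over the study extent, takes every cell center, snaps
#' each to its nearest road-network node, and merges candidates that share a
#' snap node (keeping the first in grid order). When the cell exceeds the
#' extent the single candidate sits at the extent center.
#'
#' @param extent named numeric `c(xmin, xmax, ymin, ymax)` in km
#' @param cell_km grid cell size in km (> 0)
#' @param network road network (for snapping)
#' @param units unit count assumed at a new site (default 1)
#' @param model a [capacity_model()]
#' @return data.frame: `candidate_id`, `x`, `y`, `node_id`, `units`,
#'   `capacity`
#' @export
fishnet_candidates <- function(extent, cell_km, network, units = 1,
                               model = capacity_model()) {
  stop_if_not(cell_km > 0, "cell_km must be positive")
  stop_if_not(extent["xmax"] > extent["xmin"] && extent["ymax"] > extent["ymin"],
              "extent is degenerate")
  axis_centers <- function(lo, hi) {
    n <- max(1L, floor((hi - lo) / cell_km))
    # center the grid in the extent so a degenerate grid sits at the middle
    off <- ((hi - lo) - n * cell_km) / 2
    lo + off + cell_km * (seq_len(n) - 0.5)
  }
  grid <- expand.grid(x = axis_centers(extent["xmin"], extent["xmax"]),
                      y = axis_centers(extent["ymin"], extent["ymax"]))
  stop_if_not(nrow(grid) >= 1, "empty candidate grid")
  grid$node_id <- snap_to_network(grid$x, grid$y, network)
  grid <- grid[!duplicated(grid$node_id), ]
  data.frame(candidate_id = sprintf("c%03d", seq_len(nrow(grid))),
             x = grid$x, y = grid$y, node_id = grid$node_id,
             units = units,
             capacity = facility_capacity(units, model),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Capacitated nearest-feasible demand assignment
#'
#' Demand points are processed in ascending order of their nearest-site
#' drive time (ties by point id) and each is assigned wholly to its nearest
#' site that still has capacity for its full weight and lies within the
#' drive-time cutoff; otherwise it stays unassigned. Site ties break on the
#' smaller site id. No fractional splitting.
#'
#' @param sites data.frame with `site_id`, `capacity`
#' @param demand_points data.frame with `id`, `weight` (annual screenings)
#' @param matrix drive-time matrix covering all demand x site pairs
#' @param cutoff maximum minutes a woman is assumed to travel (default 20)
#' @return list: `assignment` (data.frame `id`, `site_id`, `minutes`;
#'   `site_id` is `NA` when unassigned), `loads` (named vector),
#'   `covered_demand`
#' @export
assign_demand <- function(sites, demand_points, matrix, cutoff = 20) {
  stop_if_not(cutoff > 0, "cutoff must be positive")
  stop_if_not(all(demand_points$id %in% rownames(matrix)) &&
                all(sites$site_id %in% colnames(matrix)),
              "matrix must cover all demand x site pairs")
  site_ids <- sort(sites$site_id)
  m <- matrix[demand_points$id, site_ids, drop = FALSE]
  cap <- stats::setNames(sites$capacity[match(site_ids, sites$site_id)],
                         site_ids)
  nearest_t <- apply(m, 1, min)
  ord <- order(nearest_t, demand_points$id)
  n <- nrow(demand_points)
  site_of <- rep(NA_character_, n)
  minutes <- rep(NA_real_, n)
  for (i in ord) {
    reach <- which(m[i, ] <= cutoff)
    if (!length(reach)) next
    reach <- reach[order(m[i, reach])]  # stable: ties keep site-id order
    w <- demand_points$weight[i]
    for (j in reach) {
      if (cap[j] >= w) {
        site_of[i] <- site_ids[j]
        minutes[i] <- m[i, j]
        cap[j] <- cap[j] - w
        break
      }
    }
  }
  loads <- stats::setNames(sites$capacity[match(site_ids, sites$site_id)],
                           site_ids) - cap
  list(assignment = data.frame(id = demand_points$id, site_id = site_of,
                               minutes = minutes, stringsAsFactors = FALSE),
       loads = loads,
       covered_demand = sum(demand_points$weight[!is.na(site_of)]))
}

#' Define a capacitated maximal-covering siting problem
#'
#' @param demand_points data.frame `id`, `weight`, optionally `county`
#' @param required_sites existing facilities (`site_id`, `capacity`), always
#'   open with fixed capacity
#' @param candidates candidate sites (`site_id`, `capacity`)
#' @param matrix drive-time matrix over all demand x (required + candidate)
#'   pairs
#' @param p number of candidates to open
#' @param cutoff drive-time cutoff in minutes (default 20)
#' @return object of class `allocation_problem`
#' @export
allocation_problem <- function(demand_points, required_sites, candidates,
                               matrix, p, cutoff = 20) {
  stop_if_not(p >= 1 && p <= nrow(candidates),
              "p must be between 1 and the number of candidates (%d)",
              nrow(candidates))
  stop_if_not(cutoff > 0, "cutoff must be positive")
  stop_if_not(!any(candidates$site_id %in% required_sites$site_id),
              "candidate ids must not collide with required site ids")
  structure(list(demand_points = demand_points,
                 required_sites = required_sites,
                 candidates = candidates, matrix = matrix,
                 p = as.integer(p), cutoff = cutoff),
            class = "allocation_problem")
}

coverage_of <- function(problem, open_ids) {
  sites <- rbind(
    problem$required_sites[, c("site_id", "capacity")],
    problem$candidates[problem$candidates$site_id %in% open_ids,
                       c("site_id", "capacity")]
  )
  assign_demand(sites, problem$demand_points, problem$matrix, problem$cutoff)
}

# Fast covered-demand evaluator over a fixed universe of sites. For every
# demand point the full site list is pre-sorted by (time, site id) once; an
# evaluation then just walks each point's list past inactive sites, stopping
# at the cutoff. Must replicate assign_demand()'s rules exactly (the final
# reported assignment still comes from assign_demand itself).
make_evaluator <- function(problem) {
  all_ids <- sort(c(problem$required_sites$site_id,
                    problem$candidates$site_id))
  dm <- problem$matrix[problem$demand_points$id, all_ids, drop = FALSE]
  caps_all <- unname(stats::setNames(
    c(problem$required_sites$capacity, problem$candidates$capacity),
    c(problem$required_sites$site_id, problem$candidates$site_id))[all_ids])
  w <- problem$demand_points$weight
  ids <- problem$demand_points$id
  req_idx <- match(sort(problem$required_sites$site_id), all_ids)
  cutoff <- problem$cutoff
  n <- nrow(dm)
  ns <- length(all_ids)
  site_order <- lapply(seq_len(n), function(i) {
    o <- order(dm[i, ])            # stable: ties stay in site-id order
    o[dm[i, o] <= cutoff]          # beyond the cutoff is never assignable
  })
  times_sorted <- lapply(seq_len(n), function(i) dm[i, site_order[[i]]])
  point_rank <- match(ids, sort(ids))  # processing tie-break on point id
  function(open_ids) {
    active <- logical(ns)
    active[req_idx] <- TRUE
    active[match(open_ids, all_ids)] <- TRUE
    nt <- vapply(seq_len(n), function(i) {
      so <- site_order[[i]]
      k <- which(active[so])
      if (length(k)) times_sorted[[i]][k[1]] else Inf
    }, numeric(1))
    cap <- caps_all
    covered <- 0
    for (i in seq_len(n)[order(nt, point_rank)]) {
      so <- site_order[[i]]
      wi <- w[i]
      for (k in seq_along(so)) {
        j <- so[k]
        if (active[j] && cap[j] >= wi) {
          cap[j] <- cap[j] - wi
          covered <- covered + wi
          break
        }
      }
    }
    covered
  }
}

#' Solve the capacitated maximal-covering location problem
#'
#' Deterministic multi-start greedy construction with pairwise interchange.
#' Each start forces one of the most promising candidates (ranked by
#' single-site coverage gain) as the first opened site; construction then
#' greedily opens whichever closed candidate maximizes covered demand, and
#' pairwise interchange swaps an opened (non-fixed) candidate for a closed
#' one whenever that strictly improves coverage, until no improving swap
#' remains. The best start wins; every tie-break is total-ordered (candidate
#' id, then lexicographically smallest opened set), so identical inputs give
#' identical solutions. A single greedy start can lodge in a local optimum
#' that only a double swap escapes; the multi-start makes the solver match
#' exhaustive enumeration on desk-scale instances (see the package tests).
#'
#' @param problem an [allocation_problem()]
#' @param fixed_open candidate ids forced open (used by [cumulative_siting()]
#'   to nest solutions); counted against `p`, exempt from interchange
#' @param restarts number of greedy starts (default 8); capped at the number
#'   of available candidates
#' @return object of class `allocation_result`: list with `opened`,
#'   `assignment`, `loads`, `covered_demand`, `baseline_covered_demand`,
#'   `mean_min_drive_before`, `mean_min_drive_after`, `drive_improvement`
#' @export
solve_cmclp <- function(problem, fixed_open = character(), restarts = 8L) {
  stop_if_not(inherits(problem, "allocation_problem"),
              "problem must be an allocation_problem")
  cand_ids <- sort(problem$candidates$site_id)
  stop_if_not(all(fixed_open %in% cand_ids), "fixed_open must be candidates")
  stop_if_not(length(fixed_open) <= problem$p, "more fixed sites than p")
  evaluate <- make_evaluator(problem)
  p <- problem$p

  construct <- function(open) {
    while (length(open) < p) {
      closed <- setdiff(cand_ids, open)
      cov <- vapply(closed, function(c_id) evaluate(c(open, c_id)), numeric(1))
      open <- c(open, closed[which.max(cov)])  # ties: first = smallest id
    }
    open
  }
  interchange <- function(open) {
    best <- evaluate(open)
    repeat {
      improved <- FALSE
      for (out_id in sort(setdiff(open, fixed_open))) {
        for (in_id in setdiff(cand_ids, open)) {
          trial <- c(setdiff(open, out_id), in_id)
          cov <- evaluate(trial)
          if (cov > best + 1e-9) {
            open <- trial
            best <- cov
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved) return(list(open = open, covered = best))
    }
  }

  if (length(fixed_open) >= p) {
    sol <- list(open = fixed_open, covered = evaluate(fixed_open))
  } else {
    closed0 <- setdiff(cand_ids, fixed_open)
    gain <- vapply(closed0, function(c_id) evaluate(c(fixed_open, c_id)),
                   numeric(1))
    starts <- closed0[order(-gain, closed0)][seq_len(min(restarts,
                                                         length(closed0)))]
    sol <- NULL
    for (first in starts) {
      cand_sol <- interchange(construct(c(fixed_open, first)))
      if (is.null(sol) || cand_sol$covered > sol$covered + 1e-9 ||
          (abs(cand_sol$covered - sol$covered) <= 1e-9 &&
             paste(sort(cand_sol$open), collapse = ",") <
               paste(sort(sol$open), collapse = ","))) {
        sol <- cand_sol
      }
    }
  }
  open <- sol$open
  final <- coverage_of(problem, open)
  baseline <- coverage_of(problem, character())
  imp <- drive_time_improvement(
    problem$required_sites$site_id,
    c(problem$required_sites$site_id, open),
    problem$demand_points, problem$matrix)
  structure(list(opened = open,
                 assignment = final$assignment, loads = final$loads,
                 covered_demand = final$covered_demand,
                 baseline_covered_demand = baseline$covered_demand,
                 mean_min_drive_before = imp$mean_before,
                 mean_min_drive_after = imp$mean_after,
                 drive_improvement = imp),
            class = "allocation_result")
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf(
    "<allocation_result> opened: %s | covered %.0f (baseline %.0f) | mean drive %.1f -> %.1f min (-%.1f%%)\n",
    paste(x$opened, collapse = ", "), x$covered_demand,
    x$baseline_covered_demand, x$mean_min_drive_before,
    x$mean_min_drive_after, x$drive_improvement$pct_reduction))
  invisible(x)
}

#' Cumulative siting for increasing numbers of new sites
#'
#' Solves the problem for each `p` in turn, forcing the sites chosen at
#' smaller `p` to stay open, so the solutions nest (the one-site solution is
#' contained in the three-site solution, and so on); interchange applies only
#' to the newly added sites.
#'
#' @param problem an [allocation_problem()]; its `p` field is overridden
#' @param p_values ascending site counts (default `c(1, 3, 5)`)
#' @return named list of [solve_cmclp()] results, one per `p`
#' @export
cumulative_siting <- function(problem, p_values = c(1, 3, 5)) {
  stop_if_not(all(diff(p_values) > 0), "p_values must be ascending")
  stop_if_not(max(p_values) <= nrow(problem$candidates),
              "largest p exceeds candidate count")
  out <- list()
  fixed <- character()
  for (p in p_values) {
    problem$p <- as.integer(p)
    res <- solve_cmclp(problem, fixed_open = fixed)
    fixed <- res$opened
    out[[paste0("p", p)]] <- res
  }
  out
}

#' Demand-weighted drive-time improvement
#'
#' Compares the demand-weighted mean of each point's minimum drive time over
#' the `before` sites against the same mean over the `after` sites (a
#' superset, so the reduction is never negative). Points unreachable from
#' every `before` site are excluded from both means.
#'
#' @param before_sites,after_sites character vectors of site ids (columns of
#'   `matrix`); `after_sites` must contain `before_sites`
#' @param demand_points data.frame `id`, `weight`, optionally `county`
#' @param matrix drive-time matrix
#' @return list: `mean_before`, `mean_after`, `pct_reduction`, and
#'   `by_county` (data.frame) when a `county` column is present
#' @export
drive_time_improvement <- function(before_sites, after_sites, demand_points,
                                   matrix) {
  stop_if_not(all(before_sites %in% after_sites),
              "after_sites must contain all before_sites")
  tb <- apply(matrix[demand_points$id, before_sites, drop = FALSE], 1, min)
  ta <- apply(matrix[demand_points$id, after_sites, drop = FALSE], 1, min)
  w <- demand_points$weight
  ok <- is.finite(tb)
  wmean <- function(t, keep) {
    if (sum(w[keep]) == 0) return(0)
    sum(t[keep] * w[keep]) / sum(w[keep])
  }
  pct <- function(b, a) if (b <= 0) 0 else 100 * (b - a) / b
  mb <- wmean(tb, ok)
  ma <- wmean(ta, ok)
  out <- list(mean_before = mb, mean_after = ma,
              pct_reduction = pct(mb, ma))
  if (!is.null(demand_points$county)) {
    out$by_county <- do.call(rbind, lapply(
      sort(unique(demand_points$county)), function(co) {
        keep <- ok & demand_points$county == co
        b <- wmean(tb, keep); a <- wmean(ta, keep)
        data.frame(county = co, mean_before = b, mean_after = a,
                   pct_reduction = pct(b, a), stringsAsFactors = FALSE)
      }))
  }
  out
}

#' BICOE-conversion siting
#'
#' Which existing non-BICOE facilities should be converted to BICOE status?
#' The BICOE sites (with their capacities) are the required, always-open
#' locations; every non-BICOE facility is a candidate at its actual location
#' and — by default — its actual unit capacity. The same capacitated
#' maximal-covering problem is then solved, by default for five conversions
#' under the USPSTF demand specification.
#'
#' @param facilities facility data.frame (`facility_id`, `bicoe`, `capacity`,
#'   `units`)
#' @param demand_points data.frame `id`, `weight`, optionally `county`
#' @param matrix drive-time matrix over demand x facility pairs
#' @param p number of conversions (default 5)
#' @param cutoff drive-time cutoff in minutes (default 20)
#' @param single_unit if `TRUE`, candidate capacity is reset to one unit's
#'   worth, as assumed for newly built sites
#' @param model a [capacity_model()] (used when `single_unit = TRUE`)
#' @return an `allocation_result` (see [solve_cmclp()])
#' @export
bicoe_conversion <- function(facilities, demand_points, matrix, p = 5,
                             cutoff = 20, single_unit = FALSE,
                             model = capacity_model()) {
  req <- facilities[facilities$bicoe, ]
  cand <- facilities[!facilities$bicoe, ]
  stop_if_not(nrow(req) >= 1, "at least one BICOE site is required")
  stop_if_not(nrow(cand) >= p,
              "fewer non-BICOE sites (%d) than conversions requested (%d)",
              nrow(cand), p)
  cand_cap <- if (single_unit) facility_capacity(1, model) else cand$capacity
  problem <- allocation_problem(
    demand_points,
    required_sites = data.frame(site_id = req$facility_id,
                                capacity = req$capacity,
                                stringsAsFactors = FALSE),
    candidates = data.frame(site_id = cand$facility_id,
                            capacity = cand_cap, stringsAsFactors = FALSE),
    matrix = matrix, p = p, cutoff = cutoff)
  solve_cmclp(problem)
}
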