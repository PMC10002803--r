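#' Facility inventory summary with percentage shares
#'
#' Counts facilities, units, BICOE facilities, BICOE units and population by
#' county and statewide, with each county's percentage of the state rounded
#' half-up to integers — the granularity used in published inventory tables,
#' so printed shares are reproduced exactly from printed counts.
#'
#' @param tracts tract data.frame (`county`, `population`)
#' @param facilities facility data.frame (`county`, `units`, `bicoe`)
#' @return data.frame: `county`, `measure`, `count`, `pct_of_state`
#' @export
inventory_summary <- function(tracts, facilities) {
  measures <- function(t_rows, f_rows) c(
    population = sum(t_rows$population),
    facilities = nrow(f_rows),
    units = sum(f_rows$units),
    bicoe_facilities = sum(f_rows$bicoe),
    bicoe_units = sum(f_rows$units[f_rows$bicoe])
  )
  state <- measures(tracts, facilities)
  counties <- sort(unique(c(tracts$county, facilities$county)))
  rows <- lapply(c(counties, "statewide"), function(co) {
    m <- if (co == "statewide") state else
      measures(tracts[tracts$county == co, , drop = FALSE],
               facilities[facilities$county == co, , drop = FALSE])
    data.frame(county = co, measure = names(m), count = unname(m),
               pct_of_state = round_half_up(100 * unname(m) / unname(state[names(m)])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Drive-time matrix for a scenario
#'
#' @param scenario an `equiscreen_scenario`
#' @param candidates optional candidate data.frame (`candidate_id`,
#'   `node_id`) appended as extra destinations
#' @return tract x site minutes matrix (see [travel_matrix()])
#' @export
scenario_travel_matrix <- function(scenario, candidates = NULL) {
  dest <- stats::setNames(scenario$facilities$node_id,
                          scenario$facilities$facility_id)
  if (!is.null(candidates)) {
    dest <- c(dest, stats::setNames(candidates$node_id,
                                    candidates$candidate_id))
  }
  travel_matrix(scenario$network,
                stats::setNames(scenario$tracts$node_id,
                                scenario$tracts$tract_id),
                dest)
}

#' Demand points for a scenario under one specification
#'
#' @param scenario an `equiscreen_scenario`
#' @param spec demand specification name (see [screening_demand()])
#' @return data.frame `id`, `weight`, `county` usable by the allocator
#' @export
scenario_demand_points <- function(scenario, spec = "uspstf") {
  d <- screening_demand(scenario$tracts, spec)
  data.frame(id = d$tract_id, weight = d$annual_screenings,
             county = scenario$tracts$county, stringsAsFactors = FALSE)
}

#' Fishnet candidates for a scenario
#'
#' Grids each county's bounding box separately (so cell centers stay inside
#' the study area), snaps to the road network and merges duplicates. The
#' default cell size targets roughly ten candidates per existing facility.
#'
#' @param scenario an `equiscreen_scenario`
#' @param cell_km grid cell size; default 5 km
#' @return candidate data.frame (see [fishnet_candidates()])
#' @export
scenario_candidates <- function(scenario, cell_km = 5) {
  model <- capacity_model(scenario$config$facilities$per_unit_annual)
  parts <- lapply(scenario$config$network, function(np) {
    fishnet_candidates(np$box, cell_km, scenario$network, model = model)
  })
  all <- do.call(rbind, parts)
  all <- all[!duplicated(all$node_id), ]
  all$candidate_id <- sprintf("c%03d", seq_len(nrow(all)))
  rownames(all) <- NULL
  all
}

#' Per-tract facility counts for the rate models
#'
#' Attributes each facility to the tract whose population-weighted centroid
#' is nearest (Euclidean), then tallies facilities, units, BICOE facilities
#' and BICOE units per tract.
#'
#' @param scenario an `equiscreen_scenario`
#' @return list of four count vectors aligned with `scenario$tracts`
#' @export
facility_tract_counts <- function(scenario) {
  tr <- scenario$tracts
  fc <- scenario$facilities
  nearest <- vapply(seq_len(nrow(fc)), function(i) {
    which.min((tr$centroid_x - fc$x[i])^2 + (tr$centroid_y - fc$y[i])^2)
  }, integer(1))
  tally <- function(vals) {
    out <- numeric(nrow(tr))
    agg <- tapply(vals, nearest, sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  list(facilities = tally(rep(1, nrow(fc))),
       units = tally(fc$units),
       bicoe_facilities = tally(as.numeric(fc$bicoe)),
       bicoe_units = tally(fc$units * fc$bicoe))
}

#' Pipeline run configuration
#'
#' @param scenario a [scenario_config()]
#' @param specs demand specifications to run (subset of uspstf/race/acr)
#' @param bands catchment thresholds in minutes
#' @param cutoff allocation drive-time cutoff in minutes
#' @param p_values numbers of new sites to add, ascending
#' @param cell_km fishnet cell size in km
#' @param out_dir output directory (created if missing)
#' @return object of class `run_config`
#' @export
run_config <- function(scenario = scenario_config(), specs = c("uspstf", "race", "acr"),
                       bands = c(15, 30), cutoff = 20, p_values = c(1, 3, 5),
                       cell_km = 5, out_dir = tempfile("equiscreen_run_")) {
  stop_if_not(inherits(scenario, "scenario_config"),
              "scenario must be a scenario_config()")
  stop_if_not(all(specs %in% c("uspstf", "race", "acr")),
              "unknown demand specification")
  structure(list(scenario = scenario, specs = specs, bands = bands,
                 cutoff = cutoff, p_values = p_values, cell_km = cell_km,
                 out_dir = out_dir),
            class = "run_config")
}

write_csv_q <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' simulate -> catchment -> demand -> regression -> allocation -> report,
#' writing every stage's output as CSV/JSON under `config$out_dir` plus a
#' manifest recording the seed, a digest of the configuration, and the
#' package version. Re-running an identical configuration reproduces
#' identical file content.
#'
#' @param config a [run_config()]
#' @return (invisibly) the output directory path
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "run_config"), "config must be a run_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  scen <- stage("simulate", {
    s <- generate_scenario(config$scenario)
    write_csv_q(s$tracts, out("tracts.csv"))
    write_csv_q(s$blocks, out("blocks.csv"))
    write_csv_q(s$facilities, out("facilities.csv"))
    write_csv_q(s$network$nodes, out("network_nodes.csv"))
    write_csv_q(s$network$edges, out("network_edges.csv"))
    s
  })

  tm <- stage("catchment", {
    tm <- scenario_travel_matrix(scen)
    long <- data.frame(origin = rep(rownames(tm), ncol(tm)),
                       destination = rep(colnames(tm), each = nrow(tm)),
                       minutes = as.vector(tm))
    write_csv_q(long, out("travel_matrix.csv"))
    cls <- classify_catchment(tm, config$bands)
    write_csv_q(cls, out("catchment.csv"))
    write_csv_q(catchment_summary(cls, scen$tracts), out("catchment_summary.csv"))
    tm
  })

  stage("demand", {
    dem <- do.call(rbind, lapply(config$specs, function(sp)
      screening_demand(scen$tracts, sp)))
    write_csv_q(dem, out("demand.csv"))
  })

  stage("regress", {
    counts <- facility_tract_counts(scen)
    write_csv_q(stratified_fits(scen$tracts, counts), out("regression.csv"))
  })

  alloc <- stage("allocate", {
    cands <- scenario_candidates(scen, config$cell_km)
    tmc <- scenario_travel_matrix(scen, cands)
    req <- data.frame(site_id = scen$facilities$facility_id,
                      capacity = scen$facilities$capacity,
                      stringsAsFactors = FALSE)
    cand <- data.frame(site_id = cands$candidate_id,
                       capacity = cands$capacity, stringsAsFactors = FALSE)
    rows <- list()
    for (sp in config$specs) {
      dp <- scenario_demand_points(scen, sp)
      prob <- allocation_problem(dp, req, cand, tmc,
                                 p = max(config$p_values),
                                 cutoff = config$cutoff)
      res <- cumulative_siting(prob, config$p_values)
      for (pn in names(res)) {
        r <- res[[pn]]
        rows[[paste(sp, pn)]] <- data.frame(
          spec = sp, p = as.integer(sub("^p", "", pn)),
          opened = paste(sort(r$opened), collapse = ";"),
          covered_demand = r$covered_demand,
          baseline_covered_demand = r$baseline_covered_demand,
          mean_min_drive_before = r$mean_min_drive_before,
          mean_min_drive_after = r$mean_min_drive_after,
          pct_drive_reduction = r$drive_improvement$pct_reduction,
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    write_csv_q(tab, out("allocation.csv"))
    tab
  })

  stage("report", {
    write_csv_q(inventory_summary(scen$tracts, scen$facilities),
                out("inventory.csv"))
  })

  stage("manifest", {
    cfg <- unclass_deep(config)
    cfg$out_dir <- NULL   # keep manifests identical across output locations
    cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
    cfg_path <- out("config.json")
    writeLines(cfg_json, cfg_path)
    manifest <- list(
      seed = config$scenario$seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      package_version = as.character(utils::packageVersion("equiscreen")),
      outputs = sort(list.files(config$out_dir)))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               out("manifest.json"))
  })

  invisible(config$out_dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, unclass_deep)
  }
  x
}
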