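#' Travel time along a single road edge
#'
#' @param length_km edge length in kilometres (> 0)
#' @param speed_kmh free-flow speed in km/h (> 0)
#' @return travel time in minutes, `60 * length_km / speed_kmh`
#' @export
edge_minutes <- function(length_km, speed_kmh) {
  stop_if_not(is.numeric(length_km) && all(length_km > 0),
              "length_km must be positive")
  stop_if_not(is.numeric(speed_kmh) && all(speed_kmh > 0),
              "speed_kmh must be positive")
  60 * length_km / speed_kmh
}

network_graph <- function(network) {
  edges <- network$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$node_a),
               to = as.character(edges$node_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes$node_id))
  )
  igraph::E(g)$weight <- edge_minutes(edges$length_km, edges$speed_kmh)
  g
}

#' Drive-time matrix between demand points and sites
#'
#' Exact shortest-path travel times, in minutes, over the undirected road
#' network with each edge weighted by [edge_minutes()]. Unreachable pairs are
#' `Inf`.
#'
#' @param network a road network: list with `nodes` (`node_id`, `x`, `y`) and
#'   `edges` (`node_a`, `node_b`, `length_km`, `speed_kmh`)
#' @param origins named character/integer vector: origin id -> network node id
#' @param destinations named vector: destination id -> network node id
#' @return numeric matrix (origins x destinations) with dimnames set to the
#'   origin and destination ids
#' @export
travel_matrix <- function(network, origins, destinations) {
  stop_if_not(length(origins) > 0, "no origins supplied")
  stop_if_not(length(destinations) > 0, "no destinations supplied")
  stop_if_not(!is.null(names(origins)) && !is.null(names(destinations)),
              "origins and destinations must be named by their ids")
  g <- network_graph(network)
  # several points may snap to one node; igraph wants unique vertex lists
  o_nodes <- unique(as.character(origins))
  d_nodes <- unique(as.character(destinations))
  d <- igraph::distances(g, v = o_nodes, to = d_nodes,
                         algorithm = "dijkstra")
  out <- d[match(as.character(origins), o_nodes),
           match(as.character(destinations), d_nodes), drop = FALSE]
  dimnames(out) <- list(names(origins), names(destinations))
  out
}

#' Classify tracts into drive-time catchment bands
#'
#' Each tract is banded by its minimum drive time t* across all sites:
#' `t* <= bands[1]` is `within_15`, `bands[1] < t* <= bands[2]` is
#' `within_30`, and anything beyond (including unreachable) is `over_30`.
#' Intervals are closed on the right, so a tract exactly at the threshold
#' still counts as "within". The nearest site is reported with ties broken by
#' the lexicographically smallest site id.
#'
#' @param matrix travel matrix from [travel_matrix()]
#' @param bands two ascending thresholds in minutes (default `c(15, 30)`)
#' @return data.frame: `tract_id`, `band`, `min_minutes`, `nearest_site`
#' @export
classify_catchment <- function(matrix, bands = c(15, 30)) {
  stop_if_not(ncol(matrix) >= 1, "matrix must have at least one destination")
  stop_if_not(length(bands) == 2 && bands[1] < bands[2],
              "bands must be two ascending thresholds")
  site_order <- order(colnames(matrix))
  m <- matrix[, site_order, drop = FALSE]
  t_star <- apply(m, 1, min)
  nearest <- colnames(m)[apply(m, 1, which.min)]  # first min = smallest id
  nearest[!is.finite(t_star)] <- NA_character_
  band <- ifelse(t_star <= bands[1], "within_15",
          ifelse(t_star <= bands[2], "within_30", "over_30"))
  data.frame(tract_id = rownames(matrix), band = band,
             min_minutes = unname(t_star), nearest_site = nearest,
             stringsAsFactors = FALSE)
}

#' Per-county catchment band percentages
#'
#' @param classification output of [classify_catchment()]
#' @param tracts tract data.frame with `tract_id` and `county`
#' @return data.frame with one row per county (plus `statewide`) and the
#'   percentage of tracts in each band; percentages sum to 100 per row
#' @export
catchment_summary <- function(classification, tracts) {
  stop_if_not(all(tracts$tract_id %in% classification$tract_id),
              "every tract must be classified")
  band_levels <- c("within_15", "within_30", "over_30")
  cls <- merge(classification, tracts[, c("tract_id", "county")],
               by = "tract_id")
  one <- function(df, label) {
    counts <- table(factor(df$band, levels = band_levels))
    pct <- 100 * as.numeric(counts) / nrow(df)
    out <- data.frame(county = label, n_tracts = nrow(df))
    out[paste0("pct_", band_levels)] <- as.list(pct)
    out
  }
  counties <- sort(unique(cls$county))
  do.call(rbind, c(
    lapply(counties, function(co) one(cls[cls$county == co, ], co)),
    list(one(cls, "statewide"))
  ))
}
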