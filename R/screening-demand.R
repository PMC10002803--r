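#' Screening-guideline demand specifications
#'
#' Convert tract demographics into the number of screening mammograms owed
#' per year under three competing guideline readings:
#'
#' * `uspstf` — biennial screening for women aged 50-74; at steady state half
#'   the eligible population is screened each year, so demand is
#'   `women_50_74 / 2`.
#' * `race` — the USPSTF schedule plus biennial screening of Black women
#'   starting at age 40. Black women aged 40-49 are estimated by applying the
#'   tract-level fraction of Black women to the 40-49 band (no age-by-race
#'   cross-tabulation is assumed), adding
#'   `pct_black_women * women_40_49 / 2`.
#' * `acr` — annual screening for all women 40 and older, with no upper age
#'   bound: `women_40_49 + women_50_74 + women_over_74`.
#'
#' Demand is real-valued; rounding is left to report time so the allocator
#' sees no order-dependent rounding artifacts. For every tract
#' `demand_uspstf <= demand_race_based <= demand_acr`, since the Black
#' fraction is at most 1 and biennial screening halves an annual schedule.
#'
#' @param tracts data.frame with columns `women_40_49`, `women_50_74`,
#'   `women_over_74`, `pct_black_women` (fraction in \[0,1\])
#' @return numeric vector of annual screenings, one per tract row
#' @name screening_demand
NULL

#' @rdname screening_demand
#' @export
demand_uspstf <- function(tracts) {
  check_demand_cols(tracts, "women_50_74")
  tracts$women_50_74 / 2
}

#' @rdname screening_demand
#' @export
demand_race_based <- function(tracts) {
  check_demand_cols(tracts, c("women_50_74", "women_40_49", "pct_black_women"))
  stop_if_not(all(tracts$pct_black_women >= 0 & tracts$pct_black_women <= 1),
              "pct_black_women must be a fraction in [0, 1]")
  demand_uspstf(tracts) + tracts$pct_black_women * tracts$women_40_49 / 2
}

#' @rdname screening_demand
#' @export
demand_acr <- function(tracts) {
  check_demand_cols(tracts, c("women_40_49", "women_50_74", "women_over_74"))
  tracts$women_40_49 + tracts$women_50_74 + tracts$women_over_74
}

check_demand_cols <- function(tracts, cols) {
  missing <- setdiff(cols, names(tracts))
  stop_if_not(length(missing) == 0, "tracts is missing column(s): %s",
              paste(missing, collapse = ", "))
  for (col in cols) {
    stop_if_not(is_count(tracts[[col]]),
                "column '%s' must be non-negative and finite", col)
  }
}

#' Per-tract demand under a named specification
#'
#' @param tracts tract data.frame (see [demand_uspstf()])
#' @param spec one of `"uspstf"`, `"race"`, `"acr"`
#' @return data.frame with `tract_id`, `spec`, `annual_screenings`
#' @export
screening_demand <- function(tracts, spec = c("uspstf", "race", "acr")) {
  spec <- match.arg(spec)
  screenings <- switch(spec,
    uspstf = demand_uspstf(tracts),
    race   = demand_race_based(tracts),
    acr    = demand_acr(tracts)
  )
  data.frame(tract_id = tracts$tract_id, spec = spec,
             annual_screenings = screenings, stringsAsFactors = FALSE)
}

#' Capacity model for mammography units
#'
#' A single mammography unit performs at most 3 screenings per business hour,
#' which works out to roughly 4,500 screenings per year; a site's capacity is
#' its unit count times the per-unit constant.
#'
#' @param per_unit_annual screenings per unit per year (default 4500)
#' @param per_hour documentation constant: screenings per unit per business
#'   hour (default 3, not used in arithmetic)
#' @return object of class `capacity_model`
#' @export
capacity_model <- function(per_unit_annual = 4500, per_hour = 3) {
  stop_if_not(is.numeric(per_unit_annual) && per_unit_annual > 0,
              "per_unit_annual must be positive")
  structure(list(per_unit_annual = per_unit_annual, per_hour = per_hour),
            class = "capacity_model")
}

#' Annual screening capacity of a facility
#'
#' @param units number of active mammography units (>= 1)
#' @param model a [capacity_model()]
#' @return screenings per year, vectorized over `units`
#' @export
facility_capacity <- function(units, model = capacity_model()) {
  stop_if_not(is.numeric(units) && all(units >= 1),
              "a facility must have at least one unit")
  units * model$per_unit_annual
}
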