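#' Canonical covariate order for the rate models
#'
#' @return character vector of tract covariate names, in the fixed order used
#'   throughout the package
#' @export
rate_model_covariates <- function() {
  c("deprivation", "women_40_49", "women_50_74", "women_over_74",
    "pct_black_women", "pct_vehicle", "bus_stops")
}

#' Standardize a covariate column
#'
#' Centers and scales by the sample standard deviation (n-1 denominator).
#'
#' @param x numeric vector
#' @param name covariate name, used in error messages
#' @return list with `z` (standardized column), `mean`, `sd`
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  stop_if_not(is.numeric(x) && all(is.finite(x)),
              "covariate '%s' must be finite numeric", name)
  s <- stats::sd(x)
  stop_if_not(is.finite(s) && s > 0,
              "covariate '%s' is constant and cannot be standardized", name)
  list(z = (x - mean(x)) / s, mean = mean(x), sd = s)
}

#' Poisson rate model of facility counts with a population offset
#'
#' Fits `counts ~ Z + offset(log(population))` by Poisson maximum likelihood,
#' where `Z` holds the covariates standardized within the fitted data. The
#' exponentiated coefficients are rate ratios per standard-deviation change,
#' with 95% Wald confidence intervals computed on the log scale and then
#' exponentiated.
#'
#' @param tracts tract data.frame with the seven canonical covariates and
#'   `population` (> 0 for every row)
#' @param counts non-negative integer outcome per tract (facilities, units,
#'   BICOE facilities, or BICOE units)
#' @param covariates covariate names (default [rate_model_covariates()])
#' @return object of class `rate_model_result`: data.frame with one row per
#'   covariate (`rate_ratio`, `ci_low`, `ci_high`, `std_mean`, `std_sd`),
#'   plus attributes `intercept`, `converged`
#' @export
fit_rate_model <- function(tracts, counts,
                           covariates = rate_model_covariates()) {
  stop_if_not(all(tracts$population > 0), "all tracts must be populated")
  stop_if_not(length(counts) == nrow(tracts),
              "counts must align with tracts (one per row)")
  stop_if_not(all(counts >= 0), "counts must be non-negative")
  std <- lapply(covariates, function(v) standardize(tracts[[v]], name = v))
  Z <- do.call(cbind, lapply(std, `[[`, "z"))
  colnames(Z) <- covariates
  dat <- data.frame(.counts = counts, Z, check.names = FALSE)
  fit <- stats::glm(
    stats::reformulate(sprintf("`%s`", covariates), response = ".counts"),
    family = stats::poisson(), data = dat,
    offset = log(tracts$population))
  if (!fit$converged) {
    stop("Poisson rate model did not converge", call. = FALSE)
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(se)) || any(se > 50)) {
    stop("degenerate fit (separation-like geometry): standard errors unstable",
         call. = FALSE)
  }
  z975 <- stats::qnorm(0.975)
  idx <- seq_along(covariates) + 1L
  out <- data.frame(
    covariate = covariates,
    rate_ratio = exp(est[idx]),
    ci_low = exp(est[idx] - z975 * se[idx]),
    ci_high = exp(est[idx] + z975 * se[idx]),
    std_mean = vapply(std, function(s) s$mean, numeric(1)),
    std_sd = vapply(std, function(s) s$sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("rate_model_result", "data.frame"),
            intercept = unname(est[1]), converged = fit$converged)
}

#' Rate models per outcome and county stratum
#'
#' Fits each outcome statewide and within each county stratum, standardizing
#' covariates within the fitted stratum. A stratum model is suppressed
#' (flagged `unavailable`) when the stratum's outcome total falls below
#' `min_events`, mirroring how sparse-outcome county models are withheld
#' rather than reported with unstable estimates.
#'
#' @param tracts tract data.frame with `county`, covariates, `population`
#' @param counts named list of outcome count vectors (e.g. `facilities`,
#'   `units`, `bicoe_facilities`, `bicoe_units`), each aligned with `tracts`
#' @param min_events minimum outcome total for a stratum fit (default 5)
#' @return data.frame with columns `outcome`, `stratum`, `covariate`,
#'   `rate_ratio`, `ci_low`, `ci_high`, `flag` (`ok` or `unavailable`)
#' @export
stratified_fits <- function(tracts, counts, min_events = 5) {
  strata <- c("statewide", sort(unique(tracts$county)))
  rows <- list()
  for (outcome in names(counts)) {
    y <- counts[[outcome]]
    for (st in strata) {
      keep <- if (st == "statewide") rep(TRUE, nrow(tracts)) else
        tracts$county == st
      suppressed <- function(flag) data.frame(
        outcome = outcome, stratum = st, covariate = NA_character_,
        rate_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        flag = flag, stringsAsFactors = FALSE)
      if (sum(y[keep]) < min_events) {
        rows[[length(rows) + 1L]] <- suppressed("unavailable")
        next
      }
      # convergence is checked explicitly inside fit_rate_model, so glm's
      # running commentary is redundant here
      res <- tryCatch(suppressWarnings(fit_rate_model(tracts[keep, ], y[keep])),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(res)) {
        # non-convergence / separation-like geometry: report, don't estimate
        suppressed("degenerate")
      } else {
        data.frame(
          outcome = outcome, stratum = st, covariate = res$covariate,
          rate_ratio = res$rate_ratio, ci_low = res$ci_low,
          ci_high = res$ci_high, flag = "ok", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
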