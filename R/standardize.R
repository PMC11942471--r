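# Z-score standardization, relative fertility changes and the
# longitudinal / aggregated segmentation of the indicator panel.

#' Z-score standardization
#'
#' Centers and scales by the population standard deviation (divide by N, not
#' N - 1). Missing values are excluded from the mean and sd and propagate as
#' missing in the output. A constant vector (sd 0) returns all zeros with a
#' degeneracy warning so that downstream aggregation treats the indicator as
#' uninformative rather than crashing.
#'
#' @param x Numeric vector with at least 2 non-missing values.
#' @return Numeric vector of the same length with attributes `mu` and `sigma`.
#' @examples
#' z <- zscore(c(1, 2, 3))
#' attr(z, "mu"); attr(z, "sigma")
#' @export
zscore <- function(x) {
  obs <- !is.na(x)
  if (sum(obs) < 2) {
    abort("zscore needs at least 2 non-missing values",
          class = "effindex_value_error")
  }
  mu <- mean(x[obs])
  sigma <- sqrt(mean((x[obs] - mu)^2))
  if (sigma == 0) {
    warn("zscore: constant input (sigma = 0); returning zeros")
    z <- ifelse(obs, 0, NA_real_)
  } else {
    z <- (x - mu) / sigma
  }
  attr(z, "mu") <- mu
  attr(z, "sigma") <- sigma
  z
}

#' Standardize an indicator panel
#'
#' Applies [zscore()] to each indicator column. The default pool is all
#' department-years per indicator (one transformation per indicator, keeping
#' the longitudinal dataset on a single scale); `pool = "within_year"` is
#' available for sensitivity analysis.
#'
#' @param indicators Indicator panel from [compute_indicators()] (or any
#'   tibble with `department`, `year` and numeric columns).
#' @param columns Columns to standardize; default all indicator columns.
#' @param pool `"all"` (default) or `"within_year"`.
#' @return List with `data` (standardized tibble) and `params` (tibble
#'   `indicator`, `pool`, `mu`, `sigma`).
#' @export
standardize_panel <- function(indicators, columns = NULL,
                              pool = c("all", "within_year")) {
  pool <- match.arg(pool)
  if (is.null(columns)) {
    columns <- setdiff(names(indicators), c("department", "year"))
  }
  data <- indicators[, c("department", "year", columns)]
  params <- NULL
  for (col in columns) {
    if (pool == "all") {
      z <- zscore(data[[col]])
      data[[col]] <- as.numeric(z)
      params <- rbind(params, tibble::tibble(
        indicator = col, pool = "all", year = NA_integer_,
        mu = attr(z, "mu"), sigma = attr(z, "sigma")))
    } else {
      for (yr in sort(unique(data$year))) {
        sel <- data$year == yr
        z <- zscore(data[[col]][sel])
        data[[col]][sel] <- as.numeric(z)
        params <- rbind(params, tibble::tibble(
          indicator = col, pool = "within_year", year = yr,
          mu = attr(z, "mu"), sigma = attr(z, "sigma")))
      }
    }
  }
  list(data = data, params = params)
}

#' Relative change of an indicator between two years
#'
#' Per-department relative percent change
#' `(value_to - value_from) / value_from * 100`. A zero baseline makes the
#' change undefined: the department gets a missing value and a warning names
#' the exclusion.
#'
#' @param indicators Indicator panel.
#' @param indicator Indicator column name (e.g. `"EFR"`).
#' @param from_year,to_year The year pair (baseline, comparison).
#' @return Tibble `department`, `delta`.
#' @export
relative_change <- function(indicators, indicator, from_year, to_year) {
  yrs <- unique(indicators$year)
  if (!all(c(from_year, to_year) %in% yrs)) {
    abort(sprintf("year pair (%d, %d) outside the panel years (%s)",
                  from_year, to_year, paste(sort(yrs), collapse = ", ")),
          class = "effindex_range_error")
  }
  wide <- tidyr::pivot_wider(
    indicators[indicators$year %in% c(from_year, to_year),
               c("department", "year", indicator)],
    names_from = "year", values_from = dplyr::all_of(indicator))
  base <- wide[[as.character(from_year)]]
  cur <- wide[[as.character(to_year)]]
  delta <- (cur - base) / base * 100
  zero_base <- !is.na(base) & base == 0
  if (any(zero_base)) {
    warn(sprintf("relative_change(%s): zero baseline in %d→%d for %s; set to missing",
                 indicator, from_year, to_year,
                 paste(wide$department[zero_base], collapse = ", ")))
    delta[zero_base] <- NA_real_
  }
  tibble::tibble(department = wide$department, delta = delta)
}

#' Fertility-change outcomes
#'
#' Relative changes of IFR, AFR and EFR over the configured year pair
#' (default 2020 to 2021, the pandemic-conception to maternity transition),
#' plus their Z-score standardized versions across departments.
#'
#' @param indicators Indicator panel.
#' @param from_year,to_year Year pair, defaults 2020 and 2021.
#' @return Tibble `department`, `dIFR`, `dAFR`, `dEFR`, `z_dIFR`, `z_dAFR`,
#'   `z_dEFR`.
#' @export
delta_outcomes <- function(indicators, from_year = 2020, to_year = 2021) {
  out <- tibble::tibble(department = unique(indicators$department))
  for (ind in c("IFR", "AFR", "EFR")) {
    d <- relative_change(indicators, ind, from_year, to_year)
    names(d)[2] <- paste0("d", ind)
    out <- dplyr::left_join(out, d, by = "department")
    out[[paste0("z_d", ind)]] <- as.numeric(zscore(out[[paste0("d", ind)]]))
  }
  out
}

#' Segment the indicator panel into predictor and outcome datasets
#'
#' Builds the two datasets the index model consumes:
#' * `longitudinal` — all department-years of the standardized risk
#'   indicators, fertility rates excluded by construction (they define the
#'   outcome);
#' * `aggregated` — one row per department: the standardized risk indicators
#'   averaged over the index window (default 2019-2021), joined with the
#'   fertility-change outcomes of [delta_outcomes()].
#'
#' @param indicators Indicator panel from [compute_indicators()].
#' @param predictors Risk indicators to carry; default
#'   `c("PIW", "PMW", "PSW", "DVAW", "DVAC", "CHR", "SR")`.
#' @param effi_window Years averaged into the aggregated predictors.
#' @param delta_years Length-2 year pair for the outcome changes.
#' @param pool Standardization pool, see [standardize_panel()].
#' @return An `effindex_segments` list: `longitudinal`, `aggregated`,
#'   `params`, `predictors`, `effi_window`, `delta_years`.
#' @export
segment_panel <- function(indicators, predictors = default_predictors,
                          effi_window = 2019:2021, delta_years = c(2020, 2021),
                          pool = c("all", "within_year")) {
  pool <- match.arg(pool)
  fert <- c("IFR", "AFR", "EFR")
  predictors <- setdiff(predictors, fert)
  missing_pred <- setdiff(predictors, names(indicators))
  if (length(missing_pred) > 0) {
    abort(sprintf("predictor(s) absent from the panel: %s",
                  paste(missing_pred, collapse = ", ")),
          class = "effindex_config_error")
  }
  yrs <- unique(indicators$year)
  if (!all(effi_window %in% yrs) || !all(delta_years %in% yrs)) {
    abort("index window or delta year pair outside the panel years",
          class = "effindex_range_error")
  }

  # outcome coverage: the delta pair must be computable for most departments
  base <- indicators[indicators$year == delta_years[1], c("department", "EFR")]
  n_dep <- length(unique(indicators$department))
  n_ok <- sum(!is.na(base$EFR) & base$EFR != 0)
  if (n_ok < n_dep / 2) {
    abort(sprintf("delta year pair %d→%d unavailable for more than half the departments (%d/%d usable)",
                  delta_years[1], delta_years[2], n_ok, n_dep),
          class = "effindex_coverage_error")
  }

  std <- standardize_panel(indicators, columns = predictors, pool = pool)
  longitudinal <- std$data

  agg <- dplyr::summarise(
    dplyr::group_by(longitudinal[longitudinal$year %in% effi_window, ],
                    .data$department),
    dplyr::across(dplyr::all_of(predictors), ~ mean(.x, na.rm = FALSE)),
    .groups = "drop")
  deltas <- delta_outcomes(indicators, delta_years[1], delta_years[2])
  aggregated <- dplyr::left_join(agg, deltas, by = "department")

  structure(list(longitudinal = longitudinal, aggregated = aggregated,
                 params = std$params, predictors = predictors,
                 effi_window = effi_window, delta_years = delta_years),
            class = "effindex_segments")
}

#' @export
print.effindex_segments <- function(x, ...) {
  cat(sprintf("<effindex_segments> longitudinal %d rows, aggregated %d departments\n",
              nrow(x$longitudinal), nrow(x$aggregated)))
  cat(sprintf("  predictors: %s\n", paste(x$predictors, collapse = ", ")))
  cat(sprintf("  index window %s-%s, delta %d→%d\n", min(x$effi_window),
              max(x$effi_window), x$delta_years[1], x$delta_years[2]))
  invisible(x)
}
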