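# Ten department-year indicators from harmonized counts.
#
# All are ratio indicators with the affiliated-women register, the violence
# register or the death register as denominator; a zero denominator yields a
# missing value (never a silent 0), and a subgroup count exceeding its total
# is a data-consistency error.

check_subset <- function(counts, subgroup, total, label) {
  bad <- which(!is.na(counts[[subgroup]]) & !is.na(counts[[total]]) &
                 counts[[subgroup]] > counts[[total]])
  if (length(bad) > 0) {
    abort(sprintf("data consistency: %s > %s for (%s, %d)", subgroup, total,
                  counts$department[bad[1]], counts$year[bad[1]]),
          class = "effindex_value_error")
  }
}

ratio_indicator <- function(counts, num, den, scale) {
  out <- counts[[num]] / counts[[den]] * scale
  out[!is.na(counts[[den]]) & counts[[den]] == 0] <- NA_real_
  out
}

#' Affiliation-share indicators (PIW, PMW, PSW)
#'
#' Shares of indigenous, migrant and subsidized-regime affiliated women among
#' all affiliated women, per 100.
#'
#' @param panel An `effindex_panel`.
#' @return Tibble `department`, `year`, `PIW`, `PMW`, `PSW` (values in
#'   \[0, 100\]; missing where the total is 0).
#' @export
affiliation_shares <- function(panel) {
  counts <- panel$counts
  for (sub in c("aff_indigenous", "aff_migrant", "aff_subsidized")) {
    check_subset(counts, sub, "aff_women_total", sub)
  }
  tibble::tibble(
    department = counts$department, year = counts$year,
    PIW = ratio_indicator(counts, "aff_indigenous", "aff_women_total", 100),
    PMW = ratio_indicator(counts, "aff_migrant", "aff_women_total", 100),
    PSW = ratio_indicator(counts, "aff_subsidized", "aff_women_total", 100)
  )
}

#' Early fertility rates (IFR, AFR, EFR)
#'
#' Births to mothers aged <=14 (IFR), 15-19 (AFR) and <=19 (EFR) per 1000
#' affiliated women in the matching age band (10-14, 15-19, 10-19). The
#' affiliated-women register serves as the population denominator.
#'
#' @param panel An `effindex_panel`.
#' @return Tibble `department`, `year`, `IFR`, `AFR`, `EFR`.
#' @export
fertility_rates <- function(panel) {
  counts <- panel$counts
  den_early <- counts$aff_women_10_14 + counts$aff_women_15_19
  num_early <- counts$births_le14 + counts$births_15_19
  efr <- num_early / den_early * 1000
  efr[!is.na(den_early) & den_early == 0] <- NA_real_
  tibble::tibble(
    department = counts$department, year = counts$year,
    IFR = ratio_indicator(counts, "births_le14", "aff_women_10_14", 1000),
    AFR = ratio_indicator(counts, "births_15_19", "aff_women_15_19", 1000),
    EFR = efr
  )
}

#' Domestic-violence share indicators (DVAW, DVAC)
#'
#' Reported domestic-violence cases against women (male perpetrator) and
#' against children <=18, as a share of all reported cases. The default scale
#' is per 1000 — the magnitude the indicator is tabulated at in practice —
#' and is configurable (per-100 gives conventional percentages).
#'
#' @param panel An `effindex_panel`.
#' @param scale Multiplier for the share (default 1000).
#' @return Tibble `department`, `year`, `DVAW`, `DVAC`.
#' @export
violence_shares <- function(panel, scale = 1000) {
  counts <- panel$counts
  check_subset(counts, "dv_women_male_perp", "dv_total", "DVAW")
  check_subset(counts, "dv_children_le18", "dv_total", "DVAC")
  tibble::tibble(
    department = counts$department, year = counts$year,
    DVAW = ratio_indicator(counts, "dv_women_male_perp", "dv_total", scale),
    DVAC = ratio_indicator(counts, "dv_children_le18", "dv_total", scale)
  )
}

#' Violent-death indicators (SR, CHR)
#'
#' Suicides and homicides of persons <=19 per 1000 reported deaths.
#'
#' @param panel An `effindex_panel`.
#' @return Tibble `department`, `year`, `SR`, `CHR`.
#' @export
death_rates <- function(panel) {
  counts <- panel$counts
  check_subset(counts, "deaths_suicide", "deaths_total", "SR")
  check_subset(counts, "deaths_homicide_le19", "deaths_total", "CHR")
  tibble::tibble(
    department = counts$department, year = counts$year,
    SR = ratio_indicator(counts, "deaths_suicide", "deaths_total", 1000),
    CHR = ratio_indicator(counts, "deaths_homicide_le19", "deaths_total", 1000)
  )
}

#' Compute the full ten-indicator panel
#'
#' @param panel An `effindex_panel` (typically after [impute_linear()]).
#' @param dv_scale Scale for the violence shares, see [violence_shares()].
#' @return Tibble `department`, `year` plus the ten indicator columns
#'   `PIW`, `PMW`, `PSW`, `IFR`, `AFR`, `EFR`, `DVAW`, `DVAC`, `SR`, `CHR`.
#' @export
compute_indicators <- function(panel, dv_scale = 1000) {
  by <- c("department", "year")
  out <- affiliation_shares(panel)
  out <- dplyr::left_join(out, fertility_rates(panel), by = by)
  out <- dplyr::left_join(out, violence_shares(panel, scale = dv_scale), by = by)
  out <- dplyr::left_join(out, death_rates(panel), by = by)
  out
}

fmt_num <- function(x) {
  s <- format(round(x, 2), trim = TRUE, scientific = FALSE)
  s <- sub("(\\.\\d*?)0+$", "\\1", s)
  sub("\\.$", "", s)
}

#' Summarize indicators per department over the study years
#'
#' Median, minimum and maximum per department and indicator, ignoring
#' missing years, with a report-ready `"median (min; max)"` label. A series
#' with no observed value yields missing summaries and the label
#' `"unavailable"`.
#'
#' @param indicators Indicator panel from [compute_indicators()].
#' @return Tibble `department`, `indicator`, `median`, `min`, `max`, `label`.
#' @export
summarize_indicators <- function(indicators) {
  long <- tidyr::pivot_longer(indicators, cols = -c("department", "year"),
                              names_to = "indicator", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$department, .data$indicator),
    median = if (all(is.na(.data$value))) NA_real_ else median(.data$value, na.rm = TRUE),
    min = if (all(is.na(.data$value))) NA_real_ else min(.data$value, na.rm = TRUE),
    max = if (all(is.na(.data$value))) NA_real_ else max(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  out$label <- ifelse(is.na(out$median), "unavailable",
                      sprintf("%s (%s; %s)", fmt_num(out$median),
                              fmt_num(out$min), fmt_num(out$max)))
  out
}

#' EFR heatmap matrix
#'
#' Department-by-year matrix of the early fertility rate, rows sorted in
#' decreasing order of the most recent year's EFR — the layout used to scan
#' for persistently high-fertility regions.
#'
#' @param indicators Indicator panel from [compute_indicators()].
#' @return Wide tibble: `department` then one column per year.
#' @export
efr_heatmap <- function(indicators) {
  wide <- tidyr::pivot_wider(indicators[, c("department", "year", "EFR")],
                             names_from = "year", values_from = "EFR")
  last_year <- as.character(max(indicators$year))
  wide[order(-wide[[last_year]]), ]
}
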