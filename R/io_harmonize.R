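#' Canonicalize department names
#'
#' Administrative registries spell the same department inconsistently
#' (accents, case, stray whitespace). Canonical form is uppercase ASCII with
#' collapsed single spaces; an optional alias map then resolves remaining
#' variants (applied after the mechanical cleanup, matching on canonical
#' spellings).
#'
#' @param x Character vector of department names.
#' @param alias Named character vector: `names(alias)` are variant spellings
#'   (canonicalized before matching), values the canonical replacements.
#' @return Character vector of canonical names.
#' @examples
#' canonical_department(c("Bogotá D.C.", "  choco "))
#' @export
canonical_department <- function(x, alias = NULL) {
  out <- stringi::stri_trans_general(as.character(x), "Latin-ASCII")
  out <- toupper(trimws(gsub("[[:space:]]+", " ", out)))
  if (!is.null(alias)) {
    key <- toupper(trimws(gsub("[[:space:]]+", " ",
                               stringi::stri_trans_general(names(alias), "Latin-ASCII"))))
    hit <- match(out, key)
    out[!is.na(hit)] <- unname(alias[hit[!is.na(hit)]])
  }
  out
}

#' Read one raw registry table
#'
#' Reads a long-format CSV of department-year-category counts for one of the
#' four registry sources (`births`, `affiliations`, `violence`, `deaths`),
#' canonicalizes department names, and validates the basic contract:
#' non-negative integer counts and unique (department, year, category) keys.
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @param source One of `"births"`, `"affiliations"`, `"violence"`, `"deaths"`.
#' @param col_map Named character vector mapping the required roles
#'   `department`, `year`, `category`, `count` to the file's column names.
#' @param alias Optional department alias map, see [canonical_department()].
#' @return A tibble with columns `department`, `year`, `category`, `count`
#'   and attribute `source`.
#' @export
read_record_table <- function(path, source,
                              col_map = c(department = "department",
                                          year = "year",
                                          category = "category",
                                          count = "count"),
                              alias = NULL) {
  if (!is.character(source) || length(source) != 1 || !source %in% record_sources) {
    abort(sprintf("unknown source '%s'; expected one of %s",
                  paste(source, collapse = ","),
                  paste(record_sources, collapse = ", ")),
          class = "effindex_config_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "effindex_config_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  roles <- c("department", "year", "category", "count")
  map <- col_map[roles]
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column(s) in %s: %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "effindex_schema_error")
  }
  tbl <- tibble::tibble(
    department = canonical_department(raw[[map[["department"]]]], alias = alias),
    year = as.integer(raw[[map[["year"]]]]),
    category = as.character(raw[[map[["category"]]]]),
    count = as.numeric(raw[[map[["count"]]]])
  )
  as_record_table(tbl, source)
}

#' Construct a record table from an in-memory data frame
#'
#' Validates the same contract as [read_record_table()] (used by the
#' synthetic generator and by callers that already hold parsed data).
#' Department names are assumed canonical already.
#'
#' @param data Data frame with columns `department`, `year`, `category`, `count`.
#' @param source Registry source name.
#' @return A validated record-table tibble.
#' @export
as_record_table <- function(data, source) {
  if (!source %in% record_sources) {
    abort(sprintf("unknown source '%s'", source), class = "effindex_config_error")
  }
  tbl <- tibble::as_tibble(data)[, c("department", "year", "category", "count")]
  bad <- which(!is.finite(tbl$count) | tbl$count < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative or non-finite count in %s row %d (%s, %d, %s)",
                  source, bad[1], tbl$department[bad[1]], tbl$year[bad[1]],
                  tbl$category[bad[1]]),
          class = "effindex_value_error")
  }
  key <- paste(tbl$department, tbl$year, tbl$category, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf("duplicate (department, year, category) key in %s: (%s, %d, %s)",
                  source, tbl$department[dup[1]], tbl$year[dup[1]],
                  tbl$category[dup[1]]),
          class = "effindex_value_error")
  }
  attr(tbl, "source") <- source
  tbl
}

#' Harmonize registry tables onto a rectangular department-year panel
#'
#' Pivots the long-format registry tables to one wide panel over the full
#' `departments x years` grid. Cells absent from the input are marked
#' `missing` (not zero) in a parallel provenance table; an explicit 0 count
#' is data. Departments outside the configured list are excluded with a
#' warning; an aggregate required downstream but absent from every table is
#' a schema error.
#'
#' @param tables List of record tables (see [read_record_table()]).
#' @param departments Character vector of canonical department names.
#' @param years Integer vector of study years.
#' @param category_map Optional named character vector mapping raw category
#'   labels to the required aggregate names; defaults to identity.
#' @return An `effindex_panel`: list with `counts` (wide tibble), `provenance`
#'   (same shape, values `"observed"`/`"missing"`/`"imputed"`), `departments`,
#'   `years`.
#' @export
harmonize <- function(tables, departments, years, category_map = NULL) {
  stopifnot(length(departments) > 0, length(years) > 0)
  departments <- canonical_department(departments)
  years <- sort(as.integer(years))

  long <- purrr::map_dfr(tables, function(tbl) {
    src <- attr(tbl, "source")
    if (is.null(src)) {
      abort("table lacks a source attribute; build it with read_record_table()/as_record_table()",
            class = "effindex_config_error")
    }
    out <- tbl
    if (!is.null(category_map)) {
      hit <- match(out$category, names(category_map))
      out$category[!is.na(hit)] <- unname(category_map[hit[!is.na(hit)]])
    }
    out$category <- ifelse(out$category %in% required_aggregates[[src]],
                           out$category, NA_character_)
    out[!is.na(out$category), ]
  })

  unknown_dep <- setdiff(unique(long$department), departments)
  if (length(unknown_dep) > 0) {
    warn(sprintf("excluding %d department(s) not in the configured list: %s",
                 length(unknown_dep), paste(unknown_dep, collapse = ", ")))
    long <- long[long$department %in% departments, ]
  }
  off_year <- setdiff(unique(long$year), years)
  if (length(off_year) > 0) {
    warn(sprintf("excluding rows outside the study window: year(s) %s",
                 paste(sort(off_year), collapse = ", ")))
    long <- long[long$year %in% years, ]
  }

  all_aggregates <- unlist(required_aggregates, use.names = FALSE)
  absent <- setdiff(all_aggregates, unique(long$category))
  if (length(absent) > 0) {
    abort(sprintf("required aggregate(s) absent from all input tables: %s",
                  paste(absent, collapse = ", ")),
          class = "effindex_schema_error")
  }

  grid <- tidyr::expand_grid(department = departments, year = years)
  wide <- tidyr::pivot_wider(long, id_cols = c("department", "year"),
                             names_from = "category", values_from = "count")
  counts <- dplyr::left_join(grid, wide, by = c("department", "year"))
  for (col in setdiff(all_aggregates, names(counts))) counts[[col]] <- NA_real_
  counts <- counts[, c("department", "year", all_aggregates)]

  prov <- counts
  for (col in all_aggregates) {
    prov[[col]] <- ifelse(is.na(counts[[col]]), "missing", "observed")
  }
  new_panel(counts, prov, departments, years)
}

new_panel <- function(counts, provenance, departments, years) {
  structure(list(counts = tibble::as_tibble(counts),
                 provenance = tibble::as_tibble(provenance),
                 departments = departments, years = years),
            class = "effindex_panel")
}

#' @export
print.effindex_panel <- function(x, ...) {
  n_missing <- sum(as.matrix(x$provenance[, -(1:2)]) == "missing")
  n_imputed <- sum(as.matrix(x$provenance[, -(1:2)]) == "imputed")
  cat(sprintf("<effindex_panel> %d departments x %d years, %d count columns\n",
              length(x$departments), length(x$years), ncol(x$counts) - 2L))
  cat(sprintf("  cells: %d missing, %d imputed\n", n_missing, n_imputed))
  invisible(x)
}

#' Panel accessors
#'
#' @param panel An `effindex_panel`.
#' @return `panel_counts()` the wide count tibble; `panel_provenance()` the
#'   parallel observed/missing/imputed flag tibble.
#' @export
panel_counts <- function(panel) panel$counts

#' @rdname panel_counts
#' @export
panel_provenance <- function(panel) panel$provenance

#' Impute missing panel cells by linear interpolation
#'
#' Fills missing cells along the year axis within each department and count
#' column: interior gaps by linear interpolation between the flanking
#' observed years, leading/trailing gaps by nearest-observed-value extension
#' (linear interpolation is undefined beyond the data). Observed cells are
#' never modified; filled cells are flagged `imputed` in the provenance
#' table. Idempotent.
#'
#' @param panel An `effindex_panel` from [harmonize()].
#' @return The panel with a complete rectangular grid.
#' @export
impute_linear <- function(panel) {
  counts <- panel$counts
  prov <- panel$provenance
  cols <- setdiff(names(counts), c("department", "year"))
  for (dep in panel$departments) {
    idx <- which(counts$department == dep)
    idx <- idx[order(counts$year[idx])]
    yrs <- counts$year[idx]
    for (col in cols) {
      v <- counts[[col]][idx]
      obs <- !is.na(v)
      if (all(obs)) next
      if (!any(obs)) {
        abort(sprintf("cannot impute %s for %s: no observed values", col, dep),
              class = "effindex_value_error")
      }
      filled <- if (sum(obs) == 1) {
        rep(v[obs], length(v))
      } else {
        approx(x = yrs[obs], y = v[obs], xout = yrs,
               method = "linear", rule = 2)$y
      }
      v[!obs] <- filled[!obs]
      counts[[col]][idx] <- v
      prov[[col]][idx][!obs] <- "imputed"
    }
  }
  new_panel(counts, prov, panel$departments, panel$years)
}

#' Write / read a harmonized panel
#'
#' The panel round-trips through two CSVs: the wide count table and a
#' parallel provenance table of observed/missing/imputed flags.
#'
#' @param panel An `effindex_panel`.
#' @param path Output CSV path for the counts.
#' @param provenance_path Output CSV path for the flags (default: `path`
#'   with a `_provenance` suffix).
#' @return `write_panel()` returns the paths invisibly; `read_panel()` the
#'   reconstructed panel.
#' @export
write_panel <- function(panel, path, provenance_path = NULL) {
  if (is.null(provenance_path)) {
    provenance_path <- sub("(\\.csv)?$", "_provenance.csv", path)
  }
  out <- panel$counts
  readr::write_csv(out, path, progress = FALSE)
  readr::write_csv(panel$provenance, provenance_path, progress = FALSE)
  invisible(c(path, provenance_path))
}

#' @rdname write_panel
#' @export
read_panel <- function(path, provenance_path = NULL) {
  if (is.null(provenance_path)) {
    provenance_path <- sub("(\\.csv)?$", "_provenance.csv", path)
  }
  counts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prov <- readr::read_csv(provenance_path, show_col_types = FALSE, progress = FALSE)
  counts$year <- as.integer(counts$year)
  prov$year <- as.integer(prov$year)
  new_panel(counts, prov, unique(counts$department), sort(unique(counts$year)))
}
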