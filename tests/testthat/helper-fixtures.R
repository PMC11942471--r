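# In-code fixtures: tiny registries built from explicit wide count tables.

aggregate_source <- c(
  births_le14 = "births", births_15_19 = "births",
  aff_women_10_14 = "affiliations", aff_women_15_19 = "affiliations",
  aff_women_total = "affiliations", aff_indigenous = "affiliations",
  aff_migrant = "affiliations", aff_subsidized = "affiliations",
  dv_total = "violence", dv_women_male_perp = "violence",
  dv_children_le18 = "violence",
  deaths_total = "deaths", deaths_suicide = "deaths",
  deaths_homicide_le19 = "deaths")

# wide: tibble with department, year and any subset of the 14 aggregates.
# NA cells are omitted from the emitted tables (i.e. genuinely absent).
tables_from_wide <- function(wide) {
  long <- tidyr::pivot_longer(wide, cols = -c(department, year),
                              names_to = "category", values_to = "count")
  long <- long[!is.na(long$count), ]
  srcs <- unique(aggregate_source[long$category])
  stats::setNames(lapply(srcs, function(src) {
    as_record_table(long[aggregate_source[long$category] == src, ], src)
  }), srcs)
}

# A fully observed 2-department x 2-year wide count table with easy numbers.
tiny_wide <- function(departments = c("NORTE", "SUR"), years = 2020:2021) {
  grid <- tidyr::expand_grid(department = departments, year = years)
  n <- nrow(grid)
  tibble::tibble(
    grid,
    births_le14 = rep(2, n), births_15_19 = rep(30, n),
    aff_women_10_14 = rep(1000, n), aff_women_15_19 = rep(1000, n),
    aff_women_total = rep(10000, n), aff_indigenous = rep(2500, n),
    aff_migrant = rep(250, n), aff_subsidized = rep(5000, n),
    dv_total = rep(100, n), dv_women_male_perp = rep(30, n),
    dv_children_le18 = rep(10, n),
    deaths_total = rep(1000, n), deaths_suicide = rep(5, n),
    deaths_homicide_le19 = rep(25, n))
}

panel_from_wide <- function(wide, departments = unique(wide$department),
                            years = sort(unique(wide$year))) {
  harmonize(tables_from_wide(wide), departments = departments, years = years)
}

# A mid-sized panel with department-level heterogeneity, fully observed,
# for segmentation / index tests. Deterministic trigonometric jitter breaks
# collinearity between indicator channels without any RNG state.
varied_wide <- function(n_dep = 6, years = 2019:2022) {
  deps <- sprintf("D%02d", seq_len(n_dep))
  grid <- tidyr::expand_grid(department = deps, year = years)
  i <- match(grid$department, deps)
  y <- grid$year - min(years)
  jit <- function(k) round(10 * (1 + sin(k * i + y / (k + 1))))
  tibble::tibble(
    grid,
    births_le14 = 1 + i + y,
    births_15_19 = 20 + 5 * i + 2 * y * i + jit(2),
    aff_women_10_14 = 900 + 10 * i + jit(3),
    aff_women_15_19 = 1000 + 10 * i + jit(4),
    aff_women_total = 10000 + 100 * i + 3 * jit(5),
    aff_indigenous = 100 * i + 2 * jit(6),
    aff_migrant = 10 * i + y + jit(7),
    aff_subsidized = 3000 + 300 * i + 5 * jit(8),
    dv_total = 200 + 10 * i + jit(9),
    dv_women_male_perp = 50 + 8 * i + 2 * y + jit(10),
    dv_children_le18 = 20 + 3 * i + y + jit(11),
    deaths_total = 800 + 20 * i + jit(12),
    deaths_suicide = 8 + i + jit(13),
    deaths_homicide_le19 = 2 + 2 * i + y + jit(14))
}

# Independent Spearman oracle: fractional ranks computed from first
# principles, Pearson correlation from the sum formulas (no calls into the
# package's rank/cor path).
oracle_avg_ranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}
oracle_spearman <- function(x, y) {
  rx <- oracle_avg_ranks(x); ry <- oracle_avg_ranks(y)
  n <- length(x)
  sxy <- sum(rx * ry) - n * mean(rx) * mean(ry)
  sxx <- sum(rx^2) - n * mean(rx)^2
  syy <- sum(ry^2) - n * mean(ry)^2
  sxy / sqrt(sxx * syy)
}

# Independent exhaustive permutation enumeration (recursive list-based,
# unlike the package's matrix insertion scheme).
oracle_perm_list <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perm_list(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}
oracle_perm_pvalue <- function(x, y) {
  obs <- abs(oracle_spearman(x, y))
  rhos <- vapply(oracle_perm_list(seq_along(y)),
                 function(p) oracle_spearman(x, y[p]), numeric(1))
  mean(abs(rhos) >= obs - 1e-12)
}

# Closed-form Gaussian least-squares oracle: normal equations plus
# two-sided t p-values on residual df.
oracle_lm <- function(y, X) {
  Xm <- cbind(1, as.matrix(X))
  XtX_inv <- solve(t(Xm) %*% Xm)
  beta <- XtX_inv %*% t(Xm) %*% y
  res <- y - Xm %*% beta
  df <- length(y) - ncol(Xm)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- beta / se
  list(beta = as.numeric(beta), se = as.numeric(se),
       p = as.numeric(2 * pt(-abs(tval), df)))
}
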