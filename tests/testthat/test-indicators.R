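test_that("affiliation shares follow subgroup / total x 100", {
  wide <- tiny_wide(departments = "A", years = 2020)
  wide$aff_women_total <- 120
  wide$aff_indigenous <- 25
  wide$aff_migrant <- 3
  wide$aff_subsidized <- 60
  sh <- affiliation_shares(panel_from_wide(wide))
  expect_equal(sh$PIW, 25 / 120 * 100)
  expect_equal(sh$PMW, 2.5)
  expect_equal(sh$PSW, 50)

  wide$aff_women_total <- 0
  wide$aff_indigenous <- 0
  wide$aff_migrant <- 0
  wide$aff_subsidized <- 0
  expect_true(all(is.na(affiliation_shares(panel_from_wide(wide))[, c("PIW", "PMW", "PSW")])))

  wide$aff_women_total <- 10
  wide$aff_indigenous <- 25
  expect_error(affiliation_shares(panel_from_wide(wide)),
               "consistency", class = "effindex_value_error")
})

test_that("fertility rates are per 1000 affiliated women in the matching band", {
  wide <- tiny_wide(departments = "A", years = 2020)
  fr <- fertility_rates(panel_from_wide(wide))
  expect_equal(fr$IFR, 2)             # 2 / 1000 x 1000
  expect_equal(fr$AFR, 30)
  expect_equal(fr$EFR, 16)            # (2 + 30) / 2000 x 1000

  wide$births_le14 <- 0
  wide$births_15_19 <- 0
  fr0 <- fertility_rates(panel_from_wide(wide))
  expect_equal(unlist(fr0[, c("IFR", "AFR", "EFR")], use.names = FALSE),
               c(0, 0, 0))

  wide$aff_women_10_14 <- 0
  expect_true(is.na(fertility_rates(panel_from_wide(wide))$IFR))
})

test_that("violence shares scale as configured (default per 1000)", {
  panel <- panel_from_wide(tiny_wide(departments = "A", years = 2020))
  vs <- violence_shares(panel)
  expect_equal(vs$DVAW, 300)          # 30 / 100 x 1000
  expect_equal(vs$DVAC, 100)
  expect_equal(violence_shares(panel, scale = 100)$DVAW, 30)

  wide <- tiny_wide(departments = "A", years = 2020)
  wide$dv_children_le18 <- 0
  wide$dv_total <- 50
  wide$dv_women_male_perp <- 10
  expect_equal(violence_shares(panel_from_wide(wide))$DVAC, 0)
})

test_that("death rates are per 1000 reported deaths", {
  panel <- panel_from_wide(tiny_wide(departments = "A", years = 2020))
  dr <- death_rates(panel)
  expect_equal(dr$SR, 5)
  expect_equal(dr$CHR, 25)

  wide <- tiny_wide(departments = "A", years = 2020)
  wide$deaths_suicide <- 0
  expect_equal(death_rates(panel_from_wide(wide))$SR, 0)
})

test_that("the ten indicators are invariant to rescaling all counts in a cell", {
  wide <- varied_wide(n_dep = 3, years = 2020:2021)
  base <- compute_indicators(panel_from_wide(wide))
  scaled <- wide
  count_cols <- setdiff(names(wide), c("department", "year"))
  scaled[count_cols] <- lapply(scaled[count_cols], function(v) v * 7)
  expect_equal(compute_indicators(panel_from_wide(scaled)), base)
})

test_that("indicator bounds hold over random valid count tables", {
  set.seed(42)
  for (rep in 1:20) {
    deps <- sprintf("R%02d", 1:4)
    grid <- tidyr::expand_grid(department = deps, year = 2019:2021)
    n <- nrow(grid)
    tot <- sample(100:10000, n, replace = TRUE)
    dvt <- sample(0:500, n, replace = TRUE)
    dtt <- sample(1:2000, n, replace = TRUE)
    wide <- tibble::tibble(
      grid,
      births_le14 = rpois(n, 3), births_15_19 = rpois(n, 40),
      aff_women_10_14 = pmax(1, rbinom(n, tot, 0.08)),
      aff_women_15_19 = pmax(1, rbinom(n, tot, 0.08)),
      aff_women_total = tot,
      aff_indigenous = rbinom(n, tot, runif(n)),
      aff_migrant = rbinom(n, tot, runif(n, 0, 0.05)),
      aff_subsidized = rbinom(n, tot, runif(n)),
      dv_total = dvt,
      dv_women_male_perp = rbinom(n, dvt, runif(n)),
      dv_children_le18 = rbinom(n, dvt, runif(n)),
      deaths_total = dtt,
      deaths_suicide = rbinom(n, dtt, runif(n, 0, 0.1)),
      deaths_homicide_le19 = rbinom(n, dtt, runif(n, 0, 0.1)))
    ind <- compute_indicators(panel_from_wide(wide))
    for (col in c("PIW", "PMW", "PSW")) {
      expect_true(all(ind[[col]] >= 0 & ind[[col]] <= 100, na.rm = TRUE))
    }
    for (col in c("DVAW", "DVAC", "SR", "CHR")) {
      expect_true(all(ind[[col]] >= 0 & ind[[col]] <= 1000, na.rm = TRUE))
    }
    # EFR is a count-weighted mean of IFR and AFR
    both <- !is.na(ind$IFR) & !is.na(ind$AFR)
    expect_true(all(ind$EFR[both] >= pmin(ind$IFR, ind$AFR)[both] - 1e-12))
    expect_true(all(ind$EFR[both] <= pmax(ind$IFR, ind$AFR)[both] + 1e-12))
  }
})

test_that("summaries report median (min; max) over years, ignoring missing", {
  ind <- tibble::tibble(
    department = rep(c("A", "B", "C"), each = 4),
    year = rep(2019:2022, 3),
    DVAW = c(10, 20, 30, 40, 5, NA, NA, NA, 0, 0, 0, 0))
  sm <- summarize_indicators(ind)
  expect_equal(sm$label[sm$department == "A"], "25 (10; 40)")
  expect_equal(sm$label[sm$department == "B"], "5 (5; 5)")
  expect_equal(sm$label[sm$department == "C"], "0 (0; 0)")

  ind$DVAW[ind$department == "B"] <- NA
  sm2 <- summarize_indicators(ind)
  expect_equal(sm2$label[sm2$department == "B"], "unavailable")
  expect_true(all(sm2$min <= sm2$median & sm2$median <= sm2$max, na.rm = TRUE))
})

test_that("the EFR heatmap matrix is sorted by the most recent year's EFR", {
  ind <- compute_indicators(impute_linear(panel_from_wide(varied_wide())))
  hm <- efr_heatmap(ind)
  expect_equal(names(hm), c("department", as.character(2019:2022)))
  expect_true(all(diff(hm[["2022"]]) <= 0))
})
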