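test_that("generator output is fully determined by (config, seed)", {
  cfg <- synthetic_config(n_departments = 8, seed = 42)
  g1 <- generate_synthetic(cfg)
  g2 <- generate_synthetic(cfg)
  expect_identical(g1$tables, g2$tables)
  expect_identical(g1$truth, g2$truth)

  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.csv"); f2 <- file.path(dir, "b.csv")
  readr::write_csv(g1$tables$births, f1)
  readr::write_csv(g2$tables$births, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  g3 <- generate_synthetic(synthetic_config(n_departments = 8, seed = 43))
  expect_false(identical(g1$tables$births, g3$tables$births))
})

test_that("config validation rejects degenerate parameters", {
  expect_error(synthetic_config(n_departments = 2), ">= 3",
               class = "effindex_config_error")
  expect_error(synthetic_config(years = c(2019, 2021)), "contiguous",
               class = "effindex_config_error")
  bad <- c(indigenous = 0, migrant = 0.005, subsidized = 0.55,
           dv_women = 0.32, dv_children = 0.10, homicide = 0.005,
           suicide = 0.011, ifr = 0.0015, afr = 0.030)
  expect_error(synthetic_config(baselines = bad), "indigenous",
               class = "effindex_config_error")
})

test_that("tables respect the raw input dialect and internal consistency", {
  cfg <- synthetic_config(n_departments = 10, seed = 3)
  gen <- generate_synthetic(cfg)
  expect_setequal(names(gen$tables),
                  c("births", "affiliations", "violence", "deaths"))
  for (tbl in gen$tables) {
    expect_setequal(names(tbl), c("department", "year", "category", "count"))
    expect_true(all(tbl$count >= 0))
  }
  # subgroup counts never exceed their totals (before any imputation)
  panel <- impute_linear(harmonize(gen$tables,
                                   departments = sprintf("D%02d", 1:10),
                                   years = cfg$years))
  expect_s3_class(compute_indicators(panel), "tbl_df")
})

test_that("generated births are marginally calibrated to their Poisson mean", {
  # large-n check of E[births_15_19] = aff_15_19 * afr * E[exp(noise + loading*F)]
  cfg <- synthetic_config(n_departments = 250, years = 2019:2020, seed = 9,
                          missingness = 0, shock = 0,
                          loadings = c(indigenous = 0, migrant = 0,
                                       subsidized = 0, dv_women = 0,
                                       dv_children = 0, homicide = 0,
                                       suicide = 0, fertility = 0),
                          noise_sd = 0)
  gen <- generate_synthetic(cfg)
  b <- gen$tables$births
  a <- gen$tables$affiliations
  b19 <- b[b$category == "births_15_19", ]
  a19 <- a[a$category == "aff_women_15_19", ]
  m <- dplyr::inner_join(b19, a19, by = c("department", "year"),
                         suffix = c("_b", "_a"))
  lambda <- m$count_a * cfg$baselines[["afr"]]
  pearson <- (m$count_b - lambda) / sqrt(lambda)
  # standardized residuals of a Poisson draw: mean 0 within 3 MC SEs
  expect_lt(abs(mean(pearson)), 3 / sqrt(nrow(m)))
})

test_that("zero loadings give no fragility-indicator association", {
  cfg0 <- synthetic_config(n_departments = 40, seed = 17, shock = 0,
                           missingness = 0,
                           loadings = c(indigenous = 0, migrant = 0,
                                        subsidized = 0, dv_women = 0,
                                        dv_children = 0, homicide = 0,
                                        suicide = 0, fertility = 0))
  gen <- generate_synthetic(cfg0)
  panel <- harmonize(gen$tables, sprintf("D%02d", 1:40), cfg0$years)
  ind <- compute_indicators(impute_linear(panel))
  agg <- dplyr::summarise(dplyr::group_by(ind, department),
                          PIW = mean(PIW), .groups = "drop")
  st <- spearman_test(agg$PIW, gen$truth$fragility)
  expect_lt(abs(st$rho), 0.45)
})

test_that("increasing the shock never weakens the fragility-to-change link", {
  rhos <- vapply(c(0, 0.25, 0.5, 1), function(s) {
    cfg <- synthetic_config(n_departments = 33, seed = 23, shock = s,
                            missingness = 0, noise_sd = 0.01)
    gen <- generate_synthetic(cfg)
    panel <- harmonize(gen$tables, sprintf("D%02d", 1:33), cfg$years)
    ind <- compute_indicators(impute_linear(panel))
    d <- suppressWarnings(relative_change(ind, "EFR", 2020, 2021))
    m <- dplyr::inner_join(d, gen$truth, by = "department")
    spearman_test(m$delta, m$fragility)$rho
  }, numeric(1))
  expect_true(all(diff(rhos) >= -0.05))
  expect_gt(rhos[4], 0.9)
})

test_that("recovery on the high-signal default regime finds the planted factor", {
  rec <- suppressWarnings(recover_synthetic(synthetic_config(seed = 7)))
  expect_gt(rec$spearman_fragility$rho, 0.8)
  expect_setequal(rec$planted, c("PIW", "PSW", "CHR"))
  expect_true(all(rec$retained %in% colnames(rec$segments$aggregated)))
  expect_identical(rec$validation$interpretation[rec$validation$pair == "EFFI~z_dEFR"],
                   "supports_validity")
})
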