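test_that("aggregate_index is the weighted sum of standardized indicators", {
  agg <- tibble::tibble(department = "A", X = 1, Y = 1, W = 1)
  w <- index_weights(c("X", "Y", "W"))
  expect_equal(aggregate_index(agg, w)$effi, 1)

  agg2 <- tibble::tibble(department = "A", X = 2, Y = -2)
  expect_equal(aggregate_index(agg2, index_weights(c("X", "Y")))$effi, 0)

  agg3 <- tibble::tibble(department = "A", X = 0.5, Y = -1, W = 2)
  w3 <- index_weights(c("X", "Y", "W"), mode = "custom",
                      weights = c(X = 0.2, Y = 0.3, W = 0.5))
  expect_equal(aggregate_index(agg3, w3)$effi, 0.8)

  expect_error(aggregate_index(agg2, index_weights(c("X", "Z"))),
               "absent", class = "effindex_config_error")
  expect_warning(
    out <- aggregate_index(tibble::tibble(department = c("A", "B"),
                                          X = c(1, NA), Y = c(0, 0)),
                           index_weights(c("X", "Y"))),
    "excluding")
  expect_equal(out$department, "A")
})

test_that("aggregate_index is linear in the standardized values", {
  set.seed(3)
  w <- index_weights(c("X", "Y", "W"), mode = "custom",
                     weights = c(X = 0.1, Y = 0.5, W = 0.4))
  z1 <- tibble::tibble(department = letters[1:5], X = rnorm(5), Y = rnorm(5),
                       W = rnorm(5))
  z2 <- tibble::tibble(department = letters[1:5], X = rnorm(5), Y = rnorm(5),
                       W = rnorm(5))
  mix <- z1
  mix[2:4] <- 2 * z1[2:4] + 3 * z2[2:4]
  expect_equal(aggregate_index(mix, w)$effi,
               2 * aggregate_index(z1, w)$effi + 3 * aggregate_index(z2, w)$effi)
})

test_that("fit_glm matches the normal-equations + t closed form", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(10:30, 1)
    p <- sample(1:5, 1)
    X <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(X) <- paste0("V", seq_len(p))
    y <- rnorm(n)
    fit <- fit_glm(y, X)
    or <- oracle_lm(y, X)
    expect_equal(fit$coefficients$estimate, or$beta, tolerance = 1e-8)
    expect_equal(fit$coefficients$std_error, or$se, tolerance = 1e-8)
    expect_equal(fit$coefficients$p_value, or$p, tolerance = 1e-8)
    expect_equal(fit$pseudo_r2, 1 - fit$deviance / fit$null_deviance)
  }
})

test_that("fit_glm recovers an exact predictor and handles degenerate designs", {
  set.seed(8)
  n <- 33
  X <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  fit <- fit_glm(X$signal, X)
  est <- fit$coefficients$estimate[fit$coefficients$term == "signal"]
  expect_equal(est, 1, tolerance = 1e-10)
  expect_equal(fit$pseudo_r2, 1, tolerance = 1e-10)

  Xc <- data.frame(a = rnorm(n), flat = rep(2, n))
  expect_warning(fit2 <- fit_glm(rnorm(n), Xc), "constant")
  expect_false("flat" %in% fit2$coefficients$term)

  Xs <- data.frame(a = rnorm(n))
  Xs$b <- 2 * Xs$a
  expect_error(fit_glm(rnorm(n), Xs), "collinear",
               class = "effindex_value_error")
})

test_that("single-fit significance of pure noise is nominal (~5%)", {
  set.seed(14)
  B <- 400
  n <- 30
  hits <- matrix(FALSE, B, 3)
  for (b in seq_len(B)) {
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    fit <- fit_glm(rnorm(n), X)
    hits[b, ] <- fit$coefficients$p_value[-1] < 0.05
  }
  rate <- colMeans(hits)
  band <- 3 * sqrt(0.05 * 0.95 / B)
  expect_true(all(abs(rate - 0.05) < band))
})

test_that("backward elimination drops null predictors and respects keep/alpha", {
  set.seed(5)
  n <- 200
  X <- data.frame(s1 = rnorm(n), s2 = rnorm(n), null = rnorm(n))
  y <- 5 * X$s1 + 5 * X$s2 + rnorm(n)
  pr <- prune_predictors(y, X)
  expect_setequal(pr$retained, c("s1", "s2"))
  expect_equal(pr$audit$dropped, "null")

  # deviance is non-decreasing along the elimination path
  set.seed(6)
  Xn <- as.data.frame(matrix(rnorm(40 * 6), 40, 6))
  yn <- rnorm(40)
  prn <- suppressWarnings(prune_predictors(yn, Xn))
  full_dev <- fit_glm(yn, Xn)$deviance
  expect_true(all(diff(c(full_dev, prn$audit$deviance)) >= -1e-10))

  # alpha = 1 never drops anything
  pr1 <- prune_predictors(yn, Xn, alpha = 1)
  expect_setequal(pr1$retained, names(Xn))

  # keep list retains a non-significant predictor
  prk <- suppressWarnings(prune_predictors(yn, Xn, keep = "V1"))
  expect_true("V1" %in% prk$retained)
  final_p <- prk$fit$coefficients
  expect_true(all(final_p$p_value[!final_p$term %in% c("(Intercept)", "V1")] <= 0.05))

  # everything null and droppable -> intercept-only with warning
  expect_warning(pr0 <- prune_predictors(yn, Xn[, 1:3]), "intercept-only")
  expect_length(pr0$retained, 0)
  expect_equal(pr0$fit$pseudo_r2, 0)
})

test_that("build_effi modes: circular saturated first stage vs delta outcome", {
  ind <- compute_indicators(impute_linear(panel_from_wide(varied_wide(n_dep = 10))))
  seg <- segment_panel(ind)

  lit <- suppressWarnings(build_effi(seg, mode = "composite_outcome"))
  expect_true(lit$circular)
  expect_equal(lit$first_fit$pseudo_r2, 1, tolerance = 1e-12)

  del <- suppressWarnings(build_effi(seg, mode = "delta_outcome"))
  expect_s3_class(del$scores, "tbl_df")
  if (length(del$retained) > 0) {
    expect_equal(del$weights$weight, rep(1 / length(del$retained),
                                         length(del$retained)))
    # scores equal the hand-computed equal-weight composite
    Z <- as.matrix(seg$aggregated[, del$retained, drop = FALSE])
    expect_equal(del$scores$effi, as.numeric(Z %*% del$weights$weight))
  }
})
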