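# Composite index aggregation and GLM-based predictor refinement.

#' Index weights
#'
#' @param indicators Character vector of retained indicator names.
#' @param mode `"equal"` (w = 1/k, the default construction),
#'   `"glm_coefficients"` (weights supplied from a fitted model, for
#'   sensitivity analysis) or `"custom"`.
#' @param weights Numeric weights, required for the non-equal modes; must be
#'   finite and named or in `indicators` order.
#' @return Tibble `indicator`, `weight` with attribute `mode`.
#' @export
index_weights <- function(indicators,
                          mode = c("equal", "glm_coefficients", "custom"),
                          weights = NULL) {
  mode <- match.arg(mode)
  k <- length(indicators)
  if (k == 0) abort("no indicators to weight", class = "effindex_config_error")
  if (mode == "equal") {
    w <- rep(1 / k, k)
  } else {
    if (is.null(weights) || length(weights) != k || !all(is.finite(weights))) {
      abort(sprintf("mode '%s' needs %d finite weights", mode, k),
            class = "effindex_config_error")
    }
    w <- if (!is.null(names(weights))) unname(weights[indicators]) else weights
    if (any(is.na(w))) {
      abort("weights do not cover every indicator", class = "effindex_config_error")
    }
  }
  out <- tibble::tibble(indicator = indicators, weight = w)
  attr(out, "mode") <- mode
  out
}

#' Aggregate standardized indicators into a composite index
#'
#' `FFI_d = sum_i w_i * Z_{i,d}` over the retained indicators. Departments
#' with a missing value in any retained indicator are excluded with a
#' warning.
#'
#' @param aggregated Tibble with `department` and one standardized column per
#'   indicator (e.g. `segment_panel()$aggregated`).
#' @param weights Tibble from [index_weights()].
#' @return Tibble `department`, `effi`, `rank` (1 = most fragile), with the
#'   weights attached as attribute `weights`.
#' @export
aggregate_index <- function(aggregated, weights) {
  absent <- setdiff(weights$indicator, names(aggregated))
  if (length(absent) > 0) {
    abort(sprintf("weight refers to absent indicator(s): %s",
                  paste(absent, collapse = ", ")),
          class = "effindex_config_error")
  }
  Z <- as.matrix(aggregated[, weights$indicator, drop = FALSE])
  keep <- complete.cases(Z)
  if (!all(keep)) {
    warn(sprintf("aggregate_index: excluding %s (missing indicator values)",
                 paste(aggregated$department[!keep], collapse = ", ")))
  }
  score <- as.numeric(Z[keep, , drop = FALSE] %*% weights$weight)
  out <- tibble::tibble(department = aggregated$department[keep], effi = score)
  out$rank <- rank(-out$effi, ties.method = "min")
  attr(out, "weights") <- weights
  out
}

glm_fit_summary <- function(fit, outcome_name) {
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(list(
    outcome = outcome_name,
    coefficients = tibble::tibble(
      term = rownames(ct), estimate = unname(ct[, 1]),
      std_error = unname(ct[, 2]), statistic = unname(ct[, 3]),
      p_value = unname(ct[, 4])),
    null_deviance = fit$null.deviance,
    deviance = fit$deviance,
    pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
    n = length(fit$y),
    family = fit$family$family,
    model = fit
  ), class = "effindex_glm_fit")
}

#' @export
print.effindex_glm_fit <- function(x, ...) {
  cat(sprintf("<effindex_glm_fit> %s ~ %d term(s), family %s, n = %d\n",
              x$outcome, nrow(x$coefficients) - 1L, x$family, x$n))
  cat(sprintf("  deviance %.4f (null %.4f), pseudo-R2 %.4f\n",
              x$deviance, x$null_deviance, x$pseudo_r2))
  print(x$coefficients)
  invisible(x)
}

#' Fit the index refinement GLM
#'
#' Gaussian family with identity link and an intercept; coefficient p-values
#' are two-sided t tests on the residual degrees of freedom, and the model
#' quality is summarized as pseudo-R² = 1 - residual deviance / null
#' deviance. Constant predictor columns are dropped with a warning; an
#' otherwise rank-deficient design is an error naming the collinear columns.
#'
#' @param outcome Numeric outcome vector (one value per department).
#' @param predictors Data frame / tibble of numeric predictor columns.
#' @param outcome_name Label for reports.
#' @param family A [stats::family] object; default `gaussian()`.
#' @return An `effindex_glm_fit`: coefficient table, deviances, pseudo-R²,
#'   `n`, family, and the underlying [stats::glm] object in `$model`.
#' @export
fit_glm <- function(outcome, predictors, outcome_name = "outcome",
                    family = gaussian()) {
  predictors <- tibble::as_tibble(predictors)
  if (length(outcome) != nrow(predictors)) {
    abort("outcome and predictors disagree in length", class = "effindex_value_error")
  }
  if (anyNA(outcome) || anyNA(predictors)) {
    abort("missing values in the design; filter complete cases first",
          class = "effindex_value_error")
  }
  constant <- vapply(predictors, function(v) sd(v) == 0, logical(1))
  if (any(constant)) {
    warn(sprintf("dropping constant predictor(s): %s",
                 paste(names(predictors)[constant], collapse = ", ")))
    predictors <- predictors[, !constant, drop = FALSE]
  }
  p <- ncol(predictors)
  if (length(outcome) <= p + 1) {
    abort(sprintf("need n > p + 1 (n = %d, p = %d)", length(outcome), p),
          class = "effindex_value_error")
  }
  if (p > 0) {
    X <- cbind(`(Intercept)` = 1, as.matrix(predictors))
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      dropped <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
      abort(sprintf("rank-deficient design; collinear column(s): %s",
                    paste(dropped, collapse = ", ")),
            class = "effindex_value_error")
    }
  }
  dat <- data.frame(.outcome = outcome, predictors, check.names = FALSE)
  form <- if (p > 0) {
    stats::reformulate(sprintf("`%s`", names(predictors)), response = ".outcome")
  } else {
    .outcome ~ 1
  }
  fit <- glm(form, data = dat, family = family)
  glm_fit_summary(fit, outcome_name)
}

#' Backward elimination of non-significant predictors
#'
#' Repeatedly refits the GLM and removes the predictor with the largest
#' p-value above `alpha`, one at a time, until every remaining predictor is
#' significant (or only keep-listed predictors exceed `alpha`). The audit
#' trail records each drop with its p-value and the resulting deviance and
#' pseudo-R². If every predictor is eliminated an intercept-only fit is
#' returned with a warning.
#'
#' @param outcome,predictors,outcome_name,family As in [fit_glm()].
#' @param alpha Significance threshold, default 0.05.
#' @param keep Predictors never dropped regardless of significance.
#' @return List `retained` (character), `fit` (`effindex_glm_fit`),
#'   `audit` (tibble `step`, `dropped`, `p_value`, `deviance`, `pseudo_r2`).
#' @export
prune_predictors <- function(outcome, predictors, alpha = 0.05,
                             keep = character(), outcome_name = "outcome",
                             family = gaussian()) {
  predictors <- tibble::as_tibble(predictors)
  current <- names(predictors)
  audit <- tibble::tibble(step = integer(), dropped = character(),
                          p_value = numeric(), deviance = numeric(),
                          pseudo_r2 = numeric())
  step <- 0L
  repeat {
    fit <- fit_glm(outcome, predictors[, current, drop = FALSE],
                   outcome_name = outcome_name, family = family)
    # terms may have been silently reduced (constant columns)
    current <- setdiff(fit$coefficients$term, "(Intercept)")
    coefs <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    droppable <- coefs[!(coefs$term %in% keep) & coefs$p_value > alpha, ]
    if (nrow(droppable) == 0 || length(current) == 0) break
    worst <- droppable$term[which.max(droppable$p_value)]
    step <- step + 1L
    current <- setdiff(current, worst)
    refit <- if (length(current) > 0) {
      fit_glm(outcome, predictors[, current, drop = FALSE],
              outcome_name = outcome_name, family = family)
    } else {
      fit_glm(outcome, predictors[, character(0)],
              outcome_name = outcome_name, family = family)
    }
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      step = step, dropped = worst,
      p_value = droppable$p_value[which.max(droppable$p_value)],
      deviance = refit$deviance, pseudo_r2 = refit$pseudo_r2))
    fit <- refit
    if (length(current) == 0) break
  }
  if (length(current) == 0) {
    warn("all predictors eliminated; returning intercept-only model")
  }
  list(retained = current, fit = fit, audit = audit)
}

#' Build the Early Fertility Fragility Index
#'
#' Two constructions are offered:
#' * `"delta_outcome"` (default, recommended) — backward-eliminate the
#'   candidate risk indicators against a standardized fertility-change
#'   outcome (default `z_dEFR`), then form the equal-weight composite of the
#'   retained indicators.
#' * `"composite_outcome"` — form the equal-weight composite of *all* candidate
#'   indicators first, regress that composite on its own components, prune,
#'   and re-aggregate over the retained set. The first-stage regression is
#'   circular by construction (the outcome is an exact linear combination of
#'   the predictors, so its pseudo-R² is 1); it is provided to reproduce that
#'   behaviour faithfully and is flagged in the returned object.
#'
#' @param segments An `effindex_segments` from [segment_panel()].
#' @param mode `"delta_outcome"` or `"composite_outcome"`.
#' @param outcome Outcome column for `delta_outcome` mode (default
#'   `"z_dEFR"`).
#' @param alpha Pruning threshold, default 0.05.
#' @param keep Predictors never dropped.
#' @param weight_mode `"equal"` (default) or `"glm_coefficients"`.
#' @param family GLM family, default `gaussian()`.
#' @return An `effindex_index` list: `scores` (tibble `department`, `effi`,
#'   `rank`), `weights`, `retained`, `fit` (final GLM), `first_fit`
#'   (composite-outcome first stage, else `NULL`), `audit`, `mode`, `circular`.
#' @export
build_effi <- function(segments, mode = c("delta_outcome", "composite_outcome"),
                       outcome = "z_dEFR", alpha = 0.05, keep = character(),
                       weight_mode = c("equal", "glm_coefficients"),
                       family = gaussian()) {
  mode <- match.arg(mode)
  weight_mode <- match.arg(weight_mode)
  agg <- segments$aggregated
  preds <- segments$predictors
  first_fit <- NULL

  if (mode == "delta_outcome") {
    if (!outcome %in% names(agg)) {
      abort(sprintf("outcome column '%s' not in the aggregated dataset", outcome),
            class = "effindex_config_error")
    }
    y <- agg[[outcome]]
    X <- agg[, preds, drop = FALSE]
    ok <- !is.na(y) & complete.cases(X)
    if (!all(ok)) {
      warn(sprintf("build_effi: excluding %s (incomplete outcome/predictors)",
                   paste(agg$department[!ok], collapse = ", ")))
    }
    pruned <- prune_predictors(y[ok], X[ok, , drop = FALSE], alpha = alpha,
                               keep = keep, outcome_name = outcome,
                               family = family)
  } else {
    X <- agg[, preds, drop = FALSE]
    ok <- complete.cases(X)
    if (!all(ok)) {
      warn(sprintf("build_effi: excluding %s (incomplete predictors)",
                   paste(agg$department[!ok], collapse = ", ")))
    }
    composite <- rowMeans(X[ok, , drop = FALSE])
    first_fit <- fit_glm(composite, X[ok, , drop = FALSE],
                         outcome_name = "equal_weight_composite",
                         family = family)
    warn("composite_outcome mode regresses the composite on its own components; the first-stage fit is circular by construction")
    pruned <- prune_predictors(composite, X[ok, , drop = FALSE], alpha = alpha,
                               keep = keep,
                               outcome_name = "equal_weight_composite",
                               family = family)
  }

  retained <- pruned$retained
  if (length(retained) == 0) {
    weights <- tibble::tibble(indicator = character(), weight = numeric())
    scores <- tibble::tibble(department = character(), effi = numeric(),
                             rank = integer())
  } else {
    weights <- if (weight_mode == "equal") {
      index_weights(retained, mode = "equal")
    } else {
      cf <- pruned$fit$coefficients
      w <- setNames(cf$estimate[match(retained, cf$term)], retained)
      index_weights(retained, mode = "glm_coefficients", weights = w)
    }
    scores <- aggregate_index(agg, weights)
  }
  structure(list(scores = scores, weights = weights, retained = retained,
                 fit = pruned$fit, first_fit = first_fit,
                 audit = pruned$audit, mode = mode,
                 circular = identical(mode, "composite_outcome")),
            class = "effindex_index")
}

#' @export
print.effindex_index <- function(x, ...) {
  cat(sprintf("<effindex_index> mode %s%s; retained: %s\n", x$mode,
              if (x$circular) " (circular first stage)" else "",
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "<none>"))
  if (nrow(x$scores) > 0) {
    top <- x$scores[order(x$scores$rank), ]
    cat(sprintf("  most fragile: %s (%.3f); least: %s (%.3f)\n",
                top$department[1], top$effi[1],
                top$department[nrow(top)], top$effi[nrow(top)]))
  }
  invisible(x)
}
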