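# Spearman rank-correlation validation of the composite index.

# All permutations of 1..n as an (n! x n) integer matrix, built by inserting
# n into every position of each permutation of 1..(n-1).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, m * n, n)
  for (j in seq_len(n)) {
    rows <- ((j - 1L) * m + 1L):(j * m)
    left <- if (j > 1L) sub[, seq_len(j - 1L), drop = FALSE] else NULL
    right <- if (j < n) sub[, j:(n - 1L), drop = FALSE] else NULL
    out[rows, ] <- cbind(left, n, right)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Ranks with ties averaged (fractional ranks); the coefficient is the
#' Pearson correlation of the rank vectors, so it is invariant under any
#' strictly increasing transform of either input. Missing entries are
#' removed pairwise. Two-sided p-values come from the t approximation with
#' n - 2 degrees of freedom for `n >= exact_n` and from the exact permutation
#' distribution (all n! rank permutations) below that.
#'
#' @param x,y Numeric vectors of equal length.
#' @param exact_n Sample size at and above which the t approximation is used;
#'   default 10.
#' @return List `rho`, `p_value`, `n`, `method`.
#' @examples
#' spearman_test(1:4, c(10, 20, 30, 40))$rho
#' @export
spearman_test <- function(x, y, exact_n = 10) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "effindex_value_error")
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort(sprintf("need at least 3 complete pairs (have %d)", n),
          class = "effindex_value_error")
  }
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("undefined correlation: zero rank variance", class = "effindex_value_error")
  }
  rho <- cor(rx, ry)
  if (n >= exact_n) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  } else {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- as.numeric(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

#' Validate the index against fertility-change outcomes
#'
#' Spearman correlations between the composite index and each standardized
#' fertility-change outcome, with the sign-based reading: a clearly positive
#' correlation supports the index's validity (more fragile departments saw
#' larger post-pandemic fertility increases), a near-zero one indicates no
#' link, and a clearly negative one contradicts the framework.
#'
#' @param scores Index scores (tibble with `department`, `effi`), e.g.
#'   `build_effi()$scores`.
#' @param deltas Outcome tibble from [delta_outcomes()] (or
#'   `segment_panel()$aggregated`).
#' @param outcomes Outcome columns to test.
#' @param threshold Absolute correlation below which the interpretation is
#'   `no_link`; default 0.1.
#' @return Tibble `pair`, `rho`, `p_value`, `n`, `method`, `interpretation`,
#'   with the per-pair scatter data (values and ranks) in attribute
#'   `scatter`.
#' @export
validate_index <- function(scores, deltas,
                           outcomes = c("z_dIFR", "z_dAFR", "z_dEFR"),
                           threshold = 0.1) {
  merged <- dplyr::inner_join(scores, deltas, by = "department")
  res <- NULL
  scatter <- NULL
  for (oc in outcomes) {
    if (!oc %in% names(merged)) {
      abort(sprintf("outcome column '%s' not found", oc),
            class = "effindex_config_error")
    }
    st <- spearman_test(merged$effi, merged[[oc]])
    interp <- if (abs(st$rho) < threshold) "no_link"
              else if (st$rho > 0) "supports_validity"
              else "contradicts_framework"
    res <- dplyr::bind_rows(res, tibble::tibble(
      pair = sprintf("EFFI~%s", oc), rho = st$rho, p_value = st$p_value,
      n = st$n, method = st$method, interpretation = interp))
    ok <- !is.na(merged$effi) & !is.na(merged[[oc]])
    scatter <- dplyr::bind_rows(scatter, tibble::tibble(
      pair = sprintf("EFFI~%s", oc),
      department = merged$department[ok],
      effi = merged$effi[ok], value = merged[[oc]][ok],
      rank_effi = rank(merged$effi[ok]), rank_value = rank(merged[[oc]][ok])))
  }
  attr(res, "scatter") <- scatter
  res
}
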