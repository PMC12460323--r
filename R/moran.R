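#' Global Moran's I with analytic inference
#'
#' Computes I = (N/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2 over a cross-section and its spatial weights,
#' together with the null expectation E[I] = -1/(N-1), the variance under
#' the randomization assumption (default) or the normality assumption,
#' the z-score, and a one-sided clustering flag at `significance_z`
#' (z > 2.58 marks significant clustering at the 99% level).
#'
#' @param x a [cross_section] (or named numeric vector) over the units of
#'   `W`.
#' @param W a [spatial_weights] object; row-standardized by default
#'   before the statistic is formed (set `standardize = FALSE` to use the
#'   weights as given, e.g. raw binary).
#' @param significance_z z threshold for the `significant` flag.
#' @param assumption `"randomization"` (default) or `"normality"`
#'   variance.
#' @param standardize row-standardize `W` first (default `TRUE`).
#' @return object of class `moran_result`: list with `I`, `expected_I`,
#'   `variance_I`, `z`, `p_analytic` (upper tail), `significant`, `n`,
#'   `assumption`.
#' @export
global_morans_i <- function(x, W, significance_z = 2.58,
                            assumption = c("randomization", "normality"),
                            standardize = TRUE) {
  assumption <- match.arg(assumption)
  v <- align_field(x, W)
  n <- length(v)
  assert_that(n >= 3, "need at least 3 units")
  if (pop_var(v) == 0) stop("degenerate field: zero variance", call. = FALSE)
  if (standardize && W$standardization != "row")
    W <- suppressWarnings(row_standardize(W))
  M <- weights_matrix(W)
  S0 <- sum(M)
  assert_that(S0 > 0, "weights have no edges")

  z0 <- v - mean(v)
  I <- (n / S0) * as.numeric(t(z0) %*% M %*% z0) / sum(z0^2)
  EI <- -1 / (n - 1)

  S1 <- 0.5 * sum((M + t(M))^2)
  S2 <- sum((rowSums(M) + colSums(M))^2)
  if (assumption == "normality") {
    VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  } else {
    b2 <- n * sum(z0^4) / (sum(z0^2)^2)   # sample kurtosis
    num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
      b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
    VI <- num / ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  assert_that(VI > 0, "non-positive Moran variance (degenerate weights)")
  z <- (I - EI) / sqrt(VI)
  structure(list(I = I, expected_I = EI, variance_I = VI, z = z,
                 p_analytic = stats::pnorm(z, lower.tail = FALSE),
                 significant = z > significance_z,
                 n = n, assumption = assumption,
                 label = attr(x, "label")),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f  (E[I] = %.4f, z = %.4f, p = %.3g, %s)%s\n",
              x$I, x$expected_I, x$z, x$p_analytic, x$assumption,
              if (isTRUE(x$significant)) "  [significant clustering]" else ""))
  invisible(x)
}

#' Permutation inference for Moran's I
#'
#' Random relabelling of the field over units; the pseudo p-value for the
#' clustering (high) tail is `(1 + #\{I_perm >= I_obs\}) / (1 + n_perm)`.
#'
#' @param x a [cross_section] over the units of `W`.
#' @param W a [spatial_weights] object.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param ... passed to [global_morans_i()] (e.g. `standardize`).
#' @return list with `pseudo_p`, `I_obs`, `I_perm` (vector), `n_perm`.
#' @export
morans_permutation <- function(x, W, n_perm = 999L, seed, ...) {
  assert_that(n_perm >= 99, "use at least 99 permutations")
  v <- align_field(x, W)
  obs <- global_morans_i(x, W, ...)$I
  # fix the standardization once so permutations reuse the same matrix
  Wr <- if (W$standardization != "row") suppressWarnings(row_standardize(W)) else W
  M <- weights_matrix(Wr)
  S0 <- sum(M); n <- length(v)
  perm_I <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      p <- sample(v)
      zc <- p - mean(p)
      (n / S0) * as.numeric(t(zc) %*% M %*% zc) / sum(zc^2)
    }, numeric(1))
  })
  list(pseudo_p = (1 + sum(perm_I >= obs)) / (1 + n_perm),
       I_obs = obs, I_perm = perm_I, n_perm = n_perm)
}

# match a field to the unit order of W (names optional when lengths agree)
align_field <- function(x, W) {
  v <- as.numeric(x)
  ids <- names(unclass(x))
  if (!is.null(ids)) {
    assert_that(setequal(ids, W$unit_ids),
                "field units do not match weights units")
    v <- v[match(W$unit_ids, ids)]
  } else {
    assert_that(length(v) == length(W$unit_ids),
                "unnamed field length differs from unit count")
  }
  v
}
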