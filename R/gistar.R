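#' Getis-Ord Gi* hot- and cold-spot statistics
#'
#' Self-inclusive local clustering z-scores: for each unit the sum of the
#' field over its neighborhood (itself plus its contiguity neighbors) is
#' compared with the expectation under spatial randomness,
#' \deqn{z_i = (\sum_j w_{ij} x_j - \bar{x} \sum_j w_{ij}) /
#'       (S \sqrt{[N \sum_j w_{ij}^2 - (\sum_j w_{ij})^2]/(N-1)})}
#' with \eqn{S = \sqrt{\sum_j x_j^2 / N - \bar{x}^2}} and sums including
#' j = i with weight 1. Units are binned by the two-sided normal
#' thresholds 1.645 / 1.960 / 2.576 into 90/95/99% hot (positive z) or
#' cold (negative z) classes.
#'
#' @param x a [cross_section] over the units of `W`.
#' @param W binary contiguity [spatial_weights] (self-inclusion is applied
#'   internally; do not pre-add self-links).
#' @param row_standardized use row-standardized self-inclusive weights
#'   instead of binary (off by default; the binary form is the classical
#'   Gi*).
#' @return object of class `gistar_result`: data frame with columns
#'   `unit`, `value`, `z`, `p` (two-sided) and `bin` in
#'   `hot99, hot95, hot90, ns, cold90, cold95, cold99`.
#' @export
getis_ord_gistar <- function(x, W, row_standardized = FALSE) {
  v <- align_field(x, W)
  n <- length(v)
  xbar <- mean(v)
  S <- sqrt(sum(v^2) / n - xbar^2)
  if (S == 0) stop("degenerate field: zero variance", call. = FALSE)

  M <- weights_matrix(W)
  if (any(M != 0 & M != 1))
    stop("Gi* expects binary contiguity weights", call. = FALSE)
  diag(M) <- 1                       # the * variant: include self
  if (row_standardized) M <- M / rowSums(M)

  islands <- W$unit_ids[lengths(W$neighbors) == 0]
  if (length(islands))
    warning("Gi* on island unit(s) uses the self term only: ",
            paste(islands, collapse = ", "), call. = FALSE)

  wsum <- rowSums(M)
  w2sum <- rowSums(M^2)
  num <- as.numeric(M %*% v) - xbar * wsum
  den <- S * sqrt(pmax(n * w2sum - wsum^2, 0) / (n - 1))
  z <- ifelse(den > 0, num / den, 0)

  bin <- gistar_bins(z)
  structure(data.frame(unit = W$unit_ids, value = v, z = z,
                       p = 2 * stats::pnorm(-abs(z)), bin = bin,
                       stringsAsFactors = FALSE),
            label = attr(x, "label"),
            class = c("gistar_result", "data.frame"))
}

# two-sided 90/95/99% confidence bins from z-scores
gistar_bins <- function(z) {
  bin <- rep("ns", length(z))
  bin[z >= 1.645] <- "hot90";  bin[z >= 1.960] <- "hot95"
  bin[z >= 2.576] <- "hot99"
  bin[z <= -1.645] <- "cold90"; bin[z <= -1.960] <- "cold95"
  bin[z <= -2.576] <- "cold99"
  factor(bin, levels = c("hot99", "hot95", "hot90", "ns",
                         "cold90", "cold95", "cold99"))
}

#' Persistence of hot and cold spots across time windows
#'
#' Tabulates each unit's Gi* bin over a sequence of windows (e.g. the six
#' five-year intervals) and counts, per unit, the windows spent at each
#' confidence class — the summary behind statements like "the core hot
#' cluster held the 99% level in every window".
#'
#' @param sections list of [getis_ord_gistar()] results over identical
#'   unit sets (>= 2 windows).
#' @return data frame: one row per unit, a `bin_<label>` column per
#'   window, plus counts `n_hot99`, `n_hot` (any hot class), `n_cold99`,
#'   `n_cold`, `n_ns`.
#' @export
hotspot_persistence <- function(sections) {
  assert_that(length(sections) >= 2, "need at least two windows")
  units <- sections[[1]]$unit
  for (s in sections)
    assert_that(identical(sort(s$unit), sort(units)),
                "window unit sets differ")
  labs <- vapply(seq_along(sections), function(i) {
    l <- attr(sections[[i]], "label")
    if (is.null(l) || l == "") sprintf("w%d", i) else l
  }, character(1))
  out <- data.frame(unit = units, stringsAsFactors = FALSE)
  binmat <- sapply(sections, function(s)
    as.character(s$bin[match(units, s$unit)]))
  colnames(binmat) <- paste0("bin_", labs)
  out <- cbind(out, as.data.frame(binmat, stringsAsFactors = FALSE))
  hot <- c("hot90", "hot95", "hot99"); cold <- c("cold90", "cold95", "cold99")
  out$n_hot99 <- rowSums(binmat == "hot99")
  out$n_hot <- rowSums(matrix(binmat %in% hot, nrow = length(units)))
  out$n_cold99 <- rowSums(binmat == "cold99")
  out$n_cold <- rowSums(matrix(binmat %in% cold, nrow = length(units)))
  out$n_ns <- rowSums(binmat == "ns")
  out
}
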