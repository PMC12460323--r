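#' Discretize a continuous covariate into ordered strata
#'
#' Converts a continuous factor into the categorical strata the
#' q-statistic requires, by one of four schemes: `equal_interval`
#' (uniform-width bins over the observed range), `quantile` (equal-count
#' bins), `natural_breaks` (Jenks variance-minimizing breaks, found by
#' exact dynamic programming), and `geometric` (bin edges in geometric
#' progression over the range, shifted positive when needed). Empty bins
#' are dropped and the stratum count adjusted.
#'
#' @param x numeric vector, finite, non-constant.
#' @param method one of `"equal_interval"`, `"quantile"`,
#'   `"natural_breaks"`, `"geometric"`.
#' @param n_classes requested number of classes (>= 2).
#' @param factor_name label carried into results.
#' @param shift allow shifting non-positive data before geometric edges
#'   (default `TRUE`; `FALSE` raises an error on non-positive minima).
#' @param breaks optional explicit bin edges (overrides `method`; used to
#'   freeze a discretization).
#' @return object of class `stratification`: list with `labels` (integer
#'   stratum per record), `n_strata`, `method`, `n_classes`, `breaks`,
#'   `factor_name`.
#' @export
discretize <- function(x, method = c("equal_interval", "geometric",
                                     "natural_breaks", "quantile"),
                       n_classes = 4L, factor_name = "x",
                       shift = TRUE, breaks = NULL) {
  method <- match.arg(method)
  assert_that(all(is.finite(x)), "x must be finite")
  assert_that(n_classes >= 2, "need at least 2 classes")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant x cannot be discretized", call. = FALSE)

  if (is.null(breaks)) {
    breaks <- switch(method,
      equal_interval = seq(rng[1], rng[2], length.out = n_classes + 1L),
      quantile = unique(stats::quantile(x, probs = seq(0, 1,
                          length.out = n_classes + 1L), names = FALSE)),
      natural_breaks = jenks_breaks(x, n_classes),
      geometric = {
        off <- 0
        if (rng[1] <= 0) {
          if (!shift)
            stop("geometric intervals need a positive range (set shift=TRUE)",
                 call. = FALSE)
          off <- 1 - rng[1]
        }
        a <- rng[1] + off; b <- rng[2] + off
        r <- (b / a)^(1 / n_classes)
        a * r^(0:n_classes) - off
      })
  }
  breaks <- sort(unique(breaks))
  if (length(breaks) < 3)
    stop("discretization collapsed to a single class", call. = FALSE)
  lab <- cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  # clamp values outside the break range (perturbed data on frozen edges)
  lab[x <= breaks[1]] <- 1L
  lab[x >= breaks[length(breaks)]] <- length(breaks) - 1L
  used <- sort(unique(lab))
  lab <- match(lab, used)               # drop empty bins, relabel 1..L
  structure(list(labels = lab, n_strata = length(used), method = method,
                 n_classes = as.integer(n_classes), breaks = breaks,
                 factor_name = factor_name),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("stratification of '%s': %s, %d strata (sizes %s)\n",
              x$factor_name, x$method, x$n_strata,
              paste(tabulate(x$labels), collapse = "/")))
  invisible(x)
}

# Exact Jenks natural breaks: dynamic programme minimizing the total
# within-class sum of squared deviations over a sorted sample (Fisher's
# optimal partition). Returns k+1 break values.
jenks_breaks <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  k <- min(k, length(unique(xs)))
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  ssd <- function(i, j) {  # within-class SSD of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, n, k)          # D[j,m]: best cost of xs[1..j] in m classes
  P <- matrix(0L, n, k)           # argmin split position
  for (j in 1:n) D[j, 1] <- ssd(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      c_ <- D[i - 1, m - 1] + ssd(i, j)
      if (c_ < D[j, m]) { D[j, m] <- c_; P[j, m] <- i }
    }
  }
  cuts <- integer(0); j <- n
  if (k > 1) for (m in k:2) { i <- P[j, m]; cuts <- c(i, cuts); j <- i - 1 }
  # break between xs[i-1] and xs[i]: use the midpoint
  inner <- vapply(cuts, function(i) (xs[i - 1] + xs[i]) / 2, numeric(1))
  c(xs[1], inner, xs[n])
}

#' The GeoDetector q-statistic with noncentral-F significance
#'
#' q = 1 - SSW/SST measures the share of the outcome variance explained
#' by a categorical stratification (1 = the strata determine the outcome
#' exactly). Significance uses the framework's noncentral-F test:
#' F = (N-L)/(L-1) * q/(1-q) against F(L-1, N-L; lambda) with
#' lambda = [sum_h ybar_h^2 - (sum_h sqrt(N_h) ybar_h)^2 / N] / sigma^2.
#'
#' @param y numeric outcome vector.
#' @param strata a `stratification` (from [discretize()]) or a vector of
#'   stratum labels aligned with `y`.
#' @return object of class `q_result`: list with `q`, `ssw`, `sst`,
#'   `F_stat`, `lambda`, `p`, `N`, `L`.
#' @export
q_statistic <- function(y, strata) {
  lab <- if (inherits(strata, "stratification")) strata$labels else strata
  assert_that(length(lab) == length(y), "strata not aligned with y")
  keep <- !is.na(lab)
  y <- y[keep]; lab <- as.character(lab[keep])
  N <- length(y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("outcome has zero variance", call. = FALSE)
  lev <- unique(lab)
  L <- length(lev)
  if (L < 2) {
    warning("single stratum: q = 0 by convention", call. = FALSE)
    return(structure(list(q = 0, ssw = sst, sst = sst, F_stat = NA_real_,
                          lambda = NA_real_, p = 1, N = N, L = 1L),
                     class = "q_result"))
  }
  Nh <- ybar_h <- numeric(L)
  ssw <- 0
  for (i in seq_len(L)) {
    yi <- y[lab == lev[i]]
    Nh[i] <- length(yi); ybar_h[i] <- mean(yi)
    ssw <- ssw + sum((yi - ybar_h[i])^2)
  }
  q <- 1 - ssw / sst
  sigma2 <- sst / N                                  # population variance
  if (L >= N || q >= 1) {
    Fs <- Inf; lambda <- NA_real_; p <- 0
  } else {
    Fs <- (N - L) / (L - 1) * q / (1 - q)
    lambda <- (sum(ybar_h^2) - sum(sqrt(Nh) * ybar_h)^2 / N) / sigma2
    # large noncentrality saturates the tail; pnbeta's precision warning
    # is immaterial there
    p <- suppressWarnings(stats::pf(Fs, L - 1, N - L, ncp = max(lambda, 0),
                                    lower.tail = FALSE))
  }
  structure(list(q = q, ssw = ssw, sst = sst, F_stat = Fs,
                 lambda = lambda, p = p, N = N, L = L),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("q = %.4f (L = %d, N = %d, F = %.3f, p = %.3g)\n",
              x$q, x$L, x$N, x$F_stat, x$p))
  invisible(x)
}

#' Search discretizations for the one maximizing explanatory power
#'
#' Evaluates the q-statistic for every (method, class-count) pair and
#' returns the winner; ties resolve to fewer classes, then the method
#' order equal interval, geometric, natural breaks, quantile.
#'
#' @param x continuous factor values.
#' @param y outcome values, aligned.
#' @param methods discretization schemes to try.
#' @param class_range integer vector of class counts (within 2..12;
#'   default 3:8).
#' @param factor_name label carried into results.
#' @return list with `stratification`, `q_result`, and `table` (the full
#'   comparison grid: method, n_classes, L, q, p).
#' @export
optimal_discretization <- function(x, y,
                                   methods = c("equal_interval", "geometric",
                                               "natural_breaks", "quantile"),
                                   class_range = 3:8,
                                   factor_name = "x") {
  assert_that(all(class_range >= 2) && all(class_range <= 12),
              "class_range must lie within [2, 12]")
  grid <- expand.grid(n_classes = sort(class_range), method = methods,
                      stringsAsFactors = FALSE)
  # method order encodes the tie-break priority
  grid$method_rank <- match(grid$method, c("equal_interval", "geometric",
                                           "natural_breaks", "quantile"))
  rows <- vector("list", nrow(grid))
  best <- NULL; best_key <- c(-Inf, Inf, Inf)
  for (i in seq_len(nrow(grid))) {
    s <- tryCatch(discretize(x, grid$method[i], grid$n_classes[i],
                             factor_name = factor_name),
                  error = function(e) NULL)
    if (is.null(s) || s$n_strata < 2) next
    qr <- q_statistic(y, s)
    rows[[i]] <- data.frame(method = grid$method[i],
                            n_classes = grid$n_classes[i],
                            L = s$n_strata, q = qr$q, p = qr$p,
                            stringsAsFactors = FALSE)
    key <- c(qr$q, grid$n_classes[i], grid$method_rank[i])
    if (key[1] > best_key[1] + 1e-12 ||
        (abs(key[1] - best_key[1]) <= 1e-12 &&
         (key[2] < best_key[2] ||
          (key[2] == best_key[2] && key[3] < best_key[3])))) {
      best <- list(stratification = s, q_result = qr)
      best_key <- key
    }
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(best))
    stop("no admissible discretization for factor ", factor_name,
         call. = FALSE)
  c(best, list(table = tab))
}

#' Classify the interaction of two stratified factors
#'
#' Computes q for each factor, overlays the two stratifications
#' (cartesian cross-classification, empty cells dropped), computes q on
#' the overlay, and classifies the interaction: weaken (nonlinear or
#' unilateral), independent (|q12 - (q1+q2)| within `tol`), or enhance
#' (bilinear when q12 exceeds both single factors, nonlinear when it
#' exceeds their sum). Independence is checked before the inequality
#' rules since exact equality never holds in floating point.
#'
#' @param y outcome vector.
#' @param s1,s2 `stratification`s over the same records.
#' @param tol equality tolerance on the q scale (default 0.01).
#' @return object of class `interaction_result`: list with `q1`, `q2`,
#'   `q12`, `category`.
#' @export
interaction_detect <- function(y, s1, s2, tol = 0.01) {
  l1 <- if (inherits(s1, "stratification")) s1$labels else s1
  l2 <- if (inherits(s2, "stratification")) s2$labels else s2
  assert_that(length(l1) == length(l2) && length(l1) == length(y),
              "stratifications must cover the same records as y")
  overlay <- paste(l1, l2, sep = ":")
  if (length(unique(overlay)) < 2)
    stop("overlay has fewer than two non-empty cells", call. = FALSE)
  q1 <- q_statistic(y, l1)$q
  q2 <- q_statistic(y, l2)$q
  q12 <- q_statistic(y, overlay)$q
  category <-
    if (abs(q12 - (q1 + q2)) <= tol) "independent"
    else if (q12 > q1 + q2) "enhance_nonlinear"
    else if (q12 > max(q1, q2)) "enhance_bilinear"
    else if (q12 < min(q1, q2)) "weaken_nonlinear"
    else "weaken_unilateral"
  structure(list(q1 = q1, q2 = q2, q12 = q12, category = category),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("q1 = %.4f, q2 = %.4f, q12 = %.4f -> %s\n",
              x$q1, x$q2, x$q12, x$category))
  invisible(x)
}

# per-window unit-level means of outcome and factors
window_means <- function(panel, factors, width = 5L) {
  out_secs <- bin_years(panel, width, "outcome")
  fac_secs <- lapply(factors, function(f) bin_years(panel, width, f))
  names(fac_secs) <- factors
  lapply(seq_along(out_secs), function(b) {
    list(label = attr(out_secs[[b]], "label"),
         y = as.numeric(out_secs[[b]]),
         x = sapply(factors, function(f) as.numeric(fac_secs[[f]][[b]])))
  })
}

# full-period unit-level means
period_means <- function(panel, factors) {
  y <- as.numeric(cumulative_surface(panel, "mean"))
  x <- sapply(factors, function(f)
    as.numeric(cumulative_surface(panel, "mean", column = f)))
  list(label = "overall", y = y, x = x)
}

#' Screen factors by explanatory power across time windows
#'
#' For each time window (per-unit window means, plus a pooled
#' whole-period window) and each factor, searches discretizations with
#' [optimal_discretization()] and reports q, its significance and the
#' within-window ranking.
#'
#' @param panel a [panel_dataset].
#' @param factors covariate names (default: all panel covariates).
#' @param alpha significance level for the `significant` flag.
#' @param width window width in years (default 5).
#' @param include_overall add the pooled full-period window.
#' @param ... passed to [optimal_discretization()].
#' @return data frame: window, factor, q, p, method, n_classes,
#'   significant, rank (1 = highest q in the window).
#' @export
factor_screen <- function(panel, factors = attr(panel, "covariates"),
                          alpha = 0.05, width = 5L,
                          include_overall = TRUE, ...) {
  wins <- window_means(panel, factors, width)
  if (include_overall) wins <- c(wins, list(period_means(panel, factors)))
  res <- lapply(wins, function(w) {
    per_factor <- lapply(factors, function(f) {
      od <- optimal_discretization(w$x[, f], w$y, factor_name = f, ...)
      data.frame(window = w$label, factor = f, q = od$q_result$q,
                 p = od$q_result$p, method = od$stratification$method,
                 n_classes = od$stratification$n_classes,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, per_factor)
    tab$significant <- tab$p < alpha
    tab$rank <- rank(-tab$q, ties.method = "first")
    tab
  })
  do.call(rbind, res)
}

#' Pairwise interaction matrix for a window of factors
#'
#' Discretizes each factor optimally against the window outcome and
#' classifies every factor pair with [interaction_detect()].
#'
#' @param y per-unit outcome values for the window.
#' @param x matrix/data frame of factor values (columns named).
#' @param ... passed to [optimal_discretization()].
#' @return list with `q_matrix` (diagonal: single-factor q; off-diagonal:
#'   pair q12) and `categories` (data frame factor1, factor2, q1, q2,
#'   q12, category).
#' @export
interaction_matrix <- function(y, x, ...) {
  x <- as.matrix(x)
  fac <- colnames(x)
  strats <- lapply(fac, function(f)
    optimal_discretization(x[, f], y, factor_name = f, ...)$stratification)
  names(strats) <- fac
  k <- length(fac)
  Q <- matrix(NA_real_, k, k, dimnames = list(fac, fac))
  rows <- list()
  for (i in seq_len(k)) {
    Q[i, i] <- q_statistic(y, strats[[i]])$q
    for (j in seq_len(k)) if (j > i) {
      ir <- interaction_detect(y, strats[[i]], strats[[j]])
      Q[i, j] <- Q[j, i] <- ir$q12
      rows[[length(rows) + 1]] <-
        data.frame(factor1 = fac[i], factor2 = fac[j], q1 = ir$q1,
                   q2 = ir$q2, q12 = ir$q12, category = ir$category,
                   stringsAsFactors = FALSE)
    }
  }
  list(q_matrix = Q, categories = do.call(rbind, rows))
}

#' Perturbation sensitivity of the factor detector
#'
#' Re-runs the factor detector after multiplying each factor's values by
#' independent Uniform(1 - f, 1 + f) noise (default f = 0.10) and
#' reports the mean relative change |q' - q| / q per factor over
#' replicates, plus the overall mean — the robustness summary judged
#' against the conventional 10% stability threshold.
#'
#' @param panel a [panel_dataset].
#' @param factors covariate names (default: all).
#' @param perturb_fraction relative perturbation half-width (default 0.10).
#' @param n_replicates perturbation replicates to average (default 20).
#' @param seed integer seed.
#' @param freeze_edges reuse the baseline bin edges on perturbed data
#'   instead of re-fitting them (default `FALSE`: edges are re-fitted with
#'   the baseline's method and class count, so classification sensitivity
#'   propagates).
#' @param ... passed to [optimal_discretization()] for the baseline fits.
#' @return object of class `sensitivity_result`: list with `table` (data
#'   frame factor, q_baseline, dq_over_q), `mean_rel_change`,
#'   `perturb_fraction`, `n_replicates`, `seed`, `stable` (mean below the
#'   0.10 threshold).
#' @export
sensitivity_analysis <- function(panel,
                                 factors = attr(panel, "covariates"),
                                 perturb_fraction = 0.10,
                                 n_replicates = 20L, seed = 1L,
                                 freeze_edges = FALSE, ...) {
  assert_that(perturb_fraction >= 0, "perturb_fraction must be >= 0")
  pm <- period_means(panel, factors)
  base <- lapply(factors, function(f)
    optimal_discretization(pm$x[, f], pm$y, factor_name = f, ...))
  names(base) <- factors

  dq <- with_seed(seed, {
    sapply(factors, function(f) {
      q0 <- base[[f]]$q_result$q
      if (q0 <= 0) {
        warning("factor '", f, "' has q = 0; relative change undefined, skipped",
                call. = FALSE)
        return(NA_real_)
      }
      s0 <- base[[f]]$stratification
      reps <- vapply(seq_len(n_replicates), function(r) {
        u <- stats::runif(length(pm$x[, f]), -perturb_fraction,
                          perturb_fraction)
        xp <- pm$x[, f] * (1 + u)
        sp <- if (freeze_edges)
          discretize(xp, s0$method, s0$n_classes, factor_name = f,
                     breaks = s0$breaks)
        else
          discretize(xp, s0$method, s0$n_classes, factor_name = f)
        qp <- q_statistic(pm$y, sp)$q
        abs(qp - q0) / q0
      }, numeric(1))
      mean(reps)
    })
  })
  tab <- data.frame(factor = factors,
                    q_baseline = vapply(base, function(b) b$q_result$q,
                                        numeric(1)),
                    dq_over_q = as.numeric(dq),
                    stringsAsFactors = FALSE)
  mean_rel <- mean(tab$dq_over_q, na.rm = TRUE)
  structure(list(table = tab, mean_rel_change = mean_rel,
                 perturb_fraction = perturb_fraction,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 stable = is.finite(mean_rel) && mean_rel < 0.10),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("sensitivity: %g%% perturbation, %d replicates; mean dq/q = %.4f (%s)\n",
              100 * x$perturb_fraction, x$n_replicates, x$mean_rel_change,
              if (x$stable) "stable, below the 10% threshold"
              else "above the 10% threshold"))
  print(x$table, ...)
  invisible(x)
}
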