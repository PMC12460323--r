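test_that("discretization schemes produce the documented bins", {
  x <- 1:10
  s_eq <- discretize(x, "equal_interval", 2)
  expect_equal(s_eq$labels, rep(1:2, each = 5))
  expect_equal(s_eq$breaks, c(1, 5.5, 10))
  s_q <- discretize(x, "quantile", 2)
  expect_equal(tabulate(s_q$labels), c(5, 5))
  expect_error(discretize(rep(3, 10)), "constant")
  expect_error(discretize(c(-2, -1, 0, 1), "geometric", 2, shift = FALSE),
               "positive range")
  # shifted geometric covers non-positive data
  s_g <- discretize(c(-2, -1, 0, 1, 5, 20), "geometric", 3)
  expect_gte(s_g$n_strata, 2)
})

test_that("natural breaks match the exhaustive threshold oracle", {
  set.seed(4)
  # two well-separated clumps: the 2-class break falls between them
  x <- c(rnorm(30, 0, 0.5), rnorm(30, 10, 0.5))
  s <- discretize(x, "natural_breaks", 2)
  expect_equal(within_class_ssd(x, s$labels), best_two_class_ssd(x),
               tolerance = 1e-10)
  expect_equal(sort(unique(s$labels[x < 5])), 1L)
  expect_equal(sort(unique(s$labels[x > 5])), 2L)
  # random data too: DP equals the exhaustive single-threshold optimum
  for (i in 1:10) {
    xr <- rnorm(40)
    sr <- discretize(xr, "natural_breaks", 2)
    expect_equal(within_class_ssd(xr, sr$labels), best_two_class_ssd(xr),
                 tolerance = 1e-10)
  }
})

test_that("q-statistic equals the record-loop oracle and honors conventions", {
  set.seed(9)
  for (rep in 1:20) {
    y <- rnorm(60)
    lab <- sample(1:4, 60, replace = TRUE)
    expect_equal(q_statistic(y, lab)$q, q_bruteforce(y, lab),
                 tolerance = 1e-12)
  }
  # piecewise-constant outcome: q = 1
  y <- rep(c(1, 5, 9), each = 10)
  expect_equal(q_statistic(y + 0, rep(1:3, each = 10))$q, 1)
  # single stratum: q = 0 with warning
  expect_warning(q0 <- q_statistic(rnorm(20), rep(1, 20)), "single stratum")
  expect_equal(q0$q, 0)
  expect_error(q_statistic(rep(2, 20), rep(1:2, 10)), "zero variance")
  # affine invariance of q
  y <- rnorm(50); lab <- sample(1:3, 50, TRUE)
  expect_equal(q_statistic(y, lab)$q, q_statistic(-4 * y + 2, lab)$q,
               tolerance = 1e-10)
})

test_that("population vs sample variance convention does not change q", {
  set.seed(2)
  y <- rnorm(80); lab <- sample(1:4, 80, TRUE)
  q <- q_statistic(y, lab)
  # SSW/SST written with sample variances: sum_h (N_h-1) s_h^2 / ((N-1) s^2)
  lev <- unique(lab)
  ssw_s <- sum(vapply(lev, function(h) {
    yh <- y[lab == h]; (length(yh) - 1) * stats::var(yh)
  }, numeric(1)))
  expect_equal(q$q, 1 - ssw_s / ((80 - 1) * stats::var(y)),
               tolerance = 1e-12)
})

test_that("noncentral-F test is calibrated under the null", {
  set.seed(31)
  for (alpha in c(0.01, 0.05)) {
    rej <- mean(vapply(1:1000, function(i) {
      y <- rnorm(48)
      lab <- sample(1:5, 48, replace = TRUE)
      q_statistic(y, lab)$p < alpha
    }, logical(1)))
    expect_lte(rej, alpha + 0.02)
  }
})

test_that("closed loop: generator target q is recovered by the detector", {
  strata <- rep(c("a", "b", "c"), each = 16)
  for (q0 in c(0.3, 0.7)) {
    s <- simulate_stratified_covariate(strata, q0, seed = 5)
    expect_equal(q_statistic(as.numeric(s$field), s$strata)$q, q0,
                 tolerance = 1e-10)
  }
})

test_that("optimal discretization finds perfect stratifications and ties break deterministically", {
  # y piecewise-constant in 3 ranges of x: 3-class candidates reach q = 1
  x <- c(runif(20, 0, 1), runif(20, 10, 11), runif(20, 20, 21))
  y <- rep(c(0, 5, 9), each = 20)
  od <- optimal_discretization(x, y, class_range = 3:5)
  expect_equal(od$q_result$q, 1, tolerance = 1e-12)
  expect_equal(od$stratification$n_classes, 3L)
  # ties at q = 1 resolve to the first-listed method
  expect_equal(od$stratification$method, "equal_interval")

  # brute-force over the grid agrees with the returned maximum
  set.seed(8)
  xg <- rnorm(100); yg <- xg^2 + rnorm(100, 0, 0.5)
  od2 <- optimal_discretization(xg, yg)
  expect_equal(od2$q_result$q, max(od2$table$q), tolerance = 1e-12)
  grid_best <- vapply(seq_len(nrow(od2$table)), function(i) {
    s <- discretize(xg, od2$table$method[i], od2$table$n_classes[i])
    q_statistic(yg, s)$q
  }, numeric(1))
  expect_equal(max(grid_best), od2$q_result$q, tolerance = 1e-12)
  expect_error(optimal_discretization(xg, yg, class_range = 13:14),
               "class_range")
})

test_that("interaction classification follows the comparison rules", {
  set.seed(14)
  n <- 300
  # correlated assignments + additive effect: bilinear enhancement
  z <- sample(1:3, n, TRUE)
  flip <- function(v) { i <- sample(n, 30); v[i] <- sample(1:3, 30, TRUE); v }
  s1 <- flip(z); s2 <- flip(z)
  y_add <- c(0, 3, 6)[z] + rnorm(n, 0, 1)
  r_add <- interaction_detect(y_add, s1, s2)
  expect_equal(r_add$category, "enhance_bilinear")
  expect_gt(r_add$q12, max(r_add$q1, r_add$q2))
  expect_lt(r_add$q12, r_add$q1 + r_add$q2)

  # XOR-style: only the joint cell determines y
  a <- sample(0:1, n, TRUE); b <- sample(0:1, n, TRUE)
  y_xor <- as.numeric(xor(a, b)) * 4 + rnorm(n, 0, 0.1)
  r_xor <- interaction_detect(y_xor, a + 1, b + 1)
  expect_equal(r_xor$category, "enhance_nonlinear")
  expect_lt(max(r_xor$q1, r_xor$q2), 0.1)
  expect_gt(r_xor$q12, 0.9)

  # duplicate factor: q12 = q1 = q2, resolved to the unilateral boundary
  s <- discretize(rnorm(n), "quantile", 4)
  y_dup <- s$labels * 2 + rnorm(n, 0, 0.5)
  r_dup <- interaction_detect(y_dup, s, s)
  expect_equal(r_dup$q12, r_dup$q1, tolerance = 1e-12)
  expect_equal(r_dup$category, "weaken_unilateral")

  # independent when q12 matches q1 + q2 within tolerance
  r_ind <- interaction_detect(y_add, s1, s2, tol = 1)
  expect_equal(r_ind$category, "independent")
  expect_error(interaction_detect(y_add, rep(1, n), rep(1, n)),
               "fewer than two")
})

test_that("full-overlay q never falls below either single-factor q", {
  set.seed(22)
  for (rep in 1:200) {
    n <- 40
    y <- rnorm(n)
    l1 <- sample(1:3, n, TRUE)
    l2 <- sample(1:3, n, TRUE)
    r <- interaction_detect(y, l1, l2)
    expect_gte(r$q12, max(r$q1, r$q2) - 1e-12)
  }
})

test_that("factor screening recovers a planted strong factor in every window", {
  W <- make_grid_weights(4, 6, "rook")
  n_units <- 24; years <- 10
  strata <- rep(c("a", "b", "c"), each = 8)
  set.seed(77)
  base <- simulate_stratified_covariate(strata, 0.8, seed = 3,
                                        unit_ids = W$unit_ids)
  units <- rep(W$unit_ids, each = years)
  df <- data.frame(unit = units, year = rep(2001:2010, n_units),
                   stringsAsFactors = FALSE)
  # outcome driven by the planted factor's stratum means, stable in time
  df$outcome <- rep(as.numeric(base$field), each = years) +
    rnorm(nrow(df), 0, 0.05)
  df$planted <- rep(as.numeric(base$field), each = years) +
    rnorm(nrow(df), 0, 0.05)
  df$noise1 <- rnorm(nrow(df))
  df$noise2 <- rnorm(nrow(df))
  p <- panel_dataset(df, covariates = c("planted", "noise1", "noise2"))
  scr <- factor_screen(p, width = 5, class_range = 2:4)
  planted_rows <- scr[scr$factor == "planted", ]
  expect_true(all(planted_rows$rank == 1))
  expect_true(all(planted_rows$significant))
  # alpha = 1 flags everything
  scr_all <- factor_screen(p, alpha = 1, width = 5, class_range = 2:4)
  expect_true(all(scr_all$significant))
})

test_that("sensitivity analysis is deterministic, zero at zero perturbation, and stable for strong factors", {
  W <- make_grid_weights(4, 6, "rook")
  years <- 10
  strata <- rep(c("a", "b", "c"), each = 8)
  base <- simulate_stratified_covariate(strata, 0.8, seed = 13,
                                        unit_ids = W$unit_ids)
  set.seed(55)
  df <- data.frame(unit = rep(W$unit_ids, each = years),
                   year = rep(2001:2010, 24),
                   stringsAsFactors = FALSE)
  df$outcome <- rep(as.numeric(base$field), each = years) +
    rnorm(nrow(df), 0, 0.05)
  df$strong <- rep(as.numeric(base$field), each = years) +
    rnorm(nrow(df), 0, 0.05)
  p <- panel_dataset(df, covariates = "strong")

  s0 <- sensitivity_analysis(p, perturb_fraction = 0, n_replicates = 3,
                             seed = 2, class_range = 2:4)
  expect_equal(s0$table$dq_over_q, 0)

  s1 <- sensitivity_analysis(p, n_replicates = 10, seed = 2,
                             class_range = 2:4)
  s2 <- sensitivity_analysis(p, n_replicates = 10, seed = 2,
                             class_range = 2:4)
  expect_identical(s1$table, s2$table)
  expect_lt(s1$mean_rel_change, 0.10)
  expect_true(s1$stable)
})
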