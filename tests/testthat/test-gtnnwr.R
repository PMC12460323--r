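test_that("split sizes follow rounded fractions with remainder to training", {
  sp <- split_data(1440, seed = 48)
  expect_equal(lengths(sp), c(train = 1080L, validation = 144L,
                              test = 216L))
  expect_equal(sort(unlist(sp)), 1:1440, ignore_attr = TRUE)
  sp2 <- split_data(1440, seed = 48)
  expect_identical(sp, sp2)
  expect_error(split_data(10), "degenerate")
  expect_warning(sp3 <- split_data(100, c(1, 0, 0), seed = 1), "empty")
  expect_length(sp3$train, 100)
})

test_that("distances are planar-Euclidean/absolute-year with leak-free scaling", {
  pts <- data.frame(x = c(0, 3), y = c(0, 4), time_coord = c(0, 0))
  D <- compute_distances(pts, pts)
  expect_equal(D$d_s[1, 2], 5)         # 3-4-5 triangle
  expect_equal(D$d_s[1, 1], 0)
  expect_equal(D$d_t, matrix(0, 2, 2))

  # bounds from the training set applied unchanged elsewhere
  tr <- data.frame(x = runif(30), y = runif(30),
                   time_coord = sample(0:9, 30, TRUE))
  te <- data.frame(x = runif(10) + 2, y = runif(10) + 2,
                   time_coord = sample(10:12, 10, TRUE))
  btr <- spatioepi:::distance_bounds(compute_distances(tr, tr))
  sc_te <- spatioepi:::scale_distances(compute_distances(te, tr), btr)
  expect_gt(max(sc_te$d_s), 1)         # test distances may exceed 1
  sc_tr <- spatioepi:::scale_distances(compute_distances(tr, tr), btr)
  expect_equal(range(sc_tr$d_s), c(0, 1), tolerance = 1e-12)
})

test_that("global OLS matches the normal-equations oracle and flags collinearity", {
  set.seed(17)
  X <- cbind(intercept = 1, a = rnorm(50), b = rnorm(50))
  beta_true <- c(1, 2, -3)
  y <- X %*% beta_true
  expect_equal(as.numeric(fit_global_ols(X, y)), beta_true,
               tolerance = 1e-10)
  # y = 2x + 1
  X2 <- cbind(intercept = 1, x = rnorm(30))
  expect_equal(as.numeric(fit_global_ols(X2, 2 * X2[, 2] + 1)), c(1, 2),
               tolerance = 1e-10)
  # random instance vs solve(t(X) X) t(X) y
  yr <- X %*% beta_true + rnorm(50)
  expect_equal(as.numeric(fit_global_ols(X, yr)),
               as.numeric(solve(crossprod(X), crossprod(X, yr))),
               tolerance = 1e-8)
  Xc <- cbind(X, dup = X[, "a"])
  expect_error(fit_global_ols(Xc, yr), "collinear.*dup")
})

test_that("metric suite equals the record-loop oracle and obeys identities", {
  set.seed(23)
  y <- rnorm(100, 50, 10); yhat <- y + rnorm(100, 1, 3)
  m <- fit_metrics(y, yhat, normalizer = diff(range(y)))
  o <- metrics_bruteforce(y, yhat, diff(range(y)))
  for (nm in names(o)) expect_equal(m[[nm]], o[[nm]], tolerance = 1e-10)
  # exact fit
  m0 <- fit_metrics(y, y, 10)
  expect_equal(m0$r2, 1); expect_equal(m0$rmse, 0)
  expect_equal(m0$mae, 0); expect_equal(m0$nmse_loss, 0)
  # constant shift: mbe = c, rmse = |c|
  mc <- fit_metrics(y, y - 2.5, 10)
  expect_equal(mc$mbe, -2.5); expect_equal(mc$rmse, 2.5)
  expect_gte(mc$rmse, abs(mc$mbe))
})

test_that("forcing unit weights reproduces global OLS predictions exactly", {
  sim <- tiny_panel()
  sp <- split_data(nrow(sim$panel), seed = 48)
  hp <- gtnnwr_hyperparams(swnn_hidden = c(16L, 8L), epochs = 5L,
                           val_interval = 2L, log_interval = 5L)
  m <- gtnnwr(sim$panel, splits = sp, hyperparams = hp, seed = 48)
  fw <- gtnnwr_forward(m, sp$test, force_unit_weights = TRUE)
  expect_equal(fw$yhat,
               as.numeric(m$X[sp$test, ] %*% m$beta_ols),
               tolerance = 1e-14)
  expect_true(all(fw$w == 1))
})

test_that("training is seed-deterministic and logs a history", {
  sim <- tiny_panel()
  hp <- gtnnwr_hyperparams(swnn_hidden = c(16L, 8L), epochs = 60L,
                           val_interval = 10L, log_interval = 20L)
  m1 <- gtnnwr(sim$panel, hyperparams = hp, seed = 48)
  m2 <- gtnnwr(sim$panel, hyperparams = hp, seed = 48)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$par, m2$par)
  expect_true(all(c("epoch", "train_nmse", "val_nmse") %in%
                    names(m1$history)))
  # different seed, different trajectory
  m3 <- gtnnwr(sim$panel, hyperparams = hp, seed = 49)
  expect_false(identical(m1$par, m3$par))
})

test_that("eval-mode forwards are identical; training mode uses dropout", {
  sim <- tiny_panel()
  hp <- gtnnwr_hyperparams(swnn_hidden = c(16L, 8L), epochs = 10L,
                           val_interval = 5L, log_interval = 10L)
  m <- gtnnwr(sim$panel, hyperparams = hp, seed = 48)
  f1 <- gtnnwr_forward(m, 1:20)
  f2 <- gtnnwr_forward(m, 1:20)
  expect_identical(f1$yhat, f2$yhat)
  expect_equal(dim(f1$w), c(20L, length(m$beta_ols)))
})

test_that("near-stationary data trains toward unit weights and OLS parity", {
  const_spec <- list(intercept = function(x, y, t) rep(2, length(x)),
                     a = function(x, y, t) rep(1.5, length(x)),
                     b = function(x, y, t) rep(-1, length(x)))
  sim <- simulate_nonstationary_panel(4, 5, 10, beta_spec = const_spec,
                                      noise_sd = 0.05, seed = 31)
  sp <- split_data(nrow(sim$panel), seed = 48)
  hp <- gtnnwr_hyperparams(swnn_hidden = c(16L, 8L), epochs = 400L,
                           dropout = 0.2, val_interval = 20L,
                           log_interval = 200L)
  m <- gtnnwr(sim$panel, splits = sp, hyperparams = hp, seed = 48)
  fw <- gtnnwr_forward(m)
  expect_lt(mean(abs(fw$w - 1)), 0.25)
  tst <- evaluate(m, "test"); ols <- evaluate(m, "test", ols = TRUE)
  # no worse than the global fit by more than 5% of its RMSE
  expect_lt(tst$rmse, ols$rmse * 1.05)
  expect_gt(evaluate(m, "train")$r2, 0.99)
})

test_that("nonstationary panels are fit better than global OLS across seeds", {
  wins <- 0L
  n_runs <- 20L
  for (s in seq_len(n_runs)) {
    sim <- simulate_nonstationary_panel(5, 5, 12, noise_sd = 0.5,
                                        seed = 500 + s)
    sp <- split_data(nrow(sim$panel), seed = s)
    hp <- gtnnwr_hyperparams(swnn_hidden = c(32L, 16L), epochs = 500L,
                             val_interval = 25L, log_interval = 500L)
    m <- gtnnwr(sim$panel, splits = sp, hyperparams = hp, seed = s)
    if (evaluate(m, "test")$rmse < evaluate(m, "test", ols = TRUE)$rmse)
      wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * n_runs))
})

test_that("coefficient surfaces rank a null covariate last", {
  sim <- tiny_panel(nrows = 4, ncols = 5, years = 10, seed = 6,
                    noise_sd = 0.3)
  sp <- split_data(nrow(sim$panel), seed = 48)
  hp <- gtnnwr_hyperparams(swnn_hidden = c(32L, 16L), epochs = 400L,
                           val_interval = 20L, log_interval = 200L)
  m <- gtnnwr(sim$panel, splits = sp, hyperparams = hp, seed = 48)
  cs <- coefficient_summary(extract_coefficients(m))
  # x3 has true coefficient 0 everywhere: lowest mean |beta| per year
  x3_ranks <- cs$rank[cs$coefficient == "x3"]
  expect_true(mean(x3_ranks == 3) >= 0.9)
  # all-ones weights give a constant surface equal to beta_ols
  fw <- gtnnwr_forward(m, 1:10, force_unit_weights = TRUE)
  B <- sweep(fw$w, 2, m$beta_ols, "*")
  expect_equal(B[1, ], m$beta_ols, ignore_attr = TRUE)
})

test_that("divergence and degenerate inputs raise errors", {
  sim <- tiny_panel()
  p_nocoord <- panel_dataset(as.data.frame(sim$panel)[,
    c("unit", "year", "outcome", "x1", "x2", "x3")])
  expect_error(gtnnwr(p_nocoord), "no coordinates")
  expect_error(evaluate(structure(list(), class = "gtnnwr_model"),
                        integer(0)), "empty split")
})
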