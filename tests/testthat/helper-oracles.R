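# Independent oracles: deliberately naive record-by-record implementations
# against which the package's vectorized statistics are checked.

# textbook double-sum Moran's I, O(N^2)
moran_bruteforce <- function(x, M) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      num <- num + M[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(M)) * num / sum((x - xb)^2)
}

# Gi* z-score for one unit from the self-inclusive binary weights row
gistar_bruteforce_one <- function(x, wrow) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  ws <- sum(wrow); w2 <- sum(wrow^2)
  (sum(wrow * x) - xbar * ws) / (S * sqrt((n * w2 - ws^2) / (n - 1)))
}

# record-loop SSW/SST q-statistic
q_bruteforce <- function(y, lab) {
  lab <- as.character(lab)
  sst <- sum((y - mean(y))^2)
  ssw <- 0
  for (h in unique(lab)) {
    yh <- y[lab == h]
    ssw <- ssw + sum((yh - mean(yh))^2)
  }
  1 - ssw / sst
}

# exhaustive single-threshold search: the 2-class Jenks oracle
best_two_class_ssd <- function(x) {
  xs <- sort(x)
  best <- Inf
  for (i in 1:(length(xs) - 1)) {
    a <- xs[1:i]; b <- xs[(i + 1):length(xs)]
    ssd <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ssd < best) best <- ssd
  }
  best
}

within_class_ssd <- function(x, lab) {
  s <- 0
  for (h in unique(lab)) {
    xh <- x[lab == h]
    s <- s + sum((xh - mean(xh))^2)
  }
  s
}

# record-loop regression metrics
metrics_bruteforce <- function(y, yhat, norm) {
  n <- length(y)
  se <- ae <- be <- 0
  for (i in seq_len(n)) {
    e <- yhat[i] - y[i]
    se <- se + e^2; ae <- ae + abs(e); be <- be + e
  }
  list(r2 = 1 - se / sum((y - mean(y))^2),
       rmse = sqrt(se / n), mae = ae / n, mbe = be / n,
       nrmse = sqrt(se / n) / norm, nmae = ae / n / norm,
       nmse_loss = se / (n * norm^2))
}

# checkerboard +-1 field on an nrows x ncols lattice from make_grid_weights
checkerboard_field <- function(W) {
  rc <- do.call(rbind, strsplit(sub("r", "", W$unit_ids), "c"))
  parity <- (as.integer(rc[, 1]) + as.integer(rc[, 2])) %% 2
  cross_section(W$unit_ids, ifelse(parity == 0, 1, -1),
                label = "checkerboard")
}

# small panel for IO / GTNNWR unit tests
tiny_panel <- function(nrows = 3, ncols = 4, years = 6, seed = 5,
                       noise_sd = 0.3) {
  simulate_nonstationary_panel(nrows, ncols, years, noise_sd = noise_sd,
                               seed = seed)
}
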