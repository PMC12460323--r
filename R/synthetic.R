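#' Lattice contiguity weights for synthetic studies
#'
#' Builds rook or queen contiguity on an `nrows` x `ncols` grid. Unit ids
#' are `"r<row>c<col>"`; centroid coordinates (col, row) are attached so
#' the same lattice feeds the spatiotemporal regression. The 6 x 8 default
#' used throughout the synthetic studies mirrors a 48-unit contiguous
#' study area.
#'
#' @param nrows,ncols grid dimensions (both >= 2 for a meaningful graph,
#'   1 x 2 minimum).
#' @param scheme `"rook"` (edge-sharing) or `"queen"` (edge or corner).
#' @return binary symmetric [spatial_weights] with a `coords` attribute
#'   (data frame: unit, x = column, y = row).
#' @export
make_grid_weights <- function(nrows = 6L, ncols = 8L,
                              scheme = c("rook", "queen")) {
  scheme <- match.arg(scheme)
  assert_that(nrows >= 1 && ncols >= 1 && nrows * ncols >= 2,
              "grid must contain at least two cells")
  grid <- expand.grid(col = seq_len(ncols), row = seq_len(nrows))
  ids <- sprintf("r%dc%d", grid$row, grid$col)
  offsets <- if (scheme == "rook")
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(rep(c(-1, 0, 1), each = 3), rep(c(-1, 0, 1), 3))[-5, ]
  nbrs <- lapply(seq_len(nrow(grid)), function(i) {
    rr <- grid$row[i] + offsets[, 1]
    cc <- grid$col[i] + offsets[, 2]
    ok <- rr >= 1 & rr <= nrows & cc >= 1 & cc <= ncols
    sprintf("r%dc%d", rr[ok], cc[ok])
  })
  W <- spatial_weights(ids, nbrs)
  attr(W, "coords") <- data.frame(unit = ids, x = grid$col, y = grid$row,
                                  stringsAsFactors = FALSE)
  W
}

#' Simulate a spatially autocorrelated field (simultaneous autoregression)
#'
#' Draws y = (I - rho W)^-1 eps with eps iid Normal(0, sigma^2) on the
#' row-standardized weights, giving fields whose clustering strength is
#' controlled by `rho`: rho = 0 is iid noise (expected Moran's I of
#' -1/(N-1)); rho near 1 gives strong positive autocorrelation.
#'
#' @param W a [spatial_weights] object; row-standardized internally if not
#'   already.
#' @param rho spatial autoregressive strength, |rho| < 1.
#' @param sigma innovation standard deviation.
#' @param seed integer seed.
#' @return a [cross_section] over `W$unit_ids`.
#' @export
simulate_sar_field <- function(W, rho, sigma = 1, seed) {
  assert_that(abs(rho) < 1, "|rho| must be < 1 for a stable SAR field")
  if (W$standardization != "row") W <- suppressWarnings(row_standardize(W))
  M <- weights_matrix(W)
  n <- nrow(M)
  A <- diag(n) - rho * M
  if (abs(det(A)) < 1e-12)
    stop("(I - rho W) is singular; choose a smaller |rho|", call. = FALSE)
  eps <- with_seed(seed, stats::rnorm(n, 0, sigma))
  y <- solve(A, eps)
  cross_section(W$unit_ids, y, label = sprintf("SAR rho=%g seed=%d",
                                               rho, as.integer(seed)))
}

#' Simulate a covariate field with exact stratified explanatory power
#'
#' Constructs values over units such that the stratification `strata`
#' explains exactly `target_q` of the variance in the q-statistic sense
#' (1 - SSW/SST): stratum means are separated, residuals are centered
#' within each stratum, and the residual scale is solved so the realized
#' ratio matches the request to machine precision. This closed-loop
#' construction is the ground truth against which the factor detector is
#' validated.
#'
#' @param strata per-unit stratum labels (>= 2 strata, each >= 2 members).
#' @param target_q requested q in `[0, 1]`.
#' @param seed integer seed.
#' @param noise_sd within-stratum residual scale before rescaling; must be
#'   0 when `target_q = 1` (a perfectly determined field has no residual).
#' @param unit_ids optional ids (default `u1..un`).
#' @return list with `field` (a [cross_section]), `realized_q`, `strata`.
#' @export
simulate_stratified_covariate <- function(strata, target_q, seed,
                                          noise_sd = 1,
                                          unit_ids = NULL) {
  strata <- as.character(strata)
  n <- length(strata)
  tab <- table(strata)
  assert_that(length(tab) >= 2, "need at least two strata")
  assert_that(all(tab >= 2), "each stratum needs at least two members")
  assert_that(target_q >= 0 && target_q <= 1, "target_q must be in [0, 1]")
  if (target_q == 1 && noise_sd > 0)
    stop("target_q = 1 is incompatible with nonzero within-stratum noise",
         call. = FALSE)
  if (is.null(unit_ids)) unit_ids <- sprintf("u%d", seq_len(n))

  lev <- names(tab)
  L <- length(lev)
  # residuals centered within stratum
  r <- with_seed(seed, stats::rnorm(n, 0, max(noise_sd, 1)))
  for (h in lev) {
    idx <- strata == h
    r[idx] <- r[idx] - mean(r[idx])
  }
  if (noise_sd == 0) r[] <- 0

  if (target_q == 0) {
    mu <- rep(0, n)              # equal stratum means: SSB = 0 exactly
    y <- mu + r
  } else {
    mu_h <- stats::setNames(seq_len(L), lev)   # distinct stratum means
    mu <- mu_h[strata]
    ssb <- sum((mu - mean(mu))^2)
    ssw_raw <- sum(r^2)
    if (target_q == 1) {
      y <- mu
    } else {
      assert_that(ssw_raw > 0, "degenerate residuals; change seed")
      # solve c so that ssw / (ssw + ssb) = 1 - q
      cc <- sqrt(ssb * (1 - target_q) / (target_q * ssw_raw))
      y <- mu + cc * r
    }
  }
  realized <- 1 - {
    ssw <- 0
    for (h in lev) { idx <- strata == h; ssw <- ssw + sum((y[idx] - mean(y[idx]))^2) }
    ssw / sum((y - mean(y))^2)
  }
  list(field = cross_section(unit_ids, y,
                             label = sprintf("stratified q=%g", target_q)),
       realized_q = realized,
       strata = stats::setNames(strata, unit_ids))
}

#' Default coefficient surfaces for the nonstationary generator
#'
#' Three covariates: a coefficient ramping linearly in the grid column and
#' in time (the nonstationary signal), a constant coefficient, and a null
#' coefficient (a covariate with no effect), plus an intercept surface
#' varying in the row direction and drifting down in time.
#'
#' @param nrows,ncols,years generator dimensions the ramps are scaled by.
#' @return named list of functions `f(x, y, t)` (x = column, y = row,
#'   t = year offset starting at 0); first element is the intercept.
#' @export
default_beta_spec <- function(nrows = 6L, ncols = 8L, years = 30L) {
  list(
    intercept = function(x, y, t) 2 + 0.5 * y / nrows - 0.3 * t / years,
    x1 = function(x, y, t) 1 + 0.5 * x / ncols + 0.3 * t / years,
    x2 = function(x, y, t) rep(0.5, length(x)),
    x3 = function(x, y, t) rep(0, length(x))
  )
}

#' Simulate a panel with spatiotemporally varying coefficients
#'
#' Generates a lattice panel in which the outcome follows
#' `y(i,t) = b0(i,t) + sum_k bk(i,t) x_k(i,t) + Normal(0, noise_sd^2)`
#' with iid standard-Normal covariates and coefficient surfaces supplied
#' as functions of grid column, grid row and year offset. The returned
#' truth (true coefficient values per record) is the recovery target for
#' the spatiotemporal regression.
#'
#' @param nrows,ncols lattice dimensions.
#' @param years number of yearly observations per unit.
#' @param beta_spec named list of surface functions, intercept first
#'   (default [default_beta_spec()]).
#' @param noise_sd observation noise standard deviation.
#' @param seed integer seed.
#' @param start_year first calendar year (labels only).
#' @return list with `panel` (a [panel_dataset] with coordinates),
#'   `weights` (rook lattice [spatial_weights]), and `truth` (list:
#'   `beta` record-by-coefficient matrix, `beta_spec`, `noise_sd`, `seed`).
#' @export
simulate_nonstationary_panel <- function(nrows = 6L, ncols = 8L,
                                         years = 30L,
                                         beta_spec = NULL,
                                         noise_sd = 0.5, seed = 1L,
                                         start_year = 1991L) {
  if (is.null(beta_spec)) beta_spec <- default_beta_spec(nrows, ncols, years)
  assert_that(length(beta_spec) >= 2,
              "beta_spec needs an intercept plus at least one covariate")
  W <- make_grid_weights(nrows, ncols, "rook")
  coords <- attr(W, "coords")
  k <- length(beta_spec) - 1L
  grid <- coords[rep(seq_len(nrow(coords)), each = years), ]
  t_off <- rep(seq_len(years) - 1L, times = nrow(coords))

  B <- sapply(beta_spec, function(f) f(grid$x, grid$y, t_off))
  X <- with_seed(seed, matrix(stats::rnorm(nrow(grid) * k), ncol = k))
  eps <- with_seed(seed + 1L, stats::rnorm(nrow(grid), 0, noise_sd))
  y <- B[, 1] + rowSums(B[, -1, drop = FALSE] * X) + eps

  cov_names <- names(beta_spec)[-1]
  df <- data.frame(unit = grid$unit, year = start_year + t_off,
                   outcome = y, x = grid$x, y = grid$y,
                   stringsAsFactors = FALSE)
  for (j in seq_len(k)) df[[cov_names[j]]] <- X[, j]
  panel <- panel_dataset(df, covariates = cov_names, coords = c("x", "y"))

  # truth rows must align with the panel's (unit, year) ordering
  ord <- order(grid$unit, start_year + t_off)
  truth <- list(beta = B[ord, , drop = FALSE], beta_spec = beta_spec,
                noise_sd = noise_sd, seed = as.integer(seed),
                nrows = nrows, ncols = ncols, years = years)
  list(panel = panel, weights = W, truth = truth)
}
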