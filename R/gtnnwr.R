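#' Train/validation/test split of panel records
#'
#' Random, disjoint, exhaustive partition of record indices. Sizes are
#' the rounded fractions of N with the remainder assigned to training;
#' the default 75/10/15 split under seed 48 reproduces the study's
#' hold-out design (1440 records give 1080/144/216).
#'
#' @param n record count, or a [panel_dataset].
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed (default 48).
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
split_data <- function(n, fractions = c(0.75, 0.10, 0.15), seed = 48L) {
  if (inherits(n, "panel_dataset")) n <- nrow(n)
  assert_that(abs(sum(fractions) - 1) < 1e-9, "fractions must sum to 1")
  assert_that(n >= 20, "fewer than 20 records: split would be degenerate")
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_val == 0 || n_test == 0)
    warning("empty validation and/or test split", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Spatial and temporal distances between estimation points and references
#'
#' Planar Euclidean spatial distance and absolute year difference between
#' each estimation point and each reference (training) sample. Min-max
#' scaling bounds are learned from the training-vs-training distances and
#' applied unchanged everywhere else, so validation/test distances can
#' exceed 1 without leaking information into the scaling.
#'
#' @param points data frame with columns `x`, `y`, `time_coord`.
#' @param references same layout (the training samples).
#' @return list with matrices `d_s`, `d_t` (points x references),
#'   unscaled.
#' @export
compute_distances <- function(points, references) {
  for (cc in c("x", "y", "time_coord")) {
    assert_that(cc %in% names(points) && !anyNA(points[[cc]]),
                paste("points missing coordinate", cc))
    assert_that(cc %in% names(references) && !anyNA(references[[cc]]),
                paste("references missing coordinate", cc))
  }
  dx <- outer(points$x, references$x, "-")
  dy <- outer(points$y, references$y, "-")
  list(d_s = sqrt(dx^2 + dy^2),
       d_t = abs(outer(points$time_coord, references$time_coord, "-")))
}

# min-max bounds from training distances; scaling is (d - min)/(max - min)
distance_bounds <- function(D) {
  b <- list(s = range(D$d_s), t = range(D$d_t))
  if (diff(b$s) == 0) b$s[2] <- b$s[1] + 1
  if (diff(b$t) == 0) b$t[2] <- b$t[1] + 1
  b
}

scale_distances <- function(D, bounds) {
  list(d_s = (D$d_s - bounds$s[1]) / diff(bounds$s),
       d_t = (D$d_t - bounds$t[1]) / diff(bounds$t))
}

# compress an (n x m) pair grid to unique (d_s, d_t) rows: the fused
# distance only depends on the pair of locations/years, so on a lattice
# panel the STPNN need only run over the unique pairs.
compress_pairs <- function(Ds, Dt) {
  key <- paste(as.vector(Ds), as.vector(Dt))
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  list(U = cbind(as.vector(Ds)[first], as.vector(Dt)[first]),
       idx = idx, dim = dim(Ds))
}

#' Hyperparameters of the spatiotemporal weighted regression
#'
#' Defaults follow the study configuration: architecture
#' `[[3], [512, 256, 64]]` (proximity-network hidden widths, then
#' weight-network hidden widths), dropout 0.4, Adadelta with a multistep
#' learning-rate schedule (milestones 1000/2000/3000/4000, factor 0.8),
#' 15,000 epochs, log interval 1000.
#'
#' @param stpnn_hidden hidden widths of the distance-fusion network.
#' @param swnn_hidden hidden widths of the weight network.
#' @param dropout dropout probability on weight-network hidden layers.
#' @param epochs training epochs.
#' @param lr base learning-rate factor for Adadelta (1 is the
#'   conventional choice).
#' @param milestones epochs at which the learning-rate factor is
#'   multiplied by `gamma`.
#' @param gamma multiplicative learning-rate decay at each milestone.
#' @param adadelta_rho,adadelta_eps Adadelta accumulator decay and
#'   stabilizer.
#' @param log_interval epochs between history log entries.
#' @param val_interval epochs between validation checks (the best
#'   validation snapshot is retained).
#' @param patience validation checks without improvement before stopping
#'   early (`Inf` disables early stopping).
#' @param leaky_slope negative slope of the leaky-rectifier activation.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @return named list of hyperparameters.
#' @export
gtnnwr_hyperparams <- function(stpnn_hidden = c(3L),
                               swnn_hidden = c(512L, 256L, 64L),
                               dropout = 0.4,
                               epochs = 15000L,
                               lr = 1,
                               milestones = c(1000L, 2000L, 3000L, 4000L),
                               gamma = 0.8,
                               adadelta_rho = 0.95,
                               adadelta_eps = 1e-6,
                               log_interval = 1000L,
                               val_interval = 25L,
                               patience = Inf,
                               leaky_slope = 0.01,
                               bn_momentum = 0.1) {
  list(stpnn_hidden = stpnn_hidden, swnn_hidden = swnn_hidden,
       dropout = dropout, epochs = as.integer(epochs), lr = lr,
       milestones = milestones, gamma = gamma,
       adadelta_rho = adadelta_rho, adadelta_eps = adadelta_eps,
       log_interval = as.integer(log_interval),
       val_interval = as.integer(val_interval), patience = patience,
       leaky_slope = leaky_slope, bn_momentum = bn_momentum)
}

#' Global ordinary least squares on the training split
#'
#' The global coefficients the network weights modulate. Rank deficiency
#' is a hard error naming the collinear columns.
#'
#' @param X design matrix including an intercept column.
#' @param y outcome vector.
#' @return named coefficient vector.
#' @export
fit_global_ols <- function(X, y) {
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.numeric(qr.coef(qr_, y)), colnames(X))
}

# ---- network internals ------------------------------------------------

lrelu <- function(z, slope) ifelse(z > 0, z, slope * z)
lrelu_grad <- function(z, slope) ifelse(z > 0, 1, slope)

he_init <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)),
         fan_in, fan_out)
}

init_params <- function(hp, n_ref, p1) {
  par <- list()
  # distance-fusion network: 2 -> hidden -> 1
  widths <- c(2L, hp$stpnn_hidden, 1L)
  for (l in seq_len(length(widths) - 1L)) {
    par[[paste0("st_W", l)]] <- he_init(widths[l], widths[l + 1])
    par[[paste0("st_b", l)]] <- rep(0, widths[l + 1])
  }
  # weight network: n_ref -> hidden (BN) -> p1, output biased at 1 so the
  # model starts at the global least-squares fit
  widths <- c(n_ref, hp$swnn_hidden, p1)
  nh <- length(hp$swnn_hidden)
  for (l in seq_len(nh)) {
    par[[paste0("sw_W", l)]] <- he_init(widths[l], widths[l + 1])
    par[[paste0("sw_b", l)]] <- rep(0, widths[l + 1])
    par[[paste0("sw_g", l)]] <- rep(1, widths[l + 1])   # BN scale
    par[[paste0("sw_be", l)]] <- rep(0, widths[l + 1])  # BN shift
  }
  par$sw_Wout <- 0.01 * he_init(widths[nh + 1], p1)
  par$sw_bout <- rep(1, p1)
  par
}

init_bn_state <- function(hp) {
  lapply(seq_along(hp$swnn_hidden), function(l)
    list(mean = rep(0, hp$swnn_hidden[l]),
         var = rep(1, hp$swnn_hidden[l])))
}

stpnn_forward <- function(par, hp, U) {
  nl <- length(hp$stpnn_hidden) + 1L
  H <- U; cache <- list(H0 = U)
  for (l in seq_len(nl)) {
    Z <- sweep(H %*% par[[paste0("st_W", l)]], 2,
               par[[paste0("st_b", l)]], "+")
    cache[[paste0("Z", l)]] <- Z
    H <- if (l < nl) lrelu(Z, hp$leaky_slope) else Z
    cache[[paste0("H", l)]] <- H
  }
  list(out = as.numeric(H), cache = cache)
}

stpnn_backward <- function(par, hp, cache, dout) {
  nl <- length(hp$stpnn_hidden) + 1L
  grads <- list()
  dH <- matrix(dout, ncol = 1)
  for (l in rev(seq_len(nl))) {
    dZ <- if (l < nl)
      dH * lrelu_grad(cache[[paste0("Z", l)]], hp$leaky_slope)
    else dH
    Hprev <- cache[[paste0("H", l - 1)]]
    if (l == 1) Hprev <- cache$H0
    grads[[paste0("st_W", l)]] <- crossprod(Hprev, dZ)
    grads[[paste0("st_b", l)]] <- colSums(dZ)
    if (l > 1) dH <- dZ %*% t(par[[paste0("st_W", l)]])
  }
  grads
}

swnn_forward <- function(par, hp, D, bn_state, training, masks = NULL) {
  nh <- length(hp$swnn_hidden)
  A <- D
  cache <- list(A0 = D)
  new_bn <- bn_state
  eps <- 1e-5
  for (l in seq_len(nh)) {
    Z <- sweep(A %*% par[[paste0("sw_W", l)]], 2,
               par[[paste0("sw_b", l)]], "+")
    if (training) {
      mu <- colMeans(Z)
      vr <- colMeans(sweep(Z, 2, mu)^2)
      new_bn[[l]]$mean <- (1 - hp$bn_momentum) * bn_state[[l]]$mean +
        hp$bn_momentum * mu
      new_bn[[l]]$var <- (1 - hp$bn_momentum) * bn_state[[l]]$var +
        hp$bn_momentum * vr
    } else {
      mu <- bn_state[[l]]$mean
      vr <- bn_state[[l]]$var
    }
    inv_sd <- 1 / sqrt(vr + eps)
    Znorm <- sweep(sweep(Z, 2, mu), 2, inv_sd, "*")
    Zbn <- sweep(sweep(Znorm, 2, par[[paste0("sw_g", l)]], "*"), 2,
                 par[[paste0("sw_be", l)]], "+")
    H <- lrelu(Zbn, hp$leaky_slope)
    if (training && hp$dropout > 0) {
      H <- H * masks[[l]]
    }
    cache[[paste0("Z", l)]] <- Z
    cache[[paste0("Znorm", l)]] <- Znorm
    cache[[paste0("Zbn", l)]] <- Zbn
    cache[[paste0("inv_sd", l)]] <- inv_sd
    cache[[paste0("A", l)]] <- H
    A <- H
  }
  Wmat <- sweep(A %*% par$sw_Wout, 2, par$sw_bout, "+")
  cache$Wmat <- Wmat
  list(Wmat = Wmat, cache = cache, bn_state = new_bn)
}

swnn_backward <- function(par, hp, cache, dWmat, masks) {
  nh <- length(hp$swnn_hidden)
  grads <- list()
  Alast <- cache[[paste0("A", nh)]]
  grads$sw_Wout <- crossprod(Alast, dWmat)
  grads$sw_bout <- colSums(dWmat)
  dA <- dWmat %*% t(par$sw_Wout)
  B <- nrow(dWmat)
  for (l in rev(seq_len(nh))) {
    if (hp$dropout > 0 && !is.null(masks)) dA <- dA * masks[[l]]
    dZbn <- dA * lrelu_grad(cache[[paste0("Zbn", l)]], hp$leaky_slope)
    Znorm <- cache[[paste0("Znorm", l)]]
    grads[[paste0("sw_g", l)]] <- colSums(dZbn * Znorm)
    grads[[paste0("sw_be", l)]] <- colSums(dZbn)
    dZnorm <- sweep(dZbn, 2, par[[paste0("sw_g", l)]], "*")
    inv_sd <- cache[[paste0("inv_sd", l)]]
    # batch-norm backward through batch statistics
    s1 <- colSums(dZnorm)
    s2 <- colSums(dZnorm * Znorm)
    dZ <- sweep(sweep(sweep(B * dZnorm, 2, s1, "-") -
                        sweep(Znorm, 2, s2, "*"),
                      2, inv_sd / B, "*"), 2, 1, "*")
    Aprev <- if (l == 1) cache$A0 else cache[[paste0("A", l - 1)]]
    grads[[paste0("sw_W", l)]] <- crossprod(Aprev, dZ)
    grads[[paste0("sw_b", l)]] <- colSums(dZ)
    if (l > 1) dA <- dZ %*% t(par[[paste0("sw_W", l)]])
    else dA0 <- dZ %*% t(par[[paste0("sw_W", l)]])
  }
  grads$dInput <- dA0
  grads
}

adadelta_init <- function(par) {
  list(Eg = lapply(par, function(p) p * 0),
       Ed = lapply(par, function(p) p * 0))
}

adadelta_step <- function(par, grads, state, hp, lr_factor) {
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$Eg[[nm]] <- hp$adadelta_rho * state$Eg[[nm]] +
      (1 - hp$adadelta_rho) * g^2
    delta <- -sqrt(state$Ed[[nm]] + hp$adadelta_eps) /
      sqrt(state$Eg[[nm]] + hp$adadelta_eps) * g * (hp$lr * lr_factor)
    state$Ed[[nm]] <- hp$adadelta_rho * state$Ed[[nm]] +
      (1 - hp$adadelta_rho) * delta^2
    par[[nm]] <- par[[nm]] + delta
  }
  list(par = par, state = state)
}

# forward pass for a set of points given compressed scaled distances
gtnnwr_eval_forward <- function(par, hp, comp, X, beta_ols, bn_state,
                                training = FALSE, masks = NULL) {
  st <- stpnn_forward(par, hp, comp$U)
  D <- matrix(st$out[comp$idx], comp$dim[1], comp$dim[2])
  sw <- swnn_forward(par, hp, D, bn_state, training, masks)
  Xb <- sweep(X, 2, beta_ols, "*")
  yhat <- as.numeric(rowSums(sw$Wmat * Xb))
  list(yhat = yhat, Wmat = sw$Wmat, D = D, Xb = Xb,
       st = st, sw = sw)
}

#' Fit the geographically and temporally weighted neural regression
#'
#' Two small networks sit on top of a global ordinary-least-squares fit:
#' a proximity network fuses min-max-scaled spatial and temporal
#' distances between each estimation point and every training sample
#' into one spatiotemporal proximity, and a weight network maps each
#' point's proximity profile to one multiplicative weight per
#' coefficient (intercept included). Predictions are
#' `yhat_i = sum_k w_ik * beta_k^OLS * x_ik`; training minimizes the
#' normalized mean squared error `sum (yhat - y)^2 / (n * normalizer^2)`
#' on the training split, with the best-validation parameter snapshot
#' retained.
#'
#' @param panel a [panel_dataset] with coordinates.
#' @param covariates covariate names entering the regression (default:
#'   all panel covariates).
#' @param splits record-index splits from [split_data()] (default:
#'   75/10/15 at seed 48).
#' @param hyperparams from [gtnnwr_hyperparams()].
#' @param seed seed for initialization and dropout.
#' @param normalizer `"range"` (default: training-outcome range),
#'   `"mean"`, or a positive number; divides RMSE/MAE into their
#'   normalized forms and squares into the NMSE loss.
#' @param verbose print history at each log interval.
#' @return object of class `gtnnwr_model`.
#' @export
gtnnwr <- function(panel, covariates = attr(panel, "covariates"),
                   splits = NULL, hyperparams = gtnnwr_hyperparams(),
                   seed = 48L, normalizer = "range", verbose = FALSE) {
  hp <- hyperparams
  assert_that(!is.null(attr(panel, "coords")),
              "panel has no coordinates; GTNNWR needs planar (x, y)")
  if (is.null(splits)) splits <- split_data(nrow(panel), seed = 48L)
  tr <- splits$train; va <- splits$validation; te <- splits$test
  assert_that(length(tr) >= 2, "empty training split")

  X <- cbind(intercept = 1,
             as.matrix(as.data.frame(panel)[, covariates, drop = FALSE]))
  y <- panel$outcome
  pts <- data.frame(x = panel$x, y = panel$y,
                    time_coord = panel$time_coord)
  beta_ols <- fit_global_ols(X[tr, , drop = FALSE], y[tr])
  p1 <- length(beta_ols)

  norm_val <- if (is.numeric(normalizer)) normalizer
  else if (normalizer == "range") diff(range(y[tr]))
  else if (normalizer == "mean") mean(y[tr])
  else stop("unknown normalizer", call. = FALSE)
  assert_that(is.finite(norm_val) && norm_val > 0,
              "normalizer must be positive")

  Dtr <- compute_distances(pts[tr, ], pts[tr, ])
  bounds <- distance_bounds(Dtr)
  sc_tr <- scale_distances(Dtr, bounds)
  comp_tr <- compress_pairs(sc_tr$d_s, sc_tr$d_t)
  comp_va <- if (length(va)) {
    sc <- scale_distances(compute_distances(pts[va, ], pts[tr, ]), bounds)
    compress_pairs(sc$d_s, sc$d_t)
  }

  par <- with_seed(seed, init_params(hp, length(tr), p1))
  bn_state <- init_bn_state(hp)
  opt <- adadelta_init(par)
  n_tr <- length(tr)
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xbtr <- sweep(Xtr, 2, beta_ols, "*")

  history <- list()
  best <- list(val = Inf, par = par, bn = bn_state, epoch = 0L)
  bad_checks <- 0L
  lr_factor <- 1

  nmse <- function(yh, yy) sum((yh - yy)^2) / (length(yy) * norm_val^2)

  with_seed(seed + 1L, {
    for (epoch in seq_len(hp$epochs)) {
      if (epoch %in% hp$milestones) lr_factor <- lr_factor * hp$gamma
      masks <- if (hp$dropout > 0)
        lapply(hp$swnn_hidden, function(w)
          matrix(stats::rbinom(n_tr * w, 1, 1 - hp$dropout) /
                   (1 - hp$dropout), n_tr, w))
      fw <- gtnnwr_eval_forward(par, hp, comp_tr, Xtr, beta_ols,
                                bn_state, training = TRUE, masks = masks)
      bn_state <- fw$sw$bn_state
      loss <- nmse(fw$yhat, ytr)
      if (!is.finite(loss))
        stop(sprintf("training diverged at epoch %d (non-finite loss)",
                     epoch), call. = FALSE)
      dyhat <- 2 * (fw$yhat - ytr) / (n_tr * norm_val^2)
      dWmat <- dyhat * fw$Xb
      swg <- swnn_backward(par, hp, fw$sw$cache, dWmat, masks)
      dD <- swg$dInput
      dout_u <- as.numeric(rowsum(as.vector(dD), comp_tr$idx))
      stg <- stpnn_backward(par, hp, fw$st$cache, dout_u)
      step <- adadelta_step(par, c(swg[names(swg) != "dInput"], stg),
                            opt, hp, lr_factor)
      par <- step$par; opt <- step$state

      if (!is.null(comp_va) &&
          (epoch %% hp$val_interval == 0 || epoch == hp$epochs)) {
        vfw <- gtnnwr_eval_forward(par, hp, comp_va,
                                   X[va, , drop = FALSE], beta_ols,
                                   bn_state, training = FALSE)
        vloss <- nmse(vfw$yhat, y[va])
        if (vloss < best$val) {
          best <- list(val = vloss, par = par, bn = bn_state,
                       epoch = epoch)
          bad_checks <- 0L
        } else {
          bad_checks <- bad_checks + 1L
          if (bad_checks >= hp$patience) break
        }
      }
      if (epoch %% hp$log_interval == 0 || epoch == 1L) {
        history[[length(history) + 1]] <-
          data.frame(epoch = epoch, train_nmse = loss,
                     val_nmse = if (is.null(comp_va)) NA_real_
                     else best$val, lr_factor = lr_factor)
        if (verbose)
          message(sprintf("epoch %6d  train NMSE %.6f  best val NMSE %s",
                          epoch, loss,
                          if (is.null(comp_va)) "-"
                          else sprintf("%.6f", best$val)))
      }
    }
  })
  if (is.infinite(best$val)) best <- list(val = NA_real_, par = par,
                                          bn = bn_state, epoch = hp$epochs)
  structure(list(par = best$par, bn_state = best$bn,
                 best_epoch = best$epoch,
                 final_par = par, hyperparams = hp,
                 beta_ols = beta_ols, covariates = covariates,
                 normalizer = norm_val, bounds = bounds,
                 splits = splits, panel = panel, X = X, y = y,
                 points = pts, seed = as.integer(seed),
                 history = do.call(rbind, history)),
            class = "gtnnwr_model")
}

#' @export
print.gtnnwr_model <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf(paste0("gtnnwr_model: %d train / %d val / %d test records, ",
                     "%d coefficients\n"),
              length(x$splits$train), length(x$splits$validation),
              length(x$splits$test), length(x$beta_ols)))
  cat(sprintf("architecture [[%s], [%s]], dropout %.2g, best epoch %d\n",
              paste(hp$stpnn_hidden, collapse = ", "),
              paste(hp$swnn_hidden, collapse = ", "),
              hp$dropout, x$best_epoch))
  invisible(x)
}

#' Forward pass of a fitted model over panel records
#'
#' Evaluation-mode forward pass (no dropout, running batch-norm
#' statistics) against the training reference set.
#'
#' @param model a fitted `gtnnwr_model`.
#' @param idx record indices into the model's panel (default: all).
#' @param force_unit_weights replace the network weights by 1, reducing
#'   the prediction to the global least-squares fit exactly.
#' @return list with `yhat`, `w` (records x coefficients weight matrix),
#'   `d_st` (fused proximity matrix).
#' @export
gtnnwr_forward <- function(model, idx = seq_len(nrow(model$panel)),
                           force_unit_weights = FALSE) {
  tr <- model$splits$train
  X <- model$X[idx, , drop = FALSE]
  if (force_unit_weights) {
    Wmat <- matrix(1, length(idx), length(model$beta_ols))
    Xb <- sweep(X, 2, model$beta_ols, "*")
    return(list(yhat = as.numeric(rowSums(Wmat * Xb)), w = Wmat,
                d_st = NULL))
  }
  sc <- scale_distances(compute_distances(model$points[idx, ],
                                          model$points[tr, ]),
                        model$bounds)
  comp <- compress_pairs(sc$d_s, sc$d_t)
  fw <- gtnnwr_eval_forward(model$par, model$hyperparams, comp, X,
                            model$beta_ols, model$bn_state,
                            training = FALSE)
  list(yhat = fw$yhat, w = fw$Wmat, d_st = fw$D)
}

#' Fit metrics on a split
#'
#' R^2, RMSE, MAE, MBE and their normalized forms (NRMSE, NMAE, the NMSE
#' loss) for the model predictions on a stored split.
#'
#' @param model fitted `gtnnwr_model`.
#' @param split `"train"`, `"validation"`, `"test"`, or an integer index
#'   vector.
#' @param ols evaluate the global least-squares baseline instead of the
#'   network.
#' @return named list of metrics (class `fit_metrics`).
#' @export
evaluate <- function(model, split = "test", ols = FALSE) {
  idx <- if (is.character(split))
    switch(split, train = model$splits$train,
           validation = model$splits$validation,
           test = model$splits$test,
           stop("unknown split: ", split, call. = FALSE))
  else split
  assert_that(length(idx) > 0, "empty split")
  yhat <- gtnnwr_forward(model, idx, force_unit_weights = ols)$yhat
  fit_metrics(model$y[idx], yhat, model$normalizer)
}

#' Regression metric suite
#' @param y observed values.
#' @param yhat predictions.
#' @param normalizer positive scale for the normalized metrics.
#' @return list with `r2`, `rmse`, `mae`, `mbe`, `nrmse`, `nmae`,
#'   `nmse_loss`.
#' @export
fit_metrics <- function(y, yhat, normalizer) {
  e <- yhat - y
  structure(list(
    r2 = 1 - sum(e^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)),
    mbe = mean(e),
    nrmse = sqrt(mean(e^2)) / normalizer,
    nmae = mean(abs(e)) / normalizer,
    nmse_loss = sum(e^2) / (length(y) * normalizer^2)),
    class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("R2 %.4f | RMSE %.4f | MAE %.4f | MBE %.4f | NRMSE %.4f | NMAE %.4f | NMSE %.6f\n",
              x$r2, x$rmse, x$mae, x$mbe, x$nrmse, x$nmae, x$nmse_loss))
  invisible(x)
}

#' Spatiotemporally varying coefficient surfaces
#'
#' Per-record coefficients `beta_ik = w_ik * beta_k^OLS` for every
#' (unit, year), the interpretable output of the weighted regression.
#'
#' @param model fitted `gtnnwr_model`.
#' @return data frame: unit, year, one `beta_<name>` column per
#'   coefficient (intercept first).
#' @export
extract_coefficients <- function(model) {
  fw <- gtnnwr_forward(model)
  B <- sweep(fw$w, 2, model$beta_ols, "*")
  colnames(B) <- paste0("beta_", names(model$beta_ols))
  cbind(data.frame(unit = model$panel$unit, year = model$panel$year,
                   stringsAsFactors = FALSE),
        as.data.frame(B))
}

#' Per-year influence ranking of the coefficient surfaces
#'
#' Cross-unit mean absolute coefficient per year and factor — the
#' summary used to rank factor influence over time.
#'
#' @param coefs output of [extract_coefficients()].
#' @return data frame: year, coefficient, mean_abs_beta, rank within
#'   year (intercept excluded from ranking).
#' @export
coefficient_summary <- function(coefs) {
  bcols <- grep("^beta_", names(coefs), value = TRUE)
  rows <- lapply(sort(unique(coefs$year)), function(yr) {
    sub <- coefs[coefs$year == yr, bcols, drop = FALSE]
    data.frame(year = yr, coefficient = sub("^beta_", "", bcols),
               mean_abs_beta = vapply(sub, function(v) mean(abs(v)),
                                      numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  non_int <- out$coefficient != "intercept"
  out$rank <- NA_integer_
  for (yr in unique(out$year)) {
    sel <- out$year == yr & non_int
    out$rank[sel] <- rank(-out$mean_abs_beta[sel], ties.method = "first")
  }
  out
}
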