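#' Coefficient-recovery benchmark for the spatiotemporal regression
#'
#' Runs the package's standard recovery experiment: a 6 x 8 lattice
#' observed for 30 years with the default nonstationary coefficient
#' surfaces (the first covariate's coefficient ramps linearly in the grid
#' column and in time) and observation noise 0.5, split 75/10/15 at seed
#' 48, then a 3000-epoch fit with desk-scale weight-network widths
#' (128, 64). Both seeds are fixed parts of the benchmark definition so
#' the experiment is reproducible run to run.
#'
#' @param epochs training epochs (default 3000).
#' @param swnn_hidden weight-network hidden widths (default `c(128, 64)`).
#' @param data_seed seed of the synthetic panel (default 2024).
#' @param model_seed seed of initialization/dropout and the split
#'   (default 48).
#' @param nrows,ncols,years,noise_sd generator dimensions and noise.
#' @param verbose print training history.
#' @return list with `model`, `sim` (generator output), `metrics`
#'   (train/validation/test plus the global-OLS test baseline), and
#'   `beta1_cor` (Pearson correlation between the fitted and true
#'   first-covariate coefficient surface).
#' @export
gtnnwr_benchmark <- function(epochs = 3000L, swnn_hidden = c(128L, 64L),
                             data_seed = 2024L, model_seed = 48L,
                             nrows = 6L, ncols = 8L, years = 30L,
                             noise_sd = 0.5, verbose = FALSE) {
  sim <- simulate_nonstationary_panel(nrows, ncols, years,
                                      noise_sd = noise_sd,
                                      seed = data_seed)
  splits <- split_data(nrow(sim$panel), seed = model_seed)
  hp <- gtnnwr_hyperparams(swnn_hidden = swnn_hidden, epochs = epochs,
                           log_interval = 500L)
  model <- gtnnwr(sim$panel, splits = splits, hyperparams = hp,
                  seed = model_seed, verbose = verbose)
  metrics <- list(train = evaluate(model, "train"),
                  validation = evaluate(model, "validation"),
                  test = evaluate(model, "test"),
                  ols_test = evaluate(model, "test", ols = TRUE))
  coefs <- extract_coefficients(model)
  b1 <- paste0("beta_", attr(sim$panel, "covariates")[1])
  list(model = model, sim = sim, metrics = metrics,
       beta1_cor = stats::cor(coefs[[b1]], sim$truth$beta[, 2]))
}
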