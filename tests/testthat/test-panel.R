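test_that("panel validation enforces structural invariants", {
  df <- data.frame(unit = rep(c("a", "b"), each = 3),
                   year = rep(2001:2003, 2),
                   outcome = 1:6, f1 = rnorm(6))
  p <- panel_dataset(df)
  expect_s3_class(p, "panel_dataset")
  expect_equal(attr(p, "covariates"), "f1")
  expect_equal(p$time_coord, p$year - 2001L)

  dup <- df; dup$year[2] <- 2001
  expect_error(panel_dataset(dup), "duplicate \\(unit, year\\)")
  gap <- df; gap$year[3] <- 2005
  expect_error(panel_dataset(gap), "non-contiguous")
  nas <- df; nas$f1[4] <- NA
  expect_error(panel_dataset(nas), "missing values")
})

test_that("read_panel round-trips a simulated panel and flags bad cells", {
  sim <- tiny_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(sim$panel, path)
  back <- read_panel(path, roles = list(unit = "unit", year = "year",
                                        outcome = "outcome",
                                        coords = c("x", "y")))
  expect_equal(nrow(back), nrow(sim$panel))
  expect_equal(back$outcome, sim$panel$outcome, tolerance = 1e-12)
  expect_equal(attr(back, "covariates"), attr(sim$panel, "covariates"))
  for (cv in attr(back, "covariates"))
    expect_equal(back[[cv]], sim$panel[[cv]], tolerance = 1e-12)

  # duplicated (unit, year) is a hard error naming the pair
  tab <- utils::read.csv(path)
  tab <- rbind(tab, tab[1, ])
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path2, row.names = FALSE)
  expect_error(read_panel(path2), "duplicate \\(unit, year\\)")

  # non-numeric covariate cell names the row
  tab2 <- utils::read.csv(path, colClasses = "character")
  tab2$x1[3] <- "oops"
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab2, path3, row.names = FALSE)
  expect_error(read_panel(path3), "non-numeric value 'oops'")

  # rows with missing outcome are dropped with a message
  tab3 <- utils::read.csv(path)
  # drop at the end of a unit's span so the year range stays contiguous
  tab3$outcome[which(tab3$year == max(tab3$year))[1]] <- NA
  path4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab3, path4, row.names = FALSE)
  expect_message(p4 <- read_panel(path4), "dropped 1 row")
  expect_equal(nrow(p4), nrow(sim$panel) - 1)
})

test_that("a 48-unit x 30-year panel has 1440 records", {
  sim <- simulate_nonstationary_panel(6, 8, 30, noise_sd = 0.5, seed = 1)
  expect_equal(nrow(sim$panel), 1440L)
  expect_equal(length(unique(sim$panel$unit)), 48L)
})

test_that("year binning matches the arithmetic-mean oracle and conserves means", {
  units <- sprintf("u%d", 1:4)
  df <- expand.grid(unit = units, year = 1991:2020,
                    stringsAsFactors = FALSE)
  df <- df[order(df$unit, df$year), ]
  df$outcome <- ifelse(df$unit == "u1", seq_len(30),
                       ifelse(df$unit == "u2", 70, rnorm(nrow(df))))
  p <- panel_dataset(df, covariates = character())

  secs <- bin_years(p, 5)
  expect_length(secs, 6)
  expect_equal(attr(secs[[1]], "label"), "1991-1995")
  expect_equal(attr(secs[[6]], "label"), "2016-2020")
  # values 1..30: first bin mean = mean(1:5) = 3
  expect_equal(unclass(secs[[1]])[["u1"]], 3)
  # constant outcome stays constant
  for (s in secs) expect_equal(unclass(s)[["u2"]], 70)
  # aggregation conservation: mean of bin means equals the 30-year mean
  binmat <- sapply(secs, function(s) as.numeric(s))
  full <- tapply(p$outcome, p$unit, mean)
  expect_equal(rowMeans(binmat), as.numeric(full[sort(units)]),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(bin_years(p, 7), "not divisible")
})

test_that("cumulative surface exposes sum and mean operators", {
  sim <- tiny_panel()
  cs_sum <- cumulative_surface(sim$panel, "sum")
  cs_mean <- cumulative_surface(sim$panel, "mean")
  yrs <- length(unique(sim$panel$year))
  expect_equal(as.numeric(cs_sum), as.numeric(cs_mean) * yrs,
               tolerance = 1e-12)
})
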