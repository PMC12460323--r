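#' Panel datasets of areal units observed over years
#'
#' A `panel_dataset` is a validated long-format data frame with one row per
#' (unit, year): an outcome (e.g. age-standardized incidence per 10,000),
#' named continuous covariates, and optional planar coordinates used for
#' spatiotemporal distances. The constructor enforces the structural
#' invariants every downstream stage relies on: unique (unit, year) pairs,
#' a shared covariate set, no missing outcomes, and a contiguous year range
#' within each unit.
#'
#' @param df data frame with at least columns `unit`, `year`, `outcome`.
#' @param covariates character vector naming covariate columns of `df`
#'   (default: every column other than unit/year/outcome/coordinates).
#' @param coords optional length-2 character vector naming the x and y
#'   coordinate columns.
#' @return a `panel_dataset`: the input data frame (columns reordered to
#'   unit, year, outcome, coordinates, covariates) with attributes
#'   `covariates` and `coords`, and `time_coord = year - min(year)`.
#' @export
panel_dataset <- function(df, covariates = NULL, coords = NULL) {
  assert_that(is.data.frame(df), "`df` must be a data frame")
  need <- c("unit", "year", "outcome")
  missing_cols <- setdiff(need, names(df))
  assert_that(length(missing_cols) == 0,
              paste("missing required columns:",
                    paste(missing_cols, collapse = ", ")))
  df$unit <- as.character(df$unit)
  df$year <- as.integer(df$year)

  if (is.null(covariates))
    covariates <- setdiff(names(df), c(need, coords, "time_coord"))
  assert_that(all(covariates %in% names(df)),
              "covariate columns not found in `df`")
  if (!is.null(coords)) {
    assert_that(length(coords) == 2 && all(coords %in% names(df)),
                "`coords` must name two columns of `df`")
    for (cc in coords) assert_that(is.numeric(df[[cc]]),
                                   paste("coordinate column", cc,
                                         "is not numeric"))
  }

  dup <- duplicated(df[c("unit", "year")])
  if (any(dup)) {
    bad <- df[dup, c("unit", "year")][1, ]
    stop(sprintf("duplicate (unit, year) pair: (%s, %d)",
                 bad$unit, bad$year), call. = FALSE)
  }
  assert_that(!anyNA(df$outcome) && is.numeric(df$outcome),
              "outcome must be numeric with no missing values")
  for (cv in covariates) {
    if (!is.numeric(df[[cv]]))
      stop(sprintf("covariate column '%s' is not numeric", cv),
           call. = FALSE)
    if (anyNA(df[[cv]]))
      stop(sprintf("covariate column '%s' has missing values", cv),
           call. = FALSE)
  }
  # contiguous year range per unit
  by_unit <- split(df$year, df$unit)
  for (u in names(by_unit)) {
    yrs <- sort(by_unit[[u]])
    if (length(yrs) > 1 && any(diff(yrs) != 1L))
      stop(sprintf("unit '%s' has a non-contiguous year range", u),
           call. = FALSE)
  }

  df <- df[order(df$unit, df$year), c(need, coords, covariates),
           drop = FALSE]
  rownames(df) <- NULL
  df$time_coord <- df$year - min(df$year)
  structure(df,
            covariates = covariates,
            coords = coords,
            class = c("panel_dataset", "data.frame"))
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("panel_dataset: %d units x %d years (%d records), %d covariates\n",
              length(unique(x$unit)), length(unique(x$year)), nrow(x),
              length(attr(x, "covariates"))))
  cat("covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  NextMethod()
}

#' Read a long-format panel from a delimited text file
#'
#' Columns are mapped to roles through `roles`; rows with missing outcome
#' are dropped with a message. Duplicated (unit, year) pairs and
#' non-numeric covariate cells are hard errors.
#'
#' @param path path to a CSV file with a header row.
#' @param roles named list mapping roles to column names:
#'   `unit`, `year`, `outcome`, optionally `coords` (length 2) and
#'   `covariates` (default: all remaining columns).
#' @param exclude_units character vector of unit ids to drop before
#'   validation (e.g. non-contiguous states).
#' @return a [panel_dataset].
#' @export
read_panel <- function(path,
                       roles = list(unit = "unit", year = "year",
                                    outcome = "outcome"),
                       exclude_units = character()) {
  assert_that(file.exists(path), paste("file not found:", path))
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  for (r in c("unit", "year", "outcome"))
    assert_that(!is.null(roles[[r]]) && roles[[r]] %in% names(raw),
                sprintf("role '%s' does not map to a column of %s", r, path))
  covs <- roles$covariates
  if (is.null(covs))
    covs <- setdiff(names(raw),
                    c(roles$unit, roles$year, roles$outcome, roles$coords))
  # non-numeric covariate cells: name the first offending row
  for (cv in covs) {
    v <- raw[[cv]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in covariate '%s' at row %d",
                     v[bad[1]], cv, bad[1]), call. = FALSE)
      raw[[cv]] <- num
    }
  }
  df <- data.frame(unit = as.character(raw[[roles$unit]]),
                   year = raw[[roles$year]],
                   outcome = suppressWarnings(as.numeric(raw[[roles$outcome]])),
                   stringsAsFactors = FALSE)
  if (!is.null(roles$coords)) {
    df$x <- as.numeric(raw[[roles$coords[1]]])
    df$y <- as.numeric(raw[[roles$coords[2]]])
  }
  for (cv in covs) df[[cv]] <- raw[[cv]]
  if (length(exclude_units)) df <- df[!(df$unit %in% exclude_units), ]
  n_missing <- sum(is.na(df$outcome))
  if (n_missing > 0) {
    message(sprintf("read_panel: dropped %d row(s) with missing outcome",
                    n_missing))
    df <- df[!is.na(df$outcome), ]
  }
  panel_dataset(df, covariates = covs,
                coords = if (is.null(roles$coords)) NULL else c("x", "y"))
}

#' Write a panel to CSV (round-trips through [read_panel])
#' @param panel a [panel_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  df$time_coord <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-sections: one value per unit
#'
#' A `cross_section` holds a single spatial field over the unit set — a
#' yearly slice, a five-year mean, or a cumulative surface — and is the
#' input type of the autocorrelation statistics.
#'
#' @param unit_ids character vector of unit identifiers.
#' @param values numeric vector, same length, all finite.
#' @param label human-readable label (e.g. "1991-1995 mean").
#' @return a `cross_section` (named numeric vector with a label attribute).
#' @export
cross_section <- function(unit_ids, values, label = "") {
  assert_that(length(unit_ids) == length(values),
              "unit_ids and values differ in length")
  assert_that(all(is.finite(values)), "cross-section values must be finite")
  structure(stats::setNames(as.numeric(values), as.character(unit_ids)),
            label = label, class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("cross_section '%s' over %d units\n",
              attr(x, "label"), length(x)))
  print(unclass(x), ...)
}

#' Aggregate a panel outcome into equal-width year bins
#'
#' Splits the panel's year span into consecutive bins of `width` years and
#' returns, per bin, the per-unit mean outcome — the five-year-interval
#' surfaces used for windowed clustering and factor analysis. The span must
#' divide evenly (30 years at width 5 gives six bins).
#'
#' @param panel a [panel_dataset].
#' @param width bin width in years (default 5).
#' @param column column to aggregate (default `"outcome"`; any covariate
#'   name is accepted so factor windows use the same binning).
#' @return list of [cross_section]s labelled `"<first>-<last>"`.
#' @export
bin_years <- function(panel, width = 5L, column = "outcome") {
  years <- sort(unique(panel$year))
  span <- length(years)
  assert_that(all(diff(years) == 1L), "panel years are not contiguous")
  if (span %% width != 0)
    stop(sprintf("year span (%d) is not divisible by bin width (%d)",
                 span, width), call. = FALSE)
  assert_that(column %in% names(panel),
              sprintf("column '%s' not in panel", column))
  units <- sort(unique(panel$unit))
  lapply(seq_len(span %/% width), function(b) {
    yrs <- years[((b - 1L) * width + 1L):(b * width)]
    sub <- panel[panel$year %in% yrs, ]
    m <- tapply(sub[[column]], sub$unit, mean)
    cross_section(units, as.numeric(m[units]),
                  label = sprintf("%d-%d", min(yrs), max(yrs)))
  })
}

#' Cumulative outcome surface over the whole study period
#'
#' Collapses the panel to one value per unit over all years. With
#' per-10,000 yearly incidence the natural cumulative scale is the sum of
#' yearly values (the default); `stat = "mean"` gives the period mean.
#'
#' @param panel a [panel_dataset].
#' @param stat `"sum"` (default) or `"mean"`.
#' @param column column to aggregate.
#' @return a [cross_section].
#' @export
cumulative_surface <- function(panel, stat = c("sum", "mean"),
                               column = "outcome") {
  stat <- match.arg(stat)
  units <- sort(unique(panel$unit))
  f <- if (stat == "sum") sum else mean
  v <- tapply(panel[[column]], panel$unit, f)
  cross_section(units, as.numeric(v[units]),
                label = sprintf("%d-%d %s", min(panel$year),
                                max(panel$year), stat))
}
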