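#' Construct a compound mixing-ratio series
#'
#' A `compound_series` is a uniformly sampled trace of one compound's
#' mixing ratio, nominally at 30 s cadence. Timestamps may be POSIXct
#' (naive local time) or plain numeric seconds.
#'
#' @param time timestamps, strictly increasing, uniform grid.
#' @param value mixing ratios (ppb, or ppm for CO2); all finite.
#' @param compound_id label, typically a protonated mass such as
#'   `"m69.0699"`.
#' @param unit `"ppb"` or `"ppm"`.
#' @param name optional human-readable compound name.
#' @param step_tol relative tolerance on step-size uniformity.
#' @return an object of class `compound_series`.
#' @export
compound_series <- function(time, value, compound_id = "compound",
                            unit = c("ppb", "ppm"), name = NULL,
                            step_tol = 0.01) {
  unit <- match.arg(unit)
  if (length(time) != length(value))
    stop("`time` and `value` must have equal length")
  if (length(time) < 2L)
    stop("a compound series needs at least 2 samples")
  tnum <- as.numeric(time)
  d <- diff(tnum)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf("timestamps must be strictly increasing (violation at sample %d, t = %s)",
                 i + 1L, format(time[i + 1L])))
  }
  step <- stats::median(d)
  if (any(abs(d - step) > step_tol * step))
    stop("timestamps are not a uniform grid (step sizes differ beyond tolerance)")
  if (any(is.infinite(value) | is.nan(value)))
    stop("series values must be finite (NA marks a missing sample)")
  structure(
    list(compound_id = compound_id, name = name, time = time,
         value = as.numeric(value), unit = unit, step_s = step),
    class = "compound_series")
}

#' @export
print.compound_series <- function(x, ...) {
  cat(sprintf("<compound_series> %s%s: %d samples @ %gs, unit %s%s\n",
              x$compound_id,
              if (!is.null(x$name)) paste0(" (", x$name, ")") else "",
              length(x$value), x$step_s, x$unit,
              if (isTRUE(attr(x, "per_person"))) " per person" else ""))
  invisible(x)
}

#' @export
length.compound_series <- function(x) length(x$value)

#' Extract the samples of a series falling inside a screening window
#'
#' The window is the closed interval `[start, end]`: boundary samples
#' are included. The sampling grid is unchanged.
#'
#' @param series a [compound_series()].
#' @param record a one-row screening data frame (columns `start_time`,
#'   `end_time`), or `NULL` if `start`/`end` are given directly.
#' @param start,end window bounds, same time type as `series$time`.
#' @return a [compound_series()] covering the overlap.
#' @export
slice_screening <- function(series, record = NULL, start = NULL, end = NULL) {
  stopifnot(inherits(series, "compound_series"))
  if (!is.null(record)) {
    stopifnot(nrow(record) == 1L)
    start <- record$start_time
    end <- record$end_time
  }
  if (as.numeric(end) <= as.numeric(start))
    stop("window end must be after window start")
  keep <- as.numeric(series$time) >= as.numeric(start) &
    as.numeric(series$time) <= as.numeric(end)
  if (sum(keep) == 0L)
    stop(sprintf("screening window [%s, %s] does not overlap the series",
                 format(start), format(end)))
  out <- series
  out$time <- series$time[keep]
  out$value <- series$value[keep]
  if (length(out$value) < 2L)
    stop("screening window contains fewer than 2 samples")
  out
}

#' Fill short gaps in a series by linear interpolation
#'
#' Missing samples (encoded as NA values) are linearly interpolated when
#' a run of consecutive NAs is at most `max_gap_steps` long. A longer
#' gap flags the series for exclusion rather than guessing the trace.
#'
#' @param series a [compound_series()]; `NA` values mark missing samples.
#' @param max_gap_steps longest NA run that is interpolated.
#' @return the series with gaps filled; attribute `excluded` is `TRUE`
#'   when an over-long gap (or a boundary NA) was found, and attribute
#'   `n_filled` counts interpolated samples.
#' @export
fill_gaps <- function(series, max_gap_steps = 3L) {
  stopifnot(inherits(series, "compound_series"))
  v <- series$value
  isna <- is.na(v)
  if (!any(isna)) {
    attr(series, "excluded") <- FALSE
    attr(series, "n_filled") <- 0L
    return(series)
  }
  r <- rle(isna)
  too_long <- any(r$values & r$lengths > max_gap_steps)
  boundary <- isna[1L] || isna[length(v)]
  if (too_long || boundary) {
    attr(series, "excluded") <- TRUE
    attr(series, "n_filled") <- 0L
    return(series)
  }
  filled <- stats::approx(seq_along(v)[!isna], v[!isna],
                          xout = seq_along(v))$y
  series$value <- filled
  attr(series, "excluded") <- FALSE
  attr(series, "n_filled") <- sum(isna)
  series
}

# internal: values of a compound_series with basic validation preserved
series_values <- function(series) {
  stopifnot(inherits(series, "compound_series"))
  series$value
}

#' Construct a residual series
#'
#' The residual series is the per-person measured trace minus the
#' constant-emission box-model prediction; it carries the scene-locked
#' peaks used for featurization.
#'
#' @param time timestamps (uniform grid).
#' @param residuals signed residuals, ppb per person.
#' @param film_length_min film length in minutes spanned by the trace.
#' @param step_s sampling step in seconds.
#' @return an object of class `residual_series`.
#' @export
residual_series <- function(time, residuals, film_length_min,
                            step_s = stats::median(diff(as.numeric(time)))) {
  if (length(time) != length(residuals))
    stop("`time` and `residuals` must have equal length")
  if (film_length_min <= 0) stop("film length must be positive")
  structure(list(time = time, residuals = as.numeric(residuals),
                 film_length_min = film_length_min, step_s = step_s),
            class = "residual_series")
}

#' @export
print.residual_series <- function(x, ...) {
  cat(sprintf("<residual_series> %d samples @ %gs, film length %.1f min, mean %.3g\n",
              length(x$residuals), x$step_s, x$film_length_min,
              mean(x$residuals)))
  invisible(x)
}
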