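#' Screening-room parameters for the one-box model
#'
#' The screening room is treated as a single well-mixed compartment of
#' volume V flushed with fresh outside air at rate Q, so a compound with
#' emission rate S obeys the mass balance
#' \deqn{dC/dt = (Q/V)(C_{in} - C) + S/V.}
#' Defaults are the measured cinema rooms: 6500 m^3 flushed with
#' 1300 m^3/h, giving an air-residence time V/Q of 5 h.
#'
#' @param volume room volume V, m^3.
#' @param ventilation_rate fresh-air flow Q, m^3/h.
#' @param inflow_mixing_ratio mixing ratio C_in of the inflowing air
#'   (same unit as the trace, ppb by default).
#' @return an object of class `room_params`.
#' @export
room_params <- function(volume = 6500, ventilation_rate = 1300,
                        inflow_mixing_ratio = 0) {
  if (volume <= 0) stop("room volume must be positive")
  if (ventilation_rate <= 0) stop("ventilation rate must be positive")
  if (inflow_mixing_ratio < 0) stop("inflow mixing ratio must be >= 0")
  structure(list(volume = volume, ventilation_rate = ventilation_rate,
                 inflow_mixing_ratio = inflow_mixing_ratio),
            class = "room_params")
}

#' @export
print.room_params <- function(x, ...) {
  cat(sprintf("<room_params> V = %g m^3, Q = %g m^3/h (tau = %.2f h), C_in = %g\n",
              x$volume, x$ventilation_rate, x$volume / x$ventilation_rate,
              x$inflow_mixing_ratio))
  invisible(x)
}

#' Remove the last minutes of a screening trace
#'
#' The end of every screening shows a large exit transient (for isoprene,
#' a spike from the audience standing up and walking out); the final
#' minutes are discarded before any modelling.
#'
#' @param series a [compound_series()].
#' @param minutes duration to remove from the end (default 5).
#' @return the trimmed [compound_series()].
#' @export
trim_tail <- function(series, minutes = 5) {
  stopifnot(inherits(series, "compound_series"), minutes >= 0)
  if (minutes == 0) return(series)
  tnum <- as.numeric(series$time)
  span_s <- tnum[length(tnum)] - tnum[1L]
  if (span_s <= minutes * 60)
    stop(sprintf("series spans %.1f min, shorter than the %g-min trim window",
                 span_s / 60, minutes))
  keep <- tnum <= tnum[length(tnum)] - minutes * 60
  out <- series
  out$time <- series$time[keep]
  out$value <- series$value[keep]
  out
}

#' Normalize a trace to the number of viewers
#'
#' Peak mixing ratios scale with audience size, so each screening's
#' trace is divided by its viewer count before model fitting, yielding
#' a per-person trace.
#'
#' @param series a [compound_series()].
#' @param viewer_count positive integer audience size N.
#' @return the per-person [compound_series()] (attribute `per_person`).
#' @export
normalize_per_person <- function(series, viewer_count) {
  stopifnot(inherits(series, "compound_series"))
  if (length(viewer_count) != 1L || is.na(viewer_count) || viewer_count < 1)
    stop("viewer_count must be a positive integer; screenings with no audience should be excluded upstream")
  out <- series
  out$value <- series$value / viewer_count
  attr(out, "per_person") <- TRUE
  out
}

# internal: exact closed-form one-box solution on a time grid.
# k = Q/V (1/h); time in seconds relative to t0.
box_solution <- function(t_h, E, C0, c_in, Q, k) {
  c_ss <- c_in + E / Q
  c_ss + (C0 - c_ss) * exp(-k * t_h)
}

#' Predict the constant-emission one-box trace
#'
#' Closed-form solution of the mass balance
#' \eqn{dC/dt = (Q/V)(C_{in} - C) + E/V} with constant per-person
#' emission rate E: exponential relaxation from `C0` toward the steady
#' state \eqn{C_{in} + E/Q} with time constant V/Q.
#'
#' @param params a [room_params()].
#' @param E emission rate, ppb m^3/h (per person when the trace is
#'   per person).
#' @param C0 mixing ratio at the first timestamp.
#' @param time uniform timestamp grid.
#' @param compound_id label for the returned series.
#' @return a [compound_series()] with the modelled trace.
#' @export
predict_box_model <- function(params, E, C0, time, compound_id = "model") {
  stopifnot(inherits(params, "room_params"))
  tnum <- as.numeric(time)
  if (length(tnum) < 2L) stop("time grid needs at least 2 samples")
  d <- diff(tnum)
  if (any(abs(d - d[1L]) > 1e-6 * d[1L]))
    stop("time grid must be uniform")
  k <- params$ventilation_rate / params$volume
  t_h <- (tnum - tnum[1L]) / 3600
  v <- box_solution(t_h, E, C0, params$inflow_mixing_ratio,
                    params$ventilation_rate, k)
  compound_series(time, v, compound_id = compound_id)
}

#' Estimate the inflow mixing ratio from a pre-entry baseline window
#'
#' Median of the samples in the `minutes` before the screening start;
#' robust against stray spikes in the empty room.
#'
#' @param series a [compound_series()] extending before the screening.
#' @param start_time screening start.
#' @param minutes baseline window length before `start_time`.
#' @return the median baseline value, or `NA` if no samples fall in the
#'   window.
#' @export
estimate_inflow <- function(series, start_time, minutes = 10) {
  tnum <- as.numeric(series$time)
  s <- as.numeric(start_time)
  sel <- tnum >= s - minutes * 60 & tnum < s
  if (!any(sel)) return(NA_real_)
  stats::median(series$value[sel])
}

#' Fit the constant-emission one-box model to a per-person trace
#'
#' Finds the emission rate E and initial value C0 minimizing the sum of
#' squared differences between the closed-form model and the trimmed,
#' per-person trace, with the inflow mixing ratio C_in held fixed. With
#' C_in fixed the model is linear in (E/Q, C0 - C_in) via the basis
#' functions \eqn{1 - e^{-kt}} and \eqn{e^{-kt}}, so the least-squares
#' problem is solved exactly; the physical bound E >= 0 is enforced by
#' the constrained (clamp-and-refit) solution unless
#' `allow_negative_E` is set (deposition-dominated compounds).
#'
#' Note C_in and E/Q multiply the same basis function inside a single
#' screening window, so only their sum is estimable from the trace
#' alone; C_in must come from the room configuration or a pre-entry
#' baseline ([estimate_inflow()]).
#'
#' @param series trimmed, per-person [compound_series()].
#' @param params a [room_params()].
#' @param c_in inflow mixing ratio; defaults to the value in `params`.
#' @param allow_negative_E drop the E >= 0 bound.
#' @return an object of class `box_model_fit` with elements
#'   `emission_rate` (E, ppb m^3/h per person), `initial_value` (C0),
#'   `inflow`, `rms_misfit` and the `fitted` model trace.
#' @export
fit_box_model <- function(series, params, c_in = params$inflow_mixing_ratio,
                          allow_negative_E = FALSE) {
  stopifnot(inherits(series, "compound_series"), inherits(params, "room_params"))
  y_all <- series$value
  if (length(y_all) < 10L)
    stop("box-model fit needs at least 10 samples")
  Q <- params$ventilation_rate
  k <- Q / params$volume
  tnum <- as.numeric(series$time)
  t_h <- (tnum - tnum[1L]) / 3600
  e_kt <- exp(-k * t_h)
  b1 <- 1 - e_kt
  b2 <- e_kt
  y <- y_all - c_in

  X <- cbind(b1, b2)
  coefs <- tryCatch(qr.coef(qr(X), y), error = function(e)
    stop(sprintf("box-model fit failed: %s", conditionMessage(e))))
  if (any(is.na(coefs)))
    stop("box-model fit is rank-deficient (degenerate time grid)")
  E <- coefs[1L] * Q
  if (E < 0 && !allow_negative_E) {
    # KKT: on the active bound E = 0, refit C0 alone
    E <- 0
    a2 <- sum(y * b2) / sum(b2 * b2)
    coefs <- c(0, a2)
  }
  fitted <- c_in + coefs[1L] * b1 + coefs[2L] * b2
  rms <- sqrt(mean((y_all - fitted)^2))
  structure(list(emission_rate = unname(E),
                 initial_value = unname(coefs[2L] + c_in),
                 inflow = c_in, rms_misfit = rms,
                 fitted = fitted, k = k, params = params),
            class = "box_model_fit")
}

#' @export
print.box_model_fit <- function(x, ...) {
  cat(sprintf("<box_model_fit> E = %.4g ppb m^3/h per person, C0 = %.4g, C_in = %.4g, rms misfit = %.4g\n",
              x$emission_rate, x$initial_value, x$inflow, x$rms_misfit))
  invisible(x)
}

#' Residual time series: measured minus modelled
#'
#' Subtracting the fitted constant-emission trend leaves the residual
#' series whose peaks and valleys recur at the same times in every
#' screening of the same film.
#'
#' @param series the per-person [compound_series()] the fit was made on.
#' @param fit the matching [fit_box_model()] result.
#' @param params a [room_params()] (recorded for provenance).
#' @return a [residual_series()].
#' @export
compute_residuals <- function(series, fit, params = fit$params) {
  stopifnot(inherits(series, "compound_series"), inherits(fit, "box_model_fit"))
  if (length(series$value) != length(fit$fitted))
    stop("series and fitted model have different lengths; the fit must come from this series")
  tnum <- as.numeric(series$time)
  residual_series(series$time, series$value - fit$fitted,
                  film_length_min = (tnum[length(tnum)] - tnum[1L]) / 60,
                  step_s = series$step_s)
}
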