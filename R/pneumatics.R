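# Pneumatic actuation analysis: set-point vacuum waveforms, a linear
# time-invariant model of the valve/line response, pressure-change-rate
# statistics, vacuum/pressure conversions, implied strain rates and cycle
# bookkeeping. Absolute-pressure convention throughout: 1 bar is
# atmosphere and applying vacuum lowers the pressure, so v% vacuum
# corresponds to (1 - v/100) bar.

#' Convert vacuum percentage to absolute pressure (and back)
#'
#' @param vacuum_percent vacuum depth in percent of atmosphere (0–100);
#'   35% vacuum is 0.65 bar absolute.
#' @param pressure_bar absolute pressure in bar (0–1) for the inverse.
#' @return Pressure in bar, or vacuum in percent.
#' @examples
#' vacuum_to_pressure(35)   # 0.65
#' pressure_to_vacuum(0.5)  # 50
#' @export
vacuum_to_pressure <- function(vacuum_percent) {
  if (any(!is.finite(vacuum_percent)) || any(vacuum_percent < 0) ||
      any(vacuum_percent > 100))
    stop("`vacuum_percent` must be within [0, 100]", call. = FALSE)
  1 - vacuum_percent / 100
}

#' @rdname vacuum_to_pressure
#' @export
pressure_to_vacuum <- function(pressure_bar) {
  if (any(!is.finite(pressure_bar)) || any(pressure_bar < 0) ||
      any(pressure_bar > 1))
    stop("`pressure_bar` must be within [0, 1]", call. = FALSE)
  (1 - pressure_bar) * 100
}

#' Set-point waveform specification
#'
#' @param shape `"rectangular"`, `"trapezoidal"` or `"sinusoidal"`.
#' @param period period time in seconds.
#' @param vacuum_fraction target vacuum depth as a fraction of atmosphere
#'   (0–1, e.g. 0.35 for 35% vacuum).
#' @param setpoint_slope ramp slope of the control signal in bar/s
#'   (rectangular transitions are ramped at this finite slope;
#'   trapezoidal uses it as the user ramp).
#' @param sample_dt sampling interval in seconds.
#' @param duration total trace duration in seconds.
#' @return Object of class `waveform_spec`.
#' @export
waveform_spec <- function(shape = c("rectangular", "trapezoidal", "sinusoidal"),
                          period = 20, vacuum_fraction = 0.35,
                          setpoint_slope = 17.5, sample_dt = 0.01,
                          duration = period) {
  shape <- match.arg(shape)
  stop_if_not_scalar_num(period, "period", positive = TRUE)
  stop_if_not_scalar_num(sample_dt, "sample_dt", positive = TRUE)
  stop_if_not_scalar_num(duration, "duration", nonneg = TRUE)
  if (vacuum_fraction < 0 || vacuum_fraction > 1)
    stop("`vacuum_fraction` must be within [0, 1]", call. = FALSE)
  if (shape != "sinusoidal" && setpoint_slope <= 0)
    stop("`setpoint_slope` must be > 0 for ramped shapes", call. = FALSE)
  structure(list(shape = shape, period = period,
                 vacuum_fraction = vacuum_fraction,
                 setpoint_slope = setpoint_slope,
                 sample_dt = sample_dt, duration = duration),
            class = "waveform_spec")
}

#' Sampled pressure trace
#'
#' @param times sample times in seconds (uniform).
#' @param pressure absolute pressure in bar.
#' @return Data frame of class `pressure_trace`.
#' @export
pressure_trace <- function(times, pressure) {
  if (length(times) != length(pressure))
    stop("`times` and `pressure` must match in length", call. = FALSE)
  if (length(times) > 1) {
    dts <- diff(times)
    if (any(abs(dts - dts[1]) > 1e-9 * max(1, dts[1])))
      stop("`times` must be uniformly sampled", call. = FALSE)
  }
  out <- data.frame(time = as.numeric(times), pressure = as.numeric(pressure))
  class(out) <- c("pressure_trace", "data.frame")
  out
}

#' Generate a set-point pressure trace
#'
#' Rectangular: each period starts relaxed at 1 bar, switches to the
#' vacuum plateau at half period (50% duty), with transitions ramped at
#' the finite `setpoint_slope` of the control hardware. Trapezoidal: the
#' same pattern with the user-chosen (slower) ramp. Sinusoidal: an offset
#' sine oscillating between 1 bar and the target pressure, starting
#' relaxed.
#'
#' @param spec a [waveform_spec()].
#' @return A [pressure_trace()] sampled at `spec$sample_dt`.
#' @examples
#' tr <- generate_setpoint(waveform_spec(period = 20, duration = 40))
#' @export
generate_setpoint <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  t <- seq(0, spec$duration, by = spec$sample_dt)
  p_lo <- 1 - spec$vacuum_fraction
  if (spec$vacuum_fraction == 0) return(pressure_trace(t, rep(1, length(t))))
  if (spec$shape == "sinusoidal") {
    p <- 1 - spec$vacuum_fraction * (1 - cos(2 * pi * t / spec$period)) / 2
    return(pressure_trace(t, p))
  }
  ramp_T <- spec$vacuum_fraction / spec$setpoint_slope
  tp <- t %% spec$period
  half <- spec$period / 2
  # piecewise: [0, half) relaxed at 1 bar (completing the venting ramp at
  # the period wrap); [half, half+ramp) evacuation ramp; then vacuum plateau
  p <- rep(1, length(t))
  evac <- tp >= half
  p[evac] <- pmax(p_lo, 1 - spec$setpoint_slope * (tp[evac] - half))
  vent <- tp < ramp_T & t >= spec$period  # no venting before the 1st period
  p[vent] <- pmin(1, p_lo + spec$setpoint_slope * tp[vent])
  pressure_trace(t, p)
}

#' Simulate the pneumatic response to a set-point trace
#'
#' Applies a linear time-invariant lag model of the valve and vacuum
#' line: first order (`dp/dt = (s - p)/tau`) or, when `damping < 1` is
#' given, an underdamped second-order system
#' (`p'' + 2 zeta omega p' + omega^2 p = omega^2 s`, `omega = 1/tau`)
#' which reproduces the overshoot-and-stabilization behavior of a real
#' proportional-valve line. Integration is classical Runge–Kutta at the
#' trace sampling rate with piecewise-linear set-point interpolation.
#'
#' @param setpoint a [pressure_trace()].
#' @param tau time constant in seconds (> 0).
#' @param damping damping ratio `zeta` for the second-order model, or
#'   `NULL` for first order. `damping >= 1` gives a monotone (overdamped)
#'   response.
#' @param p0 initial pressure; defaults to the first set-point sample.
#' @return A [pressure_trace()] of the simulated response, sampled
#'   identically to the set-point.
#' @seealso [fit_response_params()] for calibrating `tau` and `damping`
#'   to measured rise/settling times.
#' @export
simulate_response <- function(setpoint, tau = 0.1, damping = NULL,
                              p0 = NULL) {
  stopifnot(inherits(setpoint, "pressure_trace"))
  stop_if_not_scalar_num(tau, "tau", positive = TRUE)
  t <- setpoint$time; s <- setpoint$pressure
  n <- length(t)
  if (n < 2) return(setpoint)
  dt <- t[2] - t[1]
  if (is.null(p0)) p0 <- s[1]
  # piecewise-linear set-point: values at step starts, midpoints, ends
  s0 <- s[-n]; s1 <- s[-1]; sm <- (s0 + s1) / 2
  p <- numeric(n)
  if (is.null(damping)) {
    y <- p0
    p[1] <- y
    for (i in seq_len(n - 1L)) {
      k1 <- (s0[i] - y) / tau
      k2 <- (sm[i] - (y + dt / 2 * k1)) / tau
      k3 <- (sm[i] - (y + dt / 2 * k2)) / tau
      k4 <- (s1[i] - (y + dt * k3)) / tau
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      p[i + 1L] <- y
    }
  } else {
    stop_if_not_scalar_num(damping, "damping", positive = TRUE)
    om <- 1 / tau
    f <- function(sv, y) c(y[2], om^2 * (sv - y[1]) - 2 * damping * om * y[2])
    y <- c(p0, 0)
    p[1] <- y[1]
    for (i in seq_len(n - 1L)) {
      k1 <- f(s0[i], y)
      k2 <- f(sm[i], y + dt / 2 * k1)
      k3 <- f(sm[i], y + dt / 2 * k2)
      k4 <- f(s1[i], y + dt * k3)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      p[i + 1L] <- y[1]
    }
  }
  pressure_trace(t, p)
}

#' Calibrate the response model to rise and settling targets
#'
#' Solves for the natural time constant of the underdamped second-order
#' model so that a step to the given vacuum depth (with the standard
#' ramped rectangular set-point) first reaches the target pressure after
#' `rise_time` seconds, and verifies that the response settles within
#' `settle_band` of the target by `settle_time`.
#'
#' @param vacuum_fraction step depth (fraction of atmosphere).
#' @param rise_time desired time to first reach the target, seconds.
#' @param settle_time time by which the response must stay within the
#'   settling band, seconds.
#' @param settle_band settling band as a fraction of the step size.
#' @param damping damping ratio of the model.
#' @param setpoint_slope,sample_dt control-signal parameters.
#' @return List with `tau`, `damping`, and the achieved `rise` and
#'   `settled` (logical) under the calibrated parameters.
#' @export
fit_response_params <- function(vacuum_fraction = 0.35, rise_time = 0.3,
                                settle_time = 1.5, settle_band = 0.02,
                                damping = 0.6, setpoint_slope = 17.5,
                                sample_dt = 0.01) {
  step_sp <- .step_setpoint(vacuum_fraction, setpoint_slope, sample_dt,
                            duration = 4)
  target <- 1 - vacuum_fraction
  rise_of <- function(tau) {
    resp <- simulate_response(step_sp, tau = tau, damping = damping, p0 = 1)
    .first_crossing(resp$time, resp$pressure, target)
  }
  lo <- 0.01; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    r <- rise_of(mid)
    if (is.na(r) || r > rise_time) hi <- mid else lo <- mid
  }
  tau <- (lo + hi) / 2
  resp <- simulate_response(step_sp, tau = tau, damping = damping, p0 = 1)
  band <- settle_band * vacuum_fraction
  after <- resp$time >= settle_time
  settled <- all(abs(resp$pressure[after] - target) <= band)
  list(tau = tau, damping = damping, rise = rise_of(tau), settled = settled)
}

# A single evacuation step (1 bar -> target) ramped at the set-point
# slope, starting at t = 0.
.step_setpoint <- function(vacuum_fraction, setpoint_slope = 17.5,
                           sample_dt = 0.01, duration = 4) {
  t <- seq(0, duration, by = sample_dt)
  p <- pmax(1 - vacuum_fraction, 1 - setpoint_slope * t)
  pressure_trace(t, p)
}

.first_crossing <- function(t, p, target) {
  below <- p <= target
  i <- which(below)[1]
  if (is.na(i) || i == 1) return(if (isTRUE(below[1])) t[1] else NA_real_)
  # linear interpolation between the bracketing samples
  t[i - 1] + (target - p[i - 1]) / (p[i] - p[i - 1]) * (t[i] - t[i - 1])
}

#' Pressure change rate by central differences
#'
#' @param trace a [pressure_trace()] with at least three samples.
#' @return Data frame with columns `time` and `rate` (bar/s): central
#'   differences in the interior, one-sided at the ends.
#' @export
pressure_rate <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  n <- nrow(trace)
  if (n < 3) stop("rate requires at least 3 samples", call. = FALSE)
  t <- trace$time; p <- trace$pressure
  r <- numeric(n)
  r[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  r[1] <- (p[2] - p[1]) / (t[2] - t[1])
  r[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
  data.frame(time = t, rate = r)
}

#' Per-period pressure-change-rate peaks
#'
#' Splits the rate trace into complete periods and extracts, per period,
#' the most negative rate (evacuation) and the most positive rate
#' (venting); reports their means and standard errors over periods.
#'
#' @param rate data frame from [pressure_rate()].
#' @param period period time in seconds.
#' @param t0 start time of the first period.
#' @return Object of class `rate_stats`: `evacuation_rate_mean`,
#'   `evacuation_rate_sem`, `venting_rate_mean`, `venting_rate_sem`,
#'   `n_periods`.
#' @export
rate_peaks <- function(rate, period, t0 = 0) {
  stop_if_not_scalar_num(period, "period", positive = TRUE)
  idx <- floor((rate$time - t0) / period)
  full <- idx >= 0 & idx < floor((max(rate$time) - t0 + 1e-9) / period)
  if (!any(full)) stop("trace contains no complete period", call. = FALSE)
  sp <- split(rate$rate[full], idx[full])
  evac <- vapply(sp, min, numeric(1))
  vent <- vapply(sp, max, numeric(1))
  if (all(evac == 0) && all(vent == 0))
    stop("no pressure-rate peaks detected", call. = FALSE)
  structure(list(
    evacuation_rate_mean = mean(evac), evacuation_rate_sem = sem(evac),
    venting_rate_mean = mean(vent), venting_rate_sem = sem(vent),
    n_periods = length(sp)
  ), class = "rate_stats")
}

#' @export
print.rate_stats <- function(x, ...) {
  cat(sprintf("<rate_stats> n = %d periods\n", x$n_periods))
  cat(sprintf("  evacuation: %.3f +/- %.4f bar/s\n",
              x$evacuation_rate_mean, x$evacuation_rate_sem))
  cat(sprintf("  venting:    %.3f +/- %.4f bar/s\n",
              x$venting_rate_mean, x$venting_rate_sem))
  invisible(x)
}

#' Strain rate implied by a pressure change rate
#'
#' Under the (measured) linear strain–vacuum relation, a strain of
#' `strain_percent` at a vacuum depth of `vacuum_depth` bar implies a
#' strain rate of `(strain / depth) * rate` for a given pressure change
#' rate. Reported rounded to the nearest integer %/s by default.
#'
#' @param strain_percent strain at the reference vacuum depth, in percent.
#' @param vacuum_depth reference vacuum depth in bar (> 0).
#' @param rate pressure change rate magnitude in bar/s.
#' @param digits rounding digits (`NULL` to skip rounding).
#' @return Strain rate in %/s.
#' @examples
#' implied_strain_rate(8, 0.35, 2)    # 46
#' implied_strain_rate(8, 0.35, 1.3)  # 30
#' @export
implied_strain_rate <- function(strain_percent, vacuum_depth, rate,
                                digits = 0) {
  stop_if_not_scalar_num(vacuum_depth, "vacuum_depth", positive = TRUE)
  out <- (strain_percent / vacuum_depth) * rate
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Stretch-cycle bookkeeping
#'
#' @param duration experiment duration in seconds.
#' @param period stretch period in seconds (> 0).
#' @return `cycles_in_duration()`: number of complete cycles,
#'   `floor(duration / period)`; `stretch_frequency()`: `1 / period` Hz.
#' @examples
#' cycles_in_duration(18 * 3600, 20)  # 3240
#' stretch_frequency(20)              # 0.05
#' @export
cycles_in_duration <- function(duration, period) {
  stop_if_not_scalar_num(period, "period", positive = TRUE)
  stop_if_not_scalar_num(duration, "duration", nonneg = TRUE)
  floor(duration / period)
}

#' @rdname cycles_in_duration
#' @export
stretch_frequency <- function(period) {
  stop_if_not_scalar_num(period, "period", positive = TRUE)
  1 / period
}

#' Image acquisition schedule for cyclic stretching
#'
#' Periods start relaxed; the state switches to stretched at half period.
#' Images are triggered `settle_delay` seconds after each state
#' transition (to let the pneumatic response stabilize), and a
#' relaxed/stretched pair is emitted every `pair_interval` seconds.
#'
#' @param period stretch period, seconds.
#' @param settle_delay imaging delay after a transition, seconds
#'   (< period/2).
#' @param pair_interval interval between acquired pairs, seconds.
#' @param duration nominal experiment duration, seconds.
#' @return Data frame with columns `relaxed_time` and `stretched_time`;
#'   empty for `duration <= 0`.
#' @examples
#' acquisition_schedule(20, 3, 600, 3600)  # pairs every 10 min for 1 h
#' @export
acquisition_schedule <- function(period = 20, settle_delay = 3,
                                 pair_interval = period, duration = 3600) {
  stop_if_not_scalar_num(period, "period", positive = TRUE)
  stop_if_not_scalar_num(pair_interval, "pair_interval", positive = TRUE)
  if (settle_delay < 0 || settle_delay >= period / 2)
    stop("`settle_delay` must be within [0, period/2)", call. = FALSE)
  if (duration <= 0)
    return(data.frame(relaxed_time = numeric(0), stretched_time = numeric(0)))
  starts <- seq(0, duration, by = pair_interval)
  data.frame(relaxed_time = starts + settle_delay,
             stretched_time = starts + period / 2 + settle_delay)
}
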