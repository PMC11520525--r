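#' Clock hardware specification
#'
#' Describes the timekeeping hardware of a tag: the rated maximum oscillator
#' drift (in parts per million, over a stated ambient temperature range), the
#' read resolution of the real-time clock (RTC), and the latency of the
#' set-time command. Defaults match a temperature-compensated RTC rated at
#' +/- 3 ppm between -40 and 85 degC with 10 ms resolution, whose set command
#' (9 bytes over a 400 kbit/s I2C bus) takes 0.18 ms.
#'
#' @param max_drift_ppm rated maximum |drift| in parts per million (>= 0).
#' @param temp_range length-2 numeric, min/max ambient temperature in degC.
#' @param resolution_s RTC read resolution in seconds (> 0).
#' @param set_latency_s latency of the set-time command in seconds.
#' @return an object of class `clock_spec`.
#' @export
#' @examples
#' clock_spec()                       # temperature-compensated RTC
#' clock_spec(20, c(0, 50))           # plain crystal oscillator module
clock_spec <- function(max_drift_ppm = 3, temp_range = c(-40, 85),
                       resolution_s = 0.01, set_latency_s = set_latency()) {
  stop_if_not_scalar_number(max_drift_ppm, "max_drift_ppm")
  stop_if_not_scalar_number(resolution_s, "resolution_s")
  stop_if_not_scalar_number(set_latency_s, "set_latency_s")
  if (max_drift_ppm < 0) abort("`max_drift_ppm` must be >= 0.")
  if (resolution_s <= 0) abort("`resolution_s` must be > 0.")
  if (length(temp_range) != 2L || temp_range[1] >= temp_range[2]) {
    abort("`temp_range` must be (min, max) with min < max.")
  }
  structure(
    list(max_drift_ppm = max_drift_ppm, temp_range = as.numeric(temp_range),
         resolution_s = resolution_s, set_latency_s = set_latency_s),
    class = "clock_spec"
  )
}

#' RTC set-time command latency
#'
#' The set command transfers `n_bytes` over a serial bus at `bitrate_bps`;
#' the transfer time is the residual timing error left after setting the
#' clock on a full second. With the defaults (9 bytes at 400 kbit/s) this is
#' 0.18 ms.
#'
#' @param n_bytes bytes in the set command.
#' @param bitrate_bps bus speed in bits per second.
#' @return latency in seconds.
#' @export
#' @examples
#' set_latency() * 1000  # 0.18 ms
set_latency <- function(n_bytes = 9, bitrate_bps = 400000) {
  stopifnot(n_bytes > 0, bitrate_bps > 0)
  n_bytes * 8 / bitrate_bps
}

#' Piecewise-constant drift-rate profile
#'
#' A drift-rate (ppm) trajectory as contiguous, non-overlapping segments.
#' The last segment may extend to `Inf`. A single number is promoted to one
#' segment covering `[0, Inf)`.
#'
#' @param segments a data frame with columns `start_s`, `end_s`, `ppm`, or a
#'   single number for a constant rate.
#' @return a tibble of validated segments (class `ppm_profile`).
#' @export
#' @examples
#' ppm_profile(3)
#' ppm_profile(data.frame(start_s = c(0, 3600), end_s = c(3600, Inf),
#'                        ppm = c(2, -2)))
ppm_profile <- function(segments) {
  if (is.numeric(segments) && length(segments) == 1L) {
    segments <- tibble(start_s = 0, end_s = Inf, ppm = segments)
  }
  segments <- as_tibble(segments)
  if (!all(c("start_s", "end_s", "ppm") %in% names(segments))) {
    abort("`segments` needs columns start_s, end_s, ppm.")
  }
  segments <- arrange(segments, .data$start_s)
  if (any(segments$end_s <= segments$start_s)) {
    abort("Each segment must have end_s > start_s.")
  }
  if (nrow(segments) > 1L &&
      any(abs(segments$start_s[-1] - segments$end_s[-nrow(segments)]) > 1e-9)) {
    abort("Segments must be contiguous and non-overlapping.")
  }
  class(segments) <- c("ppm_profile", class(segments))
  segments
}

#' Map a temperature profile to a drift-rate profile
#'
#' Converts piecewise-constant ambient temperature segments into drift-rate
#' segments through a user-supplied temperature-to-ppm curve. Rated clock
#' specs give only a drift bound over a temperature range, not a curve, so
#' the mapping is configuration: a common simple choice is a constant within
#' spec, or a linear ramp across the rated range.
#'
#' @param temperature a data frame with columns `start_s`, `end_s`, `temp_c`.
#' @param ppm_of_temp a function taking temperature (degC) and returning ppm.
#' @return a [ppm_profile()].
#' @export
#' @examples
#' temps <- data.frame(start_s = c(0, 3600), end_s = c(3600, 7200),
#'                     temp_c = c(20, -5))
#' ppm_from_temperature(temps, function(tc) 0.1 * (tc - 25))
ppm_from_temperature <- function(temperature, ppm_of_temp) {
  temperature <- as_tibble(temperature)
  if (!all(c("start_s", "end_s", "temp_c") %in% names(temperature))) {
    abort("`temperature` needs columns start_s, end_s, temp_c.")
  }
  ppm_profile(tibble(
    start_s = temperature$start_s,
    end_s = temperature$end_s,
    ppm = vapply(temperature$temp_c, ppm_of_temp, numeric(1))
  ))
}

#' Simulated device clock
#'
#' The carrier of the time-error model: local time is reference time plus
#' accumulated oscillator drift plus the synchronisation offset,
#' `t' = t + T_drift(t) + T_off(t)`. Drift accumulates from `anchor_s` (the
#' epoch or the instant of the last clock set) at the piecewise-constant
#' rate given by `ppm`; `t_off_s` is the constant offset left behind by the
#' last synchronisation.
#'
#' @param device_id device label.
#' @param spec a [clock_spec()].
#' @param ppm a [ppm_profile()] or a single number (constant rate). Must not
#'   exceed `spec$max_drift_ppm` in magnitude.
#' @param t_off_s current synchronisation offset, seconds.
#' @param anchor_s reference time from which drift accumulates, seconds.
#' @param last_sync_utc_s UTC time of the last synchronisation (defaults to
#'   the anchor).
#' @return an object of class `sim_clock`.
#' @export
#' @examples
#' clk <- sim_clock("tag001", ppm = 3)
#' local_time(clk, 86400) - 86400   # one day of +3 ppm drift: 0.2592 s
sim_clock <- function(device_id, spec = clock_spec(), ppm = 0, t_off_s = 0,
                      anchor_s = 0, last_sync_utc_s = anchor_s) {
  prof <- ppm_profile(ppm)
  if (any(abs(prof$ppm) > spec$max_drift_ppm + 1e-12)) {
    abort("Drift-rate profile exceeds the clock's rated max_drift_ppm.")
  }
  structure(
    list(device_id = device_id, spec = spec, ppm = prof,
         t_off_s = t_off_s, anchor_s = anchor_s,
         last_sync_utc_s = last_sync_utc_s),
    class = "sim_clock"
  )
}

#' @export
print.sim_clock <- function(x, ...) {
  cat(sprintf("<sim_clock %s>  T_off = %.6f s, anchor = %.3f s, %d ppm segment(s)\n",
              x$device_id, x$t_off_s, x$anchor_s, nrow(x$ppm)))
  invisible(x)
}

#' Accumulated oscillator drift over an interval
#'
#' Exact integral of the piecewise-constant drift rate:
#' sum over segments of `ppm * 1e-6 * overlap`. Drift does not grow at a
#' fixed rate; it follows the rate profile (e.g. driven by ambient
#' temperature).
#'
#' @param clock a [sim_clock()].
#' @param t0,t1 interval bounds in reference seconds, `t0 <= t1`
#'   (`t1` may be a vector).
#' @return accumulated drift in seconds, same length as `t1`.
#' @export
#' @examples
#' drift_integral(sim_clock("a", ppm = 3), 0, 86400)  # 0.2592
drift_integral <- function(clock, t0, t1) {
  if (any(t1 < t0)) abort("`t1` must be >= `t0`.")
  seg <- clock$ppm
  out <- numeric(length(t1))
  for (i in seq_len(nrow(seg))) {
    lo <- pmax(seg$start_s[i], t0)
    hi <- pmin(seg$end_s[i], t1)
    out <- out + seg$ppm[i] * 1e-6 * pmax(0, hi - lo)
  }
  out
}

#' Local (device) time at a reference instant
#'
#' `t + T_drift(t) + T_off(t)` with drift accumulated since the clock's
#' anchor. Continuous in `t` between clock sets.
#'
#' @param clock a [sim_clock()].
#' @param t reference time(s) in seconds, at or after the clock's anchor.
#' @return local time(s) in seconds.
#' @export
local_time <- function(clock, t) {
  if (any(t < clock$anchor_s - 1e-9)) {
    abort("`t` is before the clock's epoch/anchor.")
  }
  t + drift_integral(clock, clock$anchor_s, t) + clock$t_off_s
}

#' Quantised RTC read
#'
#' Local time as the RTC reports it: floored to the clock's read resolution
#' (10 ms by default). All stored timestamps pass through this
#' quantisation.
#'
#' @inheritParams local_time
#' @return quantised local time(s) in seconds.
#' @export
rtc_read <- function(clock, t) {
  res <- clock$spec$resolution_s
  floor(local_time(clock, t) / res + 1e-9) * res
}

#' Reference instant at which the device clock shows a given local time
#'
#' Inverse of [local_time()]: the true time at which the device believes it
#' is `local_s` (e.g. when an alarm programmed for a UTC second actually
#' fires). Solved by fixed-point iteration; at ppm-scale drift rates it
#' converges far below numerical precision.
#'
#' @param clock a [sim_clock()].
#' @param local_s target local time, seconds.
#' @return reference time in seconds.
#' @export
wake_time <- function(clock, local_s) {
  t <- pmax(local_s, clock$anchor_s)
  for (i in 1:6) {
    err <- local_time(clock, pmax(t, clock$anchor_s)) - pmax(t, clock$anchor_s)
    t <- local_s - err
  }
  pmax(t, clock$anchor_s)
}

#' Decompose the time error of a clock
#'
#' Splits the deviation of local from reference time into its drift and
#' offset components: `T_error = T_drift + T_off` and
#' `t' = t + T_error`, exactly, at each requested instant.
#'
#' @param clock a [sim_clock()].
#' @param t reference time(s) in seconds.
#' @return a tibble with columns `t_s`, `t_prime_s`, `T_drift_s`, `T_off_s`,
#'   `T_error_s`.
#' @export
#' @examples
#' decompose_error(sim_clock("a", ppm = 3, t_off_s = 0.002), c(0, 43200, 86400))
decompose_error <- function(clock, t) {
  drift <- drift_integral(clock, clock$anchor_s, t)
  tibble(
    t_s = t,
    t_prime_s = t + drift + clock$t_off_s,
    T_drift_s = drift,
    T_off_s = clock$t_off_s,
    T_error_s = drift + clock$t_off_s
  )
}

#' Set the device clock to a delivered UTC time
#'
#' Models the onboard set-time procedure: having obtained a UTC estimate
#' `utc_target_s` at true time `at_reference_s`, the device waits (on a high
#' accuracy timer) until the next full UTC second of the delivered time,
#' then issues the RTC set command, which zeroes the milliseconds field and
#' costs one command-transfer latency. The post-set offset is therefore the
#' set latency plus whatever error the delivered time itself carried
#' (`utc_target_s - at_reference_s`). Drift accumulation restarts at the set
#' instant.
#'
#' @param clock a [sim_clock()].
#' @param utc_target_s the UTC time delivered by the synchronisation source
#'   (GPS, NTP, or a peer), as believed at `at_reference_s`.
#' @param at_reference_s the true reference time at which the estimate was
#'   delivered.
#' @param method label for the synchronisation method
#'   (`"GPS"`, `"WIFI_NTP"`, `"PROXIMITY"`, ...).
#' @param last_sync_utc_s value to store as the time of last
#'   synchronisation; defaults to the (full-second) set time.
#' @return a list with elements `clock` (the updated [sim_clock()]) and
#'   `record` (a one-row sync-record tibble: `device_id`, `method`,
#'   `reference_time_s`, `measured_deviation_ms`, `applied`,
#'   `post_sync_T_off_ms`).
#' @export
#' @examples
#' clk <- sim_clock("a", ppm = 3, t_off_s = 0.04)
#' res <- set_clock(clk, utc_target_s = 1000.3, at_reference_s = 1000.3)
#' res$record$post_sync_T_off_ms   # 0.18 ms: just the set latency
set_clock <- function(clock, utc_target_s, at_reference_s, method = "GPS",
                      last_sync_utc_s = NULL) {
  stop_if_not_scalar_number(utc_target_s, "utc_target_s")
  stop_if_not_scalar_number(at_reference_s, "at_reference_s")
  wait_s <- (1 - (utc_target_s %% 1)) %% 1
  fire_ref_s <- at_reference_s + wait_s
  set_second <- utc_target_s + wait_s        # full UTC second, ms zeroed
  source_error_s <- utc_target_s - at_reference_s
  new_t_off <- source_error_s + clock$spec$set_latency_s
  measured_dev_ms <- (local_time(clock, at_reference_s) - utc_target_s) * 1000

  new_clock <- sim_clock(
    device_id = clock$device_id, spec = clock$spec, ppm = clock$ppm,
    t_off_s = new_t_off, anchor_s = fire_ref_s,
    last_sync_utc_s = if (is.null(last_sync_utc_s)) set_second else last_sync_utc_s
  )
  list(
    clock = new_clock,
    record = tibble(
      device_id = clock$device_id, method = method,
      reference_time_s = fire_ref_s,
      measured_deviation_ms = measured_dev_ms,
      applied = TRUE,
      post_sync_T_off_ms = new_t_off * 1000
    )
  )
}
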