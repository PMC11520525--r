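#' Scenario configuration for a fleet simulation
#'
#' Collects everything that defines a simulated deployment: fleet size and
#' horizon, the shared wake schedule (anchored to full UTC minutes), the
#' proximity-window geometry, resynchronisation threshold, airtime,
#' per-method noise models, clock hardware and drift rates, gateways, GPS
#' availability, and the movement (inside/outside) model. A scenario plus
#' its seed fully determines a simulation run.
#'
#' Drift rates: by default each device gets a constant rate drawn uniformly
#' from `[-max_drift_ppm, +max_drift_ppm]` under a sub-seed derived from the
#' device id (so a device's rate does not depend on fleet size). Supply
#' `ppm` as a numeric vector (one rate per device) or a list of
#' [ppm_profile()]s to override.
#'
#' @param n_devices number of tags.
#' @param horizon_s simulated duration, seconds.
#' @param period_s wake period, seconds; must be a multiple of 60.
#' @param window_ms transmit/receive window length, ms.
#' @param n_messages messages per device per window.
#' @param message_spacing_ms transmit spacing, ms.
#' @param threshold_ms collective resynchronisation threshold, ms (strict
#'   greater-than).
#' @param airtime_ms airtime estimate used by the receivers, ms.
#' @param airtime_true_ms true simulated airtime, ms (set different from
#'   `airtime_ms` to study estimator mismatch).
#' @param quantize_ms floor relative stamps to whole ms (hardware
#'   behaviour); off by default so noise-free runs are exact.
#' @param spec a [clock_spec()] shared by all tags.
#' @param ppm `NULL` (draw per device), numeric vector, or list of
#'   [ppm_profile()]s.
#' @param noise named list of [offset_noise_model()]s (`gps`, `wifi`,
#'   `proximity`), see [default_noise_models()].
#' @param meas_noise_mad_ms per-message deviation measurement noise
#'   (Laplace MAD, ms).
#' @param n_gateways number of fixed sniffing gateways.
#' @param gateway_ppm_max gateway clock class: rates drawn uniformly from
#'   `[-gateway_ppm_max, +gateway_ppm_max]`.
#' @param gps_enabled may devices attempt GPS synchronisation at all.
#' @param gps_fix_prob named vector `c(outside = , inside = )` of
#'   per-attempt fix probabilities.
#' @param contact `"all"` (every awake device hears every other; gateways
#'   hear everyone) or `"location"` (only devices inside the roost hear
#'   each other and the gateways; outside devices are isolated and may use
#'   GPS).
#' @param location parameters of the per-device two-state inside/outside
#'   Markov chain stepped once per wake period: `p_start_inside`,
#'   `p_in_to_out`, `p_out_to_in`. Placeholders — real dwell statistics are
#'   study-specific.
#' @param wifi_sync_period_s if non-`NULL`, every device synchronises via
#'   WiFi/NTP at multiples of this period (off by default).
#' @param initial_sync synchronise every device (GPS-style, with GPS noise)
#'   at time zero, as deployments do before release; `FALSE` starts all
#'   clocks exactly on time with zero offset.
#' @param seed master RNG seed for the run.
#' @return an object of class `scenario_config`.
#' @export
#' @examples
#' cfg <- scenario_config(n_devices = 3, horizon_s = 3600, seed = 7)
scenario_config <- function(n_devices,
                            horizon_s,
                            period_s = 300,
                            window_ms = 800,
                            n_messages = 8,
                            message_spacing_ms = 100,
                            threshold_ms = 50,
                            airtime_ms = 5.2,
                            airtime_true_ms = airtime_ms,
                            quantize_ms = FALSE,
                            spec = clock_spec(),
                            ppm = NULL,
                            noise = default_noise_models(),
                            meas_noise_mad_ms = 2,
                            n_gateways = 0,
                            gateway_ppm_max = 10,
                            gps_enabled = TRUE,
                            gps_fix_prob = c(outside = 0.9, inside = 0),
                            contact = c("all", "location"),
                            location = list(p_start_inside = 0.8,
                                            p_in_to_out = 0.05,
                                            p_out_to_in = 0.2),
                            wifi_sync_period_s = NULL,
                            initial_sync = TRUE,
                            seed = 1L) {
  contact <- match.arg(contact)
  if (n_devices < 1) abort("`n_devices` must be >= 1.")
  if (horizon_s < period_s) abort("`horizon_s` must cover at least one wake period.")
  if (period_s %% 60 != 0) {
    abort("`period_s` must be a multiple of 60 (wakeups anchor to full UTC minutes).")
  }
  if (message_spacing_ms * n_messages > window_ms) {
    abort("`message_spacing_ms * n_messages` exceeds the window length.")
  }
  probs <- c(gps_fix_prob, unlist(location))
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  if (!is.null(ppm) && !is.list(ppm) && length(ppm) != n_devices) {
    abort("`ppm` must have one entry per device.")
  }
  structure(
    list(n_devices = n_devices, horizon_s = horizon_s, period_s = period_s,
         window_ms = window_ms, n_messages = n_messages,
         message_spacing_ms = message_spacing_ms, threshold_ms = threshold_ms,
         airtime_ms = airtime_ms, airtime_true_ms = airtime_true_ms,
         quantize_ms = quantize_ms, spec = spec, ppm = ppm, noise = noise,
         meas_noise_mad_ms = meas_noise_mad_ms, n_gateways = n_gateways,
         gateway_ppm_max = gateway_ppm_max, gps_enabled = gps_enabled,
         gps_fix_prob = gps_fix_prob, contact = contact, location = location,
         wifi_sync_period_s = wifi_sync_period_s, initial_sync = initial_sync,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Noise-free noise models
#'
#' All three methods with zero median and zero MAD: useful for reducing a
#' simulation to exact drift arithmetic.
#'
#' @return a named list of [offset_noise_model()]s.
#' @export
zero_noise_models <- function() {
  list(
    gps = offset_noise_model("GPS", 0, 0),
    wifi = offset_noise_model("WIFI_NTP", 0, 0),
    proximity = offset_noise_model("PROXIMITY", 0, 0)
  )
}

#' The cave-roosting fruit-bat case-study scenario
#'
#' The deployment the simulator emulates by default: 99 tagged bats, four
#' sniffing gateways inside the roost, a 10-day horizon, wakeups every full
#' five UTC minutes, GPS resynchronisation outside the cave and
#' proximity-message resynchronisation inside (GPS is suppressed whenever a
#' gateway was heard), temperature-compensated RTCs rated at 3 ppm.
#'
#' @param seed master RNG seed.
#' @param n_devices,horizon_s,n_gateways overridable study dimensions
#'   (defaults are the full deployment; smaller values are useful for quick
#'   replicate runs).
#' @param ... further overrides passed to [scenario_config()].
#' @return a [scenario_config()].
#' @export
bat_scenario <- function(seed = 1L, n_devices = 99, horizon_s = 10 * 86400,
                         n_gateways = 4, ...) {
  scenario_config(
    n_devices = n_devices, horizon_s = horizon_s, period_s = 300,
    n_gateways = n_gateways, contact = "location", gps_enabled = TRUE,
    seed = seed, ...
  )
}

#' Two-tag stationary benchmark configuration
#'
#' Two stationary tags exchanging proximity messages every full UTC hour
#' over 16 days, with the collective 50 ms resynchronisation rule active —
#' the long-horizon relative-accuracy benchmark. One tag can be given a
#' different (e.g. temperature-driven) drift profile than the other via
#' `ppm`.
#'
#' @param ppm length-2 numeric or list of two [ppm_profile()]s.
#' @param horizon_s duration, default 16 days.
#' @param period_s exchange period, default 3600 s.
#' @param ... overrides passed to [scenario_config()].
#' @param seed master RNG seed.
#' @return a [scenario_config()].
#' @export
two_tag_config <- function(ppm = c(1.5, -1.5), horizon_s = 16 * 86400,
                           period_s = 3600, seed = 1L, ...) {
  scenario_config(
    n_devices = 2, horizon_s = horizon_s, period_s = period_s, ppm = ppm,
    n_gateways = 0, gps_enabled = FALSE, contact = "all", seed = seed, ...
  )
}

#' Write / read a scenario configuration as YAML
#'
#' Serialises every scalar field plus the clock spec, noise models and any
#' explicit per-device drift rates. Function-valued or profile-valued drift
#' specifications must be rebuilt in code.
#'
#' @param config a [scenario_config()].
#' @param path file path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a [scenario_config()].
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$spec <- unclass(x$spec)
  x$noise <- lapply(x$noise, function(m) {
    unclass(m)[c("method", "median_ms", "mad_ms", "family")]
  })
  x$gps_fix_prob <- as.list(x$gps_fix_prob)  # keep names through YAML
  if (is.list(x$ppm)) {
    abort("Profile-valued `ppm` cannot be serialised; rebuild in code.")
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- clock_spec(x$spec$max_drift_ppm, unlist(x$spec$temp_range),
                     x$spec$resolution_s, x$spec$set_latency_s)
  noise <- lapply(x$noise, function(m) {
    offset_noise_model(m$method, m$median_ms, m$mad_ms, m$family)
  })
  scenario_config(
    n_devices = x$n_devices, horizon_s = x$horizon_s, period_s = x$period_s,
    window_ms = x$window_ms, n_messages = x$n_messages,
    message_spacing_ms = x$message_spacing_ms, threshold_ms = x$threshold_ms,
    airtime_ms = x$airtime_ms, airtime_true_ms = x$airtime_true_ms,
    quantize_ms = x$quantize_ms, spec = spec,
    ppm = if (is.null(x$ppm)) NULL else unlist(x$ppm),
    noise = noise, meas_noise_mad_ms = x$meas_noise_mad_ms,
    n_gateways = x$n_gateways, gateway_ppm_max = x$gateway_ppm_max,
    gps_enabled = x$gps_enabled,
    gps_fix_prob = unlist(x$gps_fix_prob), contact = x$contact,
    location = x$location,
    wifi_sync_period_s = x$wifi_sync_period_s,
    initial_sync = x$initial_sync, seed = x$seed
  )
}
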