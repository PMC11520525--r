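#' Energy model for timekeeping
#'
#' Measured average costs of the synchronisation machinery: setting the RTC
#' after receiving a time (including the wait to the next full second)
#' costs 6.5 uWh; a WiFi/NTP synchronisation — connection, NTP exchange and
#' the RTC set — costs 412.5 uWh; simply keeping time between
#' synchronisations draws 720 nW (the RTC's supply current). GPS and
#' proximity synchronisations only add the RTC set, since the GPS fix and
#' the proximity messages are assumed to be recorded anyway as study data.
#'
#' @param e_sync_rtc_uWh energy per RTC set, microwatt-hours.
#' @param e_sync_wifi_uWh energy per WiFi/NTP synchronisation (includes the
#'   RTC set), microwatt-hours.
#' @param p_keep_nW keep-alive power, nanowatts.
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(e_sync_rtc_uWh = 6.5, e_sync_wifi_uWh = 412.5,
                         p_keep_nW = 720) {
  if (any(c(e_sync_rtc_uWh, e_sync_wifi_uWh, p_keep_nW) < 0)) {
    abort("Energy model parameters must be >= 0.")
  }
  structure(list(e_sync_rtc_uWh = e_sync_rtc_uWh,
                 e_sync_wifi_uWh = e_sync_wifi_uWh,
                 p_keep_nW = p_keep_nW),
            class = "energy_model")
}

#' Total timekeeping energy of a simulation (or of one device)
#'
#' `n_rtc_sets * 6.5 uWh + n_wifi_syncs * 412.5 uWh + keep-alive power x
#' duration`, where RTC sets are all applied non-WiFi synchronisations
#' (GPS and proximity) and keep-alive runs for the whole duration. The
#' accounting is additive over sync records and independent of their
#' order.
#'
#' @param log a `tagsync_log`, or a data frame of sync records with a
#'   `method` column.
#' @param model an [energy_model()].
#' @param duration_s timekeeping duration in seconds; defaults to the
#'   log's horizon. Per device.
#' @param per_device report energy per device (divide sync counts over the
#'   fleet)? Default `FALSE`: fleet totals with keep-alive counted once per
#'   device.
#' @return a tibble with columns `n_rtc_sets`, `n_wifi_syncs`,
#'   `keep_alive_uWh`, `sync_uWh`, `total_uWh`.
#' @export
#' @examples
#' energy_account(data.frame(method = character()), duration_s = 86400)
energy_account <- function(log, model = energy_model(), duration_s = NULL,
                           per_device = FALSE) {
  if (inherits(log, "tagsync_log")) {
    syncs <- log$syncs
    if (is.null(duration_s)) duration_s <- log$config$horizon_s
    n_dev <- log$config$n_devices
  } else {
    syncs <- as_tibble(log)
    if (is.null(duration_s)) abort("`duration_s` is required for a bare record table.")
    n_dev <- 1
  }
  if (duration_s < 0) abort("`duration_s` must be >= 0.")
  n_wifi <- sum(syncs$method == "WIFI_NTP")
  n_rtc <- sum(syncs$method != "WIFI_NTP")
  scale <- if (per_device) 1 / n_dev else 1
  keep_devices <- if (per_device) 1 else n_dev
  keep <- model$p_keep_nW * 1e-3 * duration_s / 3600 * keep_devices
  sync_e <- (n_rtc * model$e_sync_rtc_uWh + n_wifi * model$e_sync_wifi_uWh) * scale
  tibble(
    n_rtc_sets = n_rtc * scale, n_wifi_syncs = n_wifi * scale,
    keep_alive_uWh = keep, sync_uWh = sync_e, total_uWh = keep + sync_e
  )
}
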