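#' GPS time-delivery delay model
#'
#' GPS modules deliver the UTC time over a serial link after internal
#' position processing; the reported time therefore lags real time by a
#' delay that varies with the number of visible satellites. The delay is
#' modelled linearly: `delay_ms(n_sats) = c0 + c1 * n_sats`. The
#' coefficients are module-specific calibration inputs (estimated from
#' large numbers of fixes against a pulse-per-second reference); the
#' defaults are zero, i.e. no compensation.
#'
#' @param c0 fixed delay component, ms.
#' @param c1 per-visible-satellite component, ms.
#' @return an object of class `gps_delay_model`.
#' @export
gps_delay_model <- function(c0 = 0, c1 = 0) {
  stop_if_not_scalar_number(c0, "c0")
  stop_if_not_scalar_number(c1, "c1")
  structure(list(c0 = c0, c1 = c1), class = "gps_delay_model")
}

#' Delay-compensated GPS time
#'
#' Adds the modelled delivery delay back onto the UTC time reported by the
#' GPS module: because the report lags real time, the compensated estimate
#' is `reported + delay(n_sats)`. Time is only valid after a fix; a missing
#' report (`NA`) is rejected.
#'
#' @param reported_utc_ms UTC as reported by the module, milliseconds
#'   (vectorised).
#' @param n_sats number of visible satellites (>= 1, recycled).
#' @param model a [gps_delay_model()].
#' @return compensated UTC in milliseconds.
#' @export
#' @examples
#' gps_compensated_time(1e6, 8, gps_delay_model(c0 = 20, c1 = -1))
gps_compensated_time <- function(reported_utc_ms, n_sats,
                                 model = gps_delay_model()) {
  if (!inherits(model, "gps_delay_model")) {
    abort("`model` must be a gps_delay_model.")
  }
  if (any(is.na(reported_utc_ms))) {
    abort("No GPS time available (no fix).")
  }
  n_sats <- rep_len(n_sats, length(reported_utc_ms))
  if (any(n_sats < 1)) abort("`n_sats` must be >= 1 (time needs a fix).")
  reported_utc_ms + model$c0 + model$c1 * n_sats
}
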