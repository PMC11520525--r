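#' Synchronisation offset noise model
#'
#' Field measurements of synchronisation accuracy are reported as a median
#' offset and a (raw, unscaled) median absolute deviation. The model draws
#' offsets from a Laplace distribution located at the median and scaled so
#' that its MAD matches: for Laplace, MAD = scale * ln 2, hence
#' `scale = mad_ms / ln 2`. The heavy-tailed Laplace is a conservative
#' choice for timing residuals; the measurements themselves do not pin down
#' a family.
#'
#' @param method label (`"GPS"`, `"WIFI_NTP"`, `"PROXIMITY"`, ...).
#' @param median_ms location, milliseconds.
#' @param mad_ms spread as an unscaled MAD, milliseconds (>= 0).
#' @param family distribution family; only `"laplace"` is implemented.
#' @return an object of class `offset_noise_model`.
#' @export
#' @examples
#' offset_noise_model("GPS", 2.72, 12.47)
offset_noise_model <- function(method, median_ms, mad_ms, family = "laplace") {
  stop_if_not_scalar_number(median_ms, "median_ms")
  stop_if_not_scalar_number(mad_ms, "mad_ms")
  if (mad_ms < 0) abort("`mad_ms` must be >= 0.")
  family <- match.arg(family, "laplace")
  structure(
    list(method = method, median_ms = median_ms, mad_ms = mad_ms,
         family = family, scale_ms = mad_ms / log(2)),
    class = "offset_noise_model"
  )
}

#' Default per-method noise models
#'
#' Stationary-test accuracies of the three synchronisation methods, used to
#' parameterise the simulator: GPS median 2.72 ms (MAD 12.47), WiFi/NTP
#' median 0.43 ms (MAD 1.51), and proximity-message relative accuracy
#' median 5 ms (MAD 2) immediately after a resynchronisation.
#'
#' @return a named list of [offset_noise_model()] objects
#'   (`gps`, `wifi`, `proximity`).
#' @export
default_noise_models <- function() {
  list(
    gps = offset_noise_model("GPS", 2.72, 12.47),
    wifi = offset_noise_model("WIFI_NTP", 0.43, 1.51),
    proximity = offset_noise_model("PROXIMITY", 5, 2)
  )
}

#' Draw synchronisation offsets from a noise model
#'
#' Inverse-CDF Laplace sampling; deterministic under a fixed RNG seed. With
#' `mad_ms = 0` every draw equals the median.
#'
#' @param model an [offset_noise_model()].
#' @param n number of draws.
#' @return numeric vector of offsets in milliseconds.
#' @export
#' @examples
#' set.seed(1)
#' summary(sample_offset(offset_noise_model("GPS", 2.72, 12.47), 1000))
sample_offset <- function(model, n = 1) {
  if (!inherits(model, "offset_noise_model")) {
    abort("`model` must be an offset_noise_model.")
  }
  u <- runif(n, -0.5, 0.5)
  model$median_ms - model$scale_ms * sign(u) * log1p(-2 * abs(u))
}
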