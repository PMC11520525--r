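#' Estimate per-tag window start times in the gateway frame
#'
#' For every sniffed message, subtracting the in-window relative timestamp
#' from the gateway arrival timestamp estimates when that tag's window
#' started, expressed on the gateway's relative clock. Per tag and event
#' (and gateway), the median over its messages is taken — robust to a
#' corrupted message. Gateway clock drift within one 800 ms window is of
#' order ppm x 0.8 ms and cancels to first order in the later pairwise
#' differences; radio airtime cancels there exactly, so neither is
#' corrected here.
#'
#' @param sniffs a data frame of gateway sniff records with columns
#'   `gateway_id`, `event_id`, `gw_rel_arrival_ms`, `sender_id`, `rel_ms`
#'   (e.g. `log$sniffs` from [run_scenario()], or a CSV read of real
#'   gateway data).
#' @return a tibble with columns `gateway_id`, `event_id`, `device_id`,
#'   `start_ms`, `n_msgs`.
#' @export
start_times <- function(sniffs) {
  sniffs <- as_tibble(sniffs)
  need <- c("gateway_id", "event_id", "gw_rel_arrival_ms", "sender_id", "rel_ms")
  if (!all(need %in% names(sniffs))) {
    abort(sprintf("`sniffs` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (nrow(sniffs) == 0) abort("`sniffs` is empty.")
  sniffs %>%
    group_by(.data$gateway_id, .data$event_id, device_id = .data$sender_id) %>%
    summarise(
      start_ms = median(.data$gw_rel_arrival_ms - .data$rel_ms),
      n_msgs = n(), .groups = "drop"
    )
}

#' Pairwise relative time differences between tags in each event
#'
#' The signed start-time difference for every unordered pair of tags heard
#' in the same event by the same gateway; `delta_ms` is device `a` minus
#' device `b` with `a < b` by id, so differences are antisymmetric and,
#' within one event, exactly additive (`delta(a,c) = delta(a,b) +
#' delta(b,c)`). Events with fewer than two tags yield no rows.
#'
#' @param starts a start-time table from [start_times()].
#' @return a tibble with columns `gateway_id`, `event_id`, `device_a`,
#'   `device_b`, `delta_ms`.
#' @export
pairwise_relative_errors <- function(starts) {
  starts <- as_tibble(starts)
  a <- select(starts, "gateway_id", "event_id",
              device_a = "device_id", start_a = "start_ms")
  b <- select(starts, "gateway_id", "event_id",
              device_b = "device_id", start_b = "start_ms")
  inner_join(a, b, by = c("gateway_id", "event_id"),
             relationship = "many-to-many") %>%
    filter(.data$device_a < .data$device_b) %>%
    mutate(delta_ms = .data$start_a - .data$start_b) %>%
    select("gateway_id", "event_id", "device_a", "device_b", "delta_ms")
}

#' Median and (unscaled) median absolute deviation
#'
#' The reporting convention for all timing accuracies: the sample median
#' and the raw MAD, `median(|x - median(x)|)`, with no normal-consistency
#' scaling.
#'
#' @param x numeric vector (at least one value).
#' @return a tibble with columns `median`, `mad`, `n`.
#' @export
#' @examples
#' median_mad(c(1, 2, 4, 7))
median_mad <- function(x) {
  if (length(x) == 0 || !is.numeric(x)) abort("`x` must be non-empty numeric.")
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("`x` has no non-missing values.")
  m <- median(x)
  tibble(median = m, mad = median(abs(x - m)), n = length(x))
}

#' Guaranteed time-error budget versus resynchronisation interval
#'
#' Combines a quantile of the synchronisation-offset distribution with the
#' worst-case drift accumulated over a resynchronisation interval:
#'
#'   max T_error(q, interval) = base_q + ppm * 1e-6 * interval * 1000  [ms]
#'
#' rounded half away from zero. The base quantiles describe the offset a
#' single GPS/WiFi synchronisation leaves behind; the drift term is the
#' rated worst case for the clock over the ambient temperature range.
#' Cells are non-decreasing in the interval, the drift rate and the
#' quantile level.
#'
#' @param bases a data frame with columns `level` (quantile level, e.g.
#'   0.95) and `base_ms` (offset quantile, ms); extra columns (e.g. a
#'   temperature-range label) are carried through.
#' @param ppm worst-case drift rate over the temperature range.
#' @param intervals_s resynchronisation intervals, seconds.
#' @param digits rounding precision for the printed cells.
#' @return a tibble with one row per (base row x interval): the carried
#'   columns plus `ppm`, `resync_interval_s`, `level`, `max_T_error_ms`.
#' @export
#' @examples
#' error_budget_table(data.frame(level = 0.95, base_ms = 55.1),
#'                    ppm = 1.5, intervals_s = 86400)
error_budget_table <- function(bases, ppm, intervals_s, digits = 0) {
  bases <- as_tibble(bases)
  if (!all(c("level", "base_ms") %in% names(bases))) {
    abort("`bases` needs columns level and base_ms.")
  }
  if (ppm < 0 || any(intervals_s < 0) || any(bases$base_ms < 0)) {
    abort("`ppm`, `intervals_s` and `base_ms` must be >= 0.")
  }
  tidyr::crossing(bases, resync_interval_s = intervals_s) %>%
    mutate(
      ppm = ppm,
      max_T_error_ms = round_half_away(
        .data$base_ms + drift_budget(ppm, .data$resync_interval_s) * 1000,
        digits
      )
    ) %>%
    arrange(.data$resync_interval_s, .data$level)
}

#' Fit a drift rate to a time-error trace
#'
#' Least-squares slope of `T_error` against reference time, in parts per
#' million. Drift is generally not linear over long horizons (temperature
#' moves), so fit over windows in which the rate can be taken as constant;
#' on noiseless constant-rate data the fit is exact.
#'
#' @param trace a data frame with a time column (seconds, strictly
#'   increasing) and an error column (seconds).
#' @param t,err column names (tidyselect-style strings) of time and error;
#'   default `"t_s"` and `"T_error_s"`, matching simulation snapshots.
#' @return an object of class `ppm_fit` with elements `ppm`,
#'   `intercept_s`, `n`, and the underlying `lm` fit. [tidy()] and
#'   [glance()] methods are provided.
#' @export
#' @examples
#' tr <- data.frame(t_s = 0:10 * 3600, T_error_s = 3e-6 * 0:10 * 3600)
#' fit_ppm(tr)$ppm  # 3
fit_ppm <- function(trace, t = "t_s", err = "T_error_s") {
  trace <- as_tibble(trace)
  if (!all(c(t, err) %in% names(trace))) {
    abort(sprintf("`trace` needs columns `%s` and `%s`.", t, err))
  }
  tv <- trace[[t]]
  ev <- trace[[err]]
  if (length(tv) < 2) abort("Need at least two points to fit a drift rate.")
  if (any(diff(tv) <= 0)) abort("Time must be strictly increasing.")
  fit <- lm(ev ~ tv)
  structure(
    list(ppm = unname(coef(fit)[2]) * 1e6,
         intercept_s = unname(coef(fit)[1]),
         n = length(tv),
         window_s = range(tv),
         fit = fit),
    class = "ppm_fit"
  )
}

#' @export
print.ppm_fit <- function(x, ...) {
  cat(sprintf("<ppm_fit>  %.4f ppm over [%.0f, %.0f] s (n = %d)\n",
              x$ppm, x$window_s[1], x$window_s[2], x$n))
  invisible(x)
}

#' @rdname fit_ppm
#' @param x a `ppm_fit`.
#' @param ... unused.
#' @export
tidy.ppm_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept_s", "drift_ppm"),
    estimate = c(x$intercept_s, x$ppm),
    std.error = c(s[1, 2], s[2, 2] * 1e6),
    statistic = s[, 3],
    p.value = s[, 4]
  )
}

#' @rdname fit_ppm
#' @export
glance.ppm_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(ppm = x$ppm, r.squared = s$r.squared, sigma_s = s$sigma, n = x$n)
}
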