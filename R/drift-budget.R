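#' Seconds in the standard budget periods
#'
#' A day is 86,400 s, a week 604,800 s, and a month 31 days = 2,678,400 s
#' (the 31-day month is the convention the published worst-case tables use).
#'
#' @param period one or more of `"day"`, `"week"`, `"month"`.
#' @return numeric vector of seconds.
#' @export
#' @examples
#' period_seconds(c("day", "week", "month"))
period_seconds <- function(period) {
  lut <- c(day = 86400, week = 604800, month = 31 * 86400)
  bad <- setdiff(period, names(lut))
  if (length(bad)) abort(sprintf("Unknown period(s): %s", paste(bad, collapse = ", ")))
  unname(lut[period])
}

#' Worst-case accumulated drift for a rated clock
#'
#' `ppm * 1e-6 * duration_s`: the maximum time error a clock rated at
#' `ppm` parts per million can accumulate over `duration_s` seconds. This is
#' a hard bound — no drift trajectory whose instantaneous rate stays within
#' the rating can exceed it. Linear and monotone in both arguments.
#'
#' @param ppm rated maximum drift in parts per million (>= 0), vectorised.
#' @param duration_s duration in seconds (>= 0), vectorised.
#' @return worst-case drift in seconds.
#' @export
#' @examples
#' drift_budget(3, period_seconds("day"))      # 0.2592 s
#' drift_budget(20, period_seconds("month"))   # 53.568 s
drift_budget <- function(ppm, duration_s) {
  if (!is.numeric(ppm) || any(ppm < 0)) abort("`ppm` must be numeric >= 0.")
  if (!is.numeric(duration_s) || any(duration_s < 0)) {
    abort("`duration_s` must be numeric >= 0.")
  }
  ppm * 1e-6 * duration_s
}

#' Reference table of rated drifts for common logger components
#'
#' Published worst-case drift examples for oscillators commonly found on
#' bio-loggers, from an oven-controlled module down to an uncompensated
#' microcontroller oscillator. `printed_day_s`, `printed_week_s`,
#' `printed_month_s` are the worst-case drifts as printed (at the precision
#' given by the `digits_*` columns). The uncompensated-microcontroller row
#' prints a week value of 12,069 s where the arithmetic gives
#' 20,000 ppm x 604,800 s = 12,096 s; `week_flagged` marks that cell as a
#' suspected misprint.
#'
#' @return a tibble, one row per component.
#' @export
clock_drift_examples <- function() {
  tibble(
    component = c(
      "OCXO module, 0-50 degC",
      "TCXO RTC module, 0-50 degC",
      "TCXO RTC module, -40-85 degC",
      "80 MHz MCU oscillator, 25 degC",
      "XO RTC module, 0-50 degC",
      "MCU internal oscillator, 25 degC",
      "MCU internal oscillator, -40-125 degC"
    ),
    ppm = c(0.005, 1.5, 3, 10, 20, 20000, 140000),
    printed_day_s = c(0.0004, 0.13, 0.26, 0.86, 1.73, 1728, 12096),
    printed_week_s = c(0.0030, 0.9, 1.8, 6.0, 12.1, 12069, 84672),
    printed_month_s = c(0.0134, 4.0, 8.0, 26.8, 53.6, 53568, 374976),
    digits_day = c(4, 2, 2, 2, 2, 0, 0),
    digits_week = c(4, 1, 1, 1, 1, 0, 0),
    digits_month = c(4, 1, 1, 1, 1, 0, 0),
    week_flagged = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

#' Compute a drift-budget table for a set of components
#'
#' Applies [drift_budget()] per day/week/month to each component and rounds
#' each cell half-away-from-zero to the requested precision, reproducing the
#' layout of the published worst-case table.
#'
#' @param components a data frame with at least a `ppm` column; optional
#'   `component` labels and `digits_day`/`digits_week`/`digits_month`
#'   per-cell precisions (default: unrounded). Defaults to
#'   [clock_drift_examples()].
#' @return a tibble with columns `component`, `ppm`, `per_day_s`,
#'   `per_week_s`, `per_month_s`.
#' @export
#' @examples
#' drift_budget_table()
drift_budget_table <- function(components = clock_drift_examples()) {
  components <- as_tibble(components)
  if (!"ppm" %in% names(components)) abort("`components` needs a `ppm` column.")
  if (!"component" %in% names(components)) {
    components$component <- sprintf("clock_%d", seq_len(nrow(components)))
  }
  for (d in c("digits_day", "digits_week", "digits_month")) {
    if (!d %in% names(components)) components[[d]] <- Inf
  }
  rnd <- function(x, digits) {
    ifelse(is.finite(digits), round_half_away(x, digits), x)
  }
  tibble(
    component = components$component,
    ppm = components$ppm,
    per_day_s = rnd(drift_budget(components$ppm, period_seconds("day")),
                    components$digits_day),
    per_week_s = rnd(drift_budget(components$ppm, period_seconds("week")),
                     components$digits_week),
    per_month_s = rnd(drift_budget(components$ppm, period_seconds("month")),
                      components$digits_month)
  )
}
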