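#' NTP offset and round-trip delay from a four-timestamp exchange
#'
#' The onboard NTP algorithm assumes symmetric network delay on the
#' outbound and return paths. From the client send/receive times `t1`, `t4`
#' (client clock) and server receive/send times `t2`, `t3` (server clock):
#'
#'   offset = ((t2 - t1) + (t3 - t4)) / 2
#'   delay  = (t4 - t1) - (t3 - t2)
#'
#' Under exactly symmetric delays the offset estimate is exact; otherwise
#' its error is half the delay asymmetry. Only one exchange is used (no
#' multi-server averaging), to conserve energy.
#'
#' @param exchanges a data frame with numeric columns `t1`, `t2`, `t3`,
#'   `t4` in milliseconds (one row per exchange).
#' @return the input tibble with columns `offset_ms` and `delay_ms`
#'   appended.
#' @export
#' @examples
#' ntp_offset(data.frame(t1 = 0, t2 = 1105, t3 = 1107, t4 = 12))
ntp_offset <- function(exchanges) {
  exchanges <- as_tibble(exchanges)
  need <- c("t1", "t2", "t3", "t4")
  if (!all(need %in% names(exchanges))) {
    abort("`exchanges` needs columns t1, t2, t3, t4.")
  }
  if (any(exchanges$t4 < exchanges$t1) || any(exchanges$t3 < exchanges$t2)) {
    abort("Malformed exchange: requires t4 >= t1 and t3 >= t2.")
  }
  delay <- (exchanges$t4 - exchanges$t1) - (exchanges$t3 - exchanges$t2)
  if (any(delay < 0)) {
    abort("Malformed exchange: negative computed round-trip delay.")
  }
  mutate(
    exchanges,
    offset_ms = ((.data$t2 - .data$t1) + (.data$t3 - .data$t4)) / 2,
    delay_ms = delay
  )
}
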