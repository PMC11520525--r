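#' Build the proximity messages a device sends in one window
#'
#' Awake tags exchange proximity messages inside an 800 ms transmit/receive
#' window scheduled at a shared full UTC second: one message every 100 ms,
#' eight per window. The device begins its window when its own (erroneous)
#' clock reads the scheduled second; transmissions then follow a fixed-rate
#' hardware timer at the nominal spacing, while the relative timestamp
#' written into each message is read from the device's drifting clock — so
#' a clock running `p` ppm fast stamps the k-th message
#' `100k * (1 + p*1e-6)` ms (floored to ms resolution). Each message also
#' carries the device's UTC at second resolution and the UTC of its last
#' synchronisation.
#'
#' @param clock the sender's [sim_clock()].
#' @param window_start_utc_s scheduled window start (full UTC second).
#' @param n_messages messages per window (default 8).
#' @param spacing_ms nominal transmit spacing (default 100 ms).
#' @param window_ms window length (default 800 ms); `spacing_ms *
#'   n_messages` must not exceed it.
#' @param quantize_ms floor relative stamps to whole milliseconds, as the
#'   hardware counter would (default `FALSE`: keep exact values, so that a
#'   noise-free simulation stays exact arithmetic).
#' @return a tibble with one row per message: `sender_id`, `msg_idx`
#'   (0-based), `rel_ms`, `utc_s`, `last_sync_utc_s`,
#'   `window_start_utc_s`, and `stamp_ref_s`, the true reference time of
#'   the stamp (simulation-side bookkeeping, not part of the payload).
#' @export
#' @examples
#' build_window_messages(sim_clock("a"), 600)$rel_ms  # 0 100 ... 700
build_window_messages <- function(clock, window_start_utc_s, n_messages = 8,
                                  spacing_ms = 100, window_ms = 800,
                                  quantize_ms = FALSE) {
  if (spacing_ms * n_messages > window_ms) {
    abort("Message schedule does not fit the window.")
  }
  tau <- wake_time(clock, window_start_utc_s)
  k <- seq_len(n_messages) - 1
  stamp_ref <- tau + k * spacing_ms / 1000
  rel <- (local_time(clock, stamp_ref) - local_time(clock, tau)) * 1000
  rel_ms <- if (quantize_ms) floor(rel + 1e-9) else rel
  tibble(
    sender_id = clock$device_id,
    msg_idx = k,
    rel_ms = rel_ms,
    utc_s = window_start_utc_s + floor(rel_ms / 1000),
    last_sync_utc_s = clock$last_sync_utc_s,
    window_start_utc_s = window_start_utc_s,
    stamp_ref_s = stamp_ref
  )
}

#' Correct a received relative timestamp for radio airtime
#'
#' The sender's relative stamp refers to a point one airtime later than the
#' instant at which the receiver latches its own relative timestamp, so the
#' estimated airtime (5.2 ms by default) is subtracted from the received
#' value before comparison.
#'
#' @param rx_rel_ms received relative timestamp(s), ms (>= 0).
#' @param airtime_ms estimated radio airtime, ms.
#' @return corrected relative timestamp(s), ms.
#' @export
#' @examples
#' adjust_received_rel(100)  # 94.8
adjust_received_rel <- function(rx_rel_ms, airtime_ms = 5.2) {
  if (any(rx_rel_ms < 0)) abort("`rx_rel_ms` must be >= 0.")
  rx_rel_ms - airtime_ms
}

#' Per-message clock deviation implied by a received proximity message
#'
#' The receiver compares the airtime-corrected received relative timestamp
#' with its own relative timestamp at the latch instant; whole seconds of
#' disagreement are carried by the UTC-seconds field of the message:
#'
#'   deviation = 1000 * (own window second - sender's implied window second)
#'             + own_rel_ms - (rel_ms - airtime_ms)
#'
#' Positive deviation means the receiver's clock is ahead of the sender's.
#' Messages whose relative timestamp falls outside the window are ignored
#' (`NA`) with a warning.
#'
#' @param messages a data frame with columns `rel_ms` and `utc_s` (as built
#'   by [build_window_messages()]).
#' @param own_ws_utc_s the receiver's own window-start second.
#' @param own_rel_ms the receiver's own relative timestamp at each
#'   message's latch instant, ms (vector aligned with `messages`).
#' @param airtime_ms estimated airtime, ms.
#' @param window_ms window length, ms.
#' @return signed deviations in ms (one per message).
#' @export
proximity_deviation <- function(messages, own_ws_utc_s, own_rel_ms,
                                airtime_ms = 5.2, window_ms = 800) {
  messages <- as_tibble(messages)
  if (!all(c("rel_ms", "utc_s") %in% names(messages))) {
    abort("`messages` needs columns rel_ms and utc_s.")
  }
  outside <- messages$rel_ms < 0 | messages$rel_ms > window_ms
  if (any(outside)) {
    warn(sprintf("Ignoring %d message(s) outside the %g ms window.",
                 sum(outside), window_ms))
  }
  implied_ws <- messages$utc_s - floor(messages$rel_ms / 1000)
  dev <- 1000 * (own_ws_utc_s - implied_ws) +
    own_rel_ms - adjust_received_rel(messages$rel_ms, airtime_ms)
  dev[outside] <- NA_real_
  dev
}

#' Measure per-sender deviations for one receiver in one window
#'
#' Drives the full receive path: for each message the receiver latches its
#' own relative timestamp at the true arrival instant (one true airtime
#' before the sender's stamp point), optionally perturbed by per-message
#' measurement noise, floored to ms resolution, and compared through
#' [proximity_deviation()]. Per sender, the median over its messages is
#' returned — robust against a corrupted message.
#'
#' @param clock the receiver's [sim_clock()].
#' @param messages messages heard this window (rows from
#'   [build_window_messages()], any number of senders; must carry
#'   `stamp_ref_s`).
#' @param window_start_utc_s the receiver's scheduled window second.
#' @param airtime_est_ms airtime estimate used by the protocol, ms.
#' @param airtime_true_ms true simulated airtime, ms.
#' @param noise_mad_ms per-message measurement noise as a Laplace MAD, ms
#'   (0 disables noise).
#' @param window_ms window length, ms.
#' @param quantize_ms floor the receiver's own relative timestamps to whole
#'   milliseconds (default `FALSE`, see [build_window_messages()]).
#' @return a tibble with columns `sender_id`, `deviation_ms` (median over
#'   that sender's messages), `n_msgs`.
#' @export
measure_window_deviations <- function(clock, messages, window_start_utc_s,
                                      airtime_est_ms = 5.2,
                                      airtime_true_ms = airtime_est_ms,
                                      noise_mad_ms = 0, window_ms = 800,
                                      quantize_ms = FALSE) {
  messages <- as_tibble(messages)
  messages <- filter(messages, .data$sender_id != clock$device_id)
  if (nrow(messages) == 0) {
    return(tibble(sender_id = character(), deviation_ms = numeric(),
                  n_msgs = integer()))
  }
  tau_r <- wake_time(clock, window_start_utc_s)
  latch_ref <- messages$stamp_ref_s - airtime_true_ms / 1000
  own_rel <- (local_time(clock, pmax(latch_ref, clock$anchor_s)) -
                local_time(clock, tau_r)) * 1000
  if (noise_mad_ms > 0) {
    own_rel <- own_rel +
      sample_offset(offset_noise_model("MEAS", 0, noise_mad_ms), length(own_rel))
  }
  if (quantize_ms) own_rel <- floor(own_rel + 1e-9)
  dev <- proximity_deviation(messages, window_start_utc_s, own_rel,
                             airtime_ms = airtime_est_ms,
                             window_ms = window_ms)
  messages %>%
    mutate(deviation_ms = dev) %>%
    filter(!is.na(.data$deviation_ms)) %>%
    group_by(.data$sender_id) %>%
    summarise(deviation_ms = median(.data$deviation_ms), n_msgs = n(),
              .groups = "drop")
}

#' Decide on a collective resynchronisation after a proximity exchange
#'
#' If any measured pairwise deviation exceeds the threshold (strictly
#' greater than 50 ms by default), the group collectively synchronises to
#' the participant whose clock was most recently resynchronised — that
#' clock has accumulated the least drift and is the collectively trusted
#' time. Every other participant adopts the reference's time *and* its
#' last-synchronisation stamp, so the trusted time propagates through the
#' contact network even between devices that never meet directly. Ties on
#' the last-sync stamp break to the lowest device id (deterministic and
#' order-independent). Below the threshold nothing happens.
#'
#' @param participants a data frame with columns `device_id` and
#'   `last_sync_utc_s` (one row per device in the exchange).
#' @param deviations a data frame of measured deviations with a
#'   `deviation_ms` column (e.g. from [measure_window_deviations()]); may
#'   be empty.
#' @param threshold_ms resynchronisation threshold, ms.
#' @return a tibble with columns `device_id`, `action` (`"reference"`,
#'   `"adopt"`, or `"none"`), `reference_id`, `new_last_sync_utc_s`,
#'   `max_abs_deviation_ms`.
#' @export
#' @examples
#' parts <- data.frame(device_id = c("a", "b"),
#'                     last_sync_utc_s = c(43200, 21600))
#' resync_decide(parts, data.frame(deviation_ms = 60))
resync_decide <- function(participants, deviations, threshold_ms = 50) {
  participants <- as_tibble(participants)
  if (nrow(participants) == 0) abort("Empty participant set.")
  deviations <- as_tibble(deviations)
  max_dev <- if (nrow(deviations) == 0) 0 else
    max(abs(deviations$deviation_ms), na.rm = TRUE)

  if (!is.finite(max_dev) || max_dev <= threshold_ms) {
    return(mutate(participants[, "device_id"], action = "none",
                  reference_id = NA_character_,
                  new_last_sync_utc_s = participants$last_sync_utc_s,
                  max_abs_deviation_ms = max_dev))
  }
  ref <- participants %>%
    arrange(dplyr::desc(.data$last_sync_utc_s), .data$device_id) %>%
    head(1)
  tibble(
    device_id = participants$device_id,
    action = ifelse(participants$device_id == ref$device_id,
                    "reference", "adopt"),
    reference_id = as.character(ref$device_id),
    new_last_sync_utc_s = ref$last_sync_utc_s,
    max_abs_deviation_ms = max_dev
  )
}
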