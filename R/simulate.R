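#' Run a fleet simulation
#'
#' Discrete-event simulation of a fleet of tags (and optionally gateways)
#' over the scenario horizon. Every `period_s` seconds, at a shared full
#' UTC minute, each tag wakes by its own clock, exchanges proximity
#' messages inside the transmit/receive window with whoever it can hear,
#' measures pairwise clock deviations, and — if any deviation exceeds the
#' threshold — the group collectively adopts the clock with the most
#' recent synchronisation stamp. Gateways sniff the messages and annotate
#' arrivals on their own (drifting) relative clocks. A tag that heard no
#' gateway may attempt a GPS synchronisation, which succeeds with the
#' location-dependent fix probability. Two tags whose clocks disagree by
#' more than the window length have non-overlapping windows and cannot hear
#' each other that event; gateways, which listen continuously, still sniff
#' every awake tag.
#'
#' The run is a pure function of the configuration: identical config and
#' seed give byte-identical logs. All device clock reads go through the
#' drift-and-offset clock model; snapshots of the error decomposition are
#' taken at every wakeup.
#'
#' @param config a [scenario_config()].
#' @return an object of class `tagsync_log`: a list with the `config` and
#'   tibbles `snapshots` (per wakeup per device: `event_id`, `t_s`,
#'   `device_id`, `t_prime_s`, `T_drift_s`, `T_off_s`, `T_error_s`,
#'   `location`, `participated`), `syncs` (applied sync records) and
#'   `sniffs` (gateway sniff records).
#' @export
#' @examples
#' log <- run_scenario(scenario_config(n_devices = 3, horizon_s = 1800,
#'                                     seed = 42))
#' log$snapshots
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, run_scenario_impl(config))
}

run_scenario_impl <- function(config) {
  n <- config$n_devices
  ids <- sprintf("tag%03d", seq_len(n))
  spec <- config$spec
  K <- config$n_messages
  spacing_s <- config$message_spacing_ms / 1000
  air_true_s <- config$airtime_true_ms / 1000

  ppm_list <- device_ppm_rates(config, ids)
  clocks <- vector("list", n)
  for (i in seq_len(n)) {
    t_off0 <- if (isTRUE(config$initial_sync)) {
      sample_offset(config$noise$gps)[1] / 1000 + spec$set_latency_s
    } else 0
    clocks[[i]] <- sim_clock(ids[i], spec, ppm_list[[i]], t_off_s = t_off0,
                             anchor_s = 0, last_sync_utc_s = 0)
  }

  gw_ids <- if (config$n_gateways > 0) sprintf("gw%02d", seq_len(config$n_gateways)) else character()
  gw_ppm <- vapply(gw_ids, function(g) {
    with_seed(device_subseed(config$seed, g),
              runif(1, -config$gateway_ppm_max, config$gateway_ppm_max))
  }, numeric(1))

  use_location <- config$contact == "location"
  inside <- if (use_location) {
    runif(n) < config$location$p_start_inside
  } else rep(TRUE, n)

  n_win <- floor(config$horizon_s / config$period_s)
  snapshots <- vector("list", n_win)
  syncs <- list()
  sniffs <- list()

  for (w in seq_len(n_win)) {
    t_w <- w * config$period_s

    if (use_location) {
      u <- runif(n)
      inside <- ifelse(inside, u >= config$location$p_in_to_out,
                       u < config$location$p_out_to_in)
    }

    e <- vapply(clocks, function(ck) local_time(ck, t_w) - t_w, numeric(1))
    t_off <- vapply(clocks, function(ck) ck$t_off_s, numeric(1))
    last_sync <- vapply(clocks, function(ck) ck$last_sync_utc_s, numeric(1))

    P <- which(inside)

    snapshots[[w]] <- tibble(
      event_id = w, t_s = t_w, device_id = ids,
      t_prime_s = t_w + e, T_drift_s = e - t_off, T_off_s = t_off,
      T_error_s = e,
      location = ifelse(inside, "INSIDE", "OUTSIDE"),
      participated = inside
    )

    heard_gateway <- rep(FALSE, n)

    if (length(P) >= 1) {
      m <- length(P)
      tau <- vapply(clocks[P], function(ck) wake_time(ck, t_w), numeric(1))
      ks <- (seq_len(K) - 1) * spacing_s
      stamp <- outer(tau, ks, "+")                       # m x K true stamp times
      rel <- t(vapply(seq_len(m), function(si) {
        ck <- clocks[[P[si]]]
        (local_time(ck, stamp[si, ]) - local_time(ck, tau[si])) * 1000
      }, numeric(K)))
      if (config$quantize_ms) rel <- floor(rel + 1e-9)
      latch <- stamp - air_true_s

      if (config$n_gateways > 0) {
        heard_gateway[P] <- TRUE
        for (gi in seq_along(gw_ids)) {
          arr <- latch * (1 + gw_ppm[gi] * 1e-6) * 1000
          if (config$quantize_ms) arr <- floor(arr + 1e-9)
          sniffs[[length(sniffs) + 1L]] <- tibble(
            gateway_id = gw_ids[gi], event_id = w,
            gw_rel_arrival_ms = as.vector(t(arr)),
            sender_id = rep(ids[P], each = K),
            rel_ms = as.vector(t(rel)),
            utc_s = t_w + floor(as.vector(t(rel)) / 1000),
            last_sync_utc_s = rep(last_sync[P], each = K)
          )
        }
      }

      if (m >= 2) {
        # a pair can only exchange if their windows overlap: a device whose
        # clock differs from a peer's by more than the window length hears
        # nothing from it that event
        audible <- abs(outer(tau, tau, "-")) <= config$window_ms / 1000
        dev_pair <- matrix(NA_real_, m, m)  # [receiver, sender]
        for (ri in seq_len(m)) {
          ck <- clocks[[P[ri]]]
          own <- (local_time(ck, pmax(latch, ck$anchor_s)) -
                    local_time(ck, tau[ri])) * 1000
          if (config$meas_noise_mad_ms > 0) {
            own <- own + matrix(
              sample_offset(offset_noise_model("MEAS", 0, config$meas_noise_mad_ms),
                            m * K), m, K)
          }
          if (config$quantize_ms) own <- floor(own + 1e-9)
          devs <- own - (rel - config$airtime_ms)
          dev_pair[ri, ] <- apply(devs, 1, median)
        }
        dev_pair[!audible] <- NA_real_
        diag(dev_pair) <- NA_real_

        heard_any <- rowSums(!is.na(dev_pair)) + colSums(!is.na(dev_pair)) > 0
        max_dev <- suppressWarnings(max(abs(dev_pair), na.rm = TRUE))
        if (is.finite(max_dev) && max_dev > config$threshold_ms) {
          # only devices that exchanged at least one message take part
          E <- which(heard_any)
          parts <- tibble(device_id = ids[P][E], last_sync_utc_s = last_sync[P][E])
          decision <- resync_decide(parts,
                                    tibble(deviation_ms = as.vector(dev_pair)),
                                    config$threshold_ms)
          ref_idx <- P[match(decision$reference_id[1], ids[P])]
          t_sync <- t_w + 1
          err_ref <- local_time(clocks[[ref_idx]], t_sync) - t_sync
          adopters <- decision$device_id[decision$action == "adopt"]
          for (aid in adopters) {
            ai <- match(aid, ids)
            resid <- sample_offset(config$noise$proximity)[1] / 1000
            res <- set_clock(clocks[[ai]],
                             utc_target_s = t_sync + err_ref + resid,
                             at_reference_s = t_sync,
                             method = "PROXIMITY",
                             last_sync_utc_s = clocks[[ref_idx]]$last_sync_utc_s)
            clocks[[ai]] <- res$clock
            syncs[[length(syncs) + 1L]] <-
              mutate(res$record, event_id = w, reference_id = ids[ref_idx])
          }
        }
      }
    }

    if (!is.null(config$wifi_sync_period_s) &&
        t_w %% config$wifi_sync_period_s == 0) {
      t_sync <- t_w + 3
      for (i in seq_len(n)) {
        err <- sample_offset(config$noise$wifi)[1] / 1000
        res <- set_clock(clocks[[i]], utc_target_s = t_sync + err,
                         at_reference_s = t_sync, method = "WIFI_NTP")
        clocks[[i]] <- res$clock
        syncs[[length(syncs) + 1L]] <-
          mutate(res$record, event_id = w, reference_id = NA_character_)
      }
    }

    if (config$gps_enabled) {
      t_sync <- t_w + 2
      for (i in seq_len(n)) {
        if (gps_gate(heard_gateway[i])) {
          ploc <- if (use_location && inside[i]) "inside" else "outside"
          if (runif(1) < config$gps_fix_prob[[ploc]]) {
            err <- sample_offset(config$noise$gps)[1] / 1000
            res <- set_clock(clocks[[i]], utc_target_s = t_sync + err,
                             at_reference_s = t_sync, method = "GPS")
            clocks[[i]] <- res$clock
            syncs[[length(syncs) + 1L]] <-
              mutate(res$record, event_id = w, reference_id = NA_character_)
          }
        }
      }
    }
  }

  structure(
    list(
      config = config,
      snapshots = list_rbind(snapshots),
      syncs = if (length(syncs)) list_rbind(syncs) else empty_sync_records(),
      sniffs = if (length(sniffs)) list_rbind(sniffs) else empty_sniff_records(),
      final_clocks = clocks
    ),
    class = "tagsync_log"
  )
}

#' Should a device attempt a GPS synchronisation this wakeup?
#'
#' GPS is suppressed whenever at least one gateway was heard during the
#' proximity window — hearing a gateway means the tag is in the roost where
#' satellites are obstructed, and skipping the GPS attempt saves energy.
#'
#' @param gateway_heard was any gateway heard this window (vectorised).
#' @return logical: `TRUE` when GPS should be attempted.
#' @export
#' @examples
#' gps_gate(c(TRUE, FALSE))
gps_gate <- function(gateway_heard) {
  !gateway_heard
}

empty_sync_records <- function() {
  tibble(device_id = character(), method = character(),
         reference_time_s = numeric(), measured_deviation_ms = numeric(),
         applied = logical(), post_sync_T_off_ms = numeric(),
         event_id = integer(), reference_id = character())
}

empty_sniff_records <- function() {
  tibble(gateway_id = character(), event_id = integer(),
         gw_rel_arrival_ms = numeric(), sender_id = character(),
         rel_ms = numeric(), utc_s = numeric(), last_sync_utc_s = numeric())
}

device_ppm_rates <- function(config, ids) {
  if (is.null(config$ppm)) {
    lapply(ids, function(id) {
      with_seed(device_subseed(config$seed, id),
                runif(1, -config$spec$max_drift_ppm, config$spec$max_drift_ppm))
    })
  } else if (is.list(config$ppm)) {
    config$ppm
  } else {
    as.list(config$ppm)
  }
}

#' @export
print.tagsync_log <- function(x, ...) {
  cat(sprintf(
    "<tagsync_log>  %d device(s), %d wakeup(s), %d sync record(s), %d sniff record(s)\n",
    x$config$n_devices, max(x$snapshots$event_id), nrow(x$syncs), nrow(x$sniffs)))
  invisible(x)
}

#' Run the two-tag stationary benchmark
#'
#' Convenience wrapper around [run_scenario()] for the 16-day two-tag
#' relative-accuracy benchmark: validates that the scenario has exactly two
#' devices and an hourly-or-slower schedule and returns the event log,
#' whose snapshots give the continuous relative-error trace (see
#' [relative_errors()]). Auto-resynchronisations at the 50 ms threshold
#' appear in `$syncs`.
#'
#' @param config a [two_tag_config()] (or any two-device
#'   [scenario_config()]).
#' @return a `tagsync_log`.
#' @export
stationary_two_tag_experiment <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n_devices != 2) {
    abort("The stationary benchmark needs exactly 2 devices.")
  }
  run_scenario(config)
}

#' Pairwise relative time errors at every wakeup
#'
#' From the snapshot table of a simulation log: the signed difference of
#' clock errors for every unordered device pair at every wakeup,
#' `rel_error_ms = 1000 * (T_error_a - T_error_b)` with `a < b` by device
#' id.
#'
#' @param log a `tagsync_log`.
#' @param participating_only restrict to devices that took part in the
#'   window's exchange.
#' @return a tibble with columns `event_id`, `t_s`, `device_a`,
#'   `device_b`, `rel_error_ms`.
#' @export
relative_errors <- function(log, participating_only = FALSE) {
  stopifnot(inherits(log, "tagsync_log"))
  snap <- log$snapshots
  if (participating_only) snap <- filter(snap, .data$participated)
  a <- select(snap, "event_id", "t_s", device_a = "device_id", err_a = "T_error_s")
  b <- select(snap, "event_id", device_b = "device_id", err_b = "T_error_s")
  inner_join(a, b, by = "event_id", relationship = "many-to-many") %>%
    filter(.data$device_a < .data$device_b) %>%
    mutate(rel_error_ms = 1000 * (.data$err_a - .data$err_b)) %>%
    select("event_id", "t_s", "device_a", "device_b", "rel_error_ms")
}
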