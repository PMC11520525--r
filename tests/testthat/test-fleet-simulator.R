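quiet_cfg <- function(...) {
  scenario_config(..., noise = zero_noise_models(), meas_noise_mad_ms = 0,
                  initial_sync = FALSE, gps_enabled = FALSE)
}

test_that("zero noise and zero drift give zero deviation everywhere", {
  cfg <- quiet_cfg(n_devices = 2, horizon_s = 1800, ppm = c(0, 0), seed = 1)
  log <- run_scenario(cfg)
  re <- relative_errors(log)
  expect_true(all(re$rel_error_ms == 0))
  expect_equal(nrow(log$syncs), 0)
})

test_that("an unsynchronised 3 ppm clock accumulates the budgeted daily drift", {
  cfg <- quiet_cfg(n_devices = 1, horizon_s = 86400, ppm = 3, seed = 1)
  log <- run_scenario(cfg)
  last <- dplyr::filter(log$snapshots, t_s == 86400)
  expect_equal(last$T_error_s, drift_budget(3, 86400))  # 0.2592 s
  expect_equal(last$T_error_s, 0.2592)
})

test_that("a day of five-minute wakeups is 288 events", {
  cfg <- quiet_cfg(n_devices = 2, horizon_s = 86400, ppm = c(1, -1), seed = 1)
  log <- run_scenario(cfg)
  expect_equal(max(log$snapshots$event_id), 288)
  expect_equal(nrow(log$snapshots), 288 * 2)
})

test_that("identical config and seed reproduce the log exactly", {
  cfg <- bat_scenario(seed = 11, n_devices = 6, horizon_s = 2 * 3600,
                      n_gateways = 2)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$syncs, b$syncs)
  expect_identical(a$sniffs, b$sniffs)

  c2 <- run_scenario(bat_scenario(seed = 12, n_devices = 6,
                                  horizon_s = 2 * 3600, n_gateways = 2))
  expect_false(identical(a$snapshots$T_error_s, c2$snapshots$T_error_s))
})

test_that("hearing a gateway suppresses the GPS attempt", {
  expect_false(gps_gate(TRUE))
  expect_true(gps_gate(FALSE))

  # all inside with gateways present: no GPS records at all
  cfg <- scenario_config(
    n_devices = 4, horizon_s = 3600, n_gateways = 1, contact = "location",
    location = list(p_start_inside = 1, p_in_to_out = 0, p_out_to_in = 0),
    noise = zero_noise_models(), meas_noise_mad_ms = 0, initial_sync = FALSE,
    seed = 2
  )
  log <- run_scenario(cfg)
  expect_equal(sum(log$syncs$method == "GPS"), 0)
  expect_gt(nrow(log$sniffs), 0)

  # all outside with certain fixes: a GPS record per device per wakeup
  cfg2 <- scenario_config(
    n_devices = 3, horizon_s = 900, n_gateways = 1, contact = "location",
    location = list(p_start_inside = 0, p_in_to_out = 1, p_out_to_in = 0),
    gps_fix_prob = c(outside = 1, inside = 0),
    noise = zero_noise_models(), meas_noise_mad_ms = 0, initial_sync = FALSE,
    seed = 2
  )
  log2 <- run_scenario(cfg2)
  expect_equal(sum(log2$syncs$method == "GPS"), 3 * 3)

  # fix failures leave no record and the clock keeps drifting
  cfg3 <- scenario_config(
    n_devices = 1, horizon_s = 86400, ppm = 3, contact = "all",
    gps_fix_prob = c(outside = 0, inside = 0),
    noise = zero_noise_models(), meas_noise_mad_ms = 0, initial_sync = FALSE,
    seed = 2
  )
  log3 <- run_scenario(cfg3)
  expect_equal(nrow(log3$syncs), 0)
  expect_equal(max(log3$snapshots$T_error_s), 0.2592)
})

test_that("energy accounting is additive and matches the per-event costs", {
  empty <- energy_account(data.frame(method = character()), duration_s = 0)
  expect_equal(empty$total_uWh, 0)

  keep <- energy_account(data.frame(method = character()), duration_s = 86400)
  expect_equal(keep$total_uWh, 17.28)  # 0.72 uW for 24 h

  one_wifi <- energy_account(data.frame(method = "WIFI_NTP"),
                             duration_s = 86400)
  expect_equal(one_wifi$total_uWh, 412.5 + 17.28)

  mixed <- data.frame(method = c("GPS", "PROXIMITY", "WIFI_NTP", "GPS"))
  acc <- energy_account(mixed, duration_s = 3600)
  expect_equal(acc$sync_uWh, 3 * 6.5 + 412.5)
  # permutation invariance
  perm <- energy_account(mixed[c(3, 1, 4, 2), , drop = FALSE],
                         duration_s = 3600)
  expect_equal(acc, perm)
  # additivity over a split of the records
  a <- energy_account(mixed[1:2, , drop = FALSE], duration_s = 1800)
  b <- energy_account(mixed[3:4, , drop = FALSE], duration_s = 1800)
  expect_equal(a$total_uWh + b$total_uWh, acc$total_uWh)
})

test_that("the two-tag benchmark resynchronises at the analytic crossing time", {
  # relative drift 3 ppm, hourly exchanges, 50 ms threshold:
  # crossing at 0.05 / 3e-6 s, acted on at the next full-hour exchange
  cfg <- two_tag_config(ppm = c(1.5, -1.5), horizon_s = 6 * 86400,
                        noise = zero_noise_models(), meas_noise_mad_ms = 0,
                        initial_sync = FALSE, seed = 3)
  log <- stationary_two_tag_experiment(cfg)
  first <- min(log$syncs$reference_time_s)
  analytic <- ceiling(0.05 / 3e-6 / 3600) * 3600
  expect_lt(abs(first - analytic), 5)  # sync fires seconds after the window
  expect_true(all(log$syncs$method == "PROXIMITY"))

  # no relative drift: no resynchronisation ever
  cfg0 <- two_tag_config(ppm = c(2, 2), horizon_s = 4 * 86400,
                         noise = zero_noise_models(), meas_noise_mad_ms = 0,
                         initial_sync = FALSE, seed = 3)
  expect_equal(nrow(stationary_two_tag_experiment(cfg0)$syncs), 0)

  expect_error(
    stationary_two_tag_experiment(
      quiet_cfg(n_devices = 3, horizon_s = 3600, ppm = c(0, 0, 0))),
    "exactly 2"
  )
})

test_that("post-sync relative error stays below threshold plus inter-exchange drift plus noise", {
  mads <- 2
  cfg <- two_tag_config(ppm = c(1.5, -1.5), horizon_s = 16 * 86400,
                        meas_noise_mad_ms = mads, initial_sync = TRUE,
                        seed = 7)
  log <- stationary_two_tag_experiment(cfg)
  re <- relative_errors(log)
  # bound: threshold + relative drift over one exchange period
  #        + post-sync residual and measurement-noise allowance (99.9th pct)
  noise_q <- stats::qexp(0.999) * (2 / log(2)) + 5  # Laplace tail + residual median
  bound <- 50 + 3e-6 * 3600 * 1000 + 2 * noise_q
  expect_lt(max(abs(re$rel_error_ms)), bound)
  # and the trace is qualitatively the published one: tens of ms, not seconds
  expect_lt(median(abs(re$rel_error_ms)), 60)
})

test_that("scenario validation and YAML round-trip", {
  expect_error(scenario_config(2, 3600, period_s = 90), "multiple of 60")
  expect_error(scenario_config(2, 3600, message_spacing_ms = 150), "exceeds")
  expect_error(scenario_config(2, 3600, gps_fix_prob = c(outside = 2, inside = 0)),
               "probabilities")
  expect_error(scenario_config(0, 3600), "n_devices")
  expect_error(scenario_config(2, 100), "horizon")
  expect_error(scenario_config(3, 3600, ppm = c(1, 2)), "per device")

  cfg <- scenario_config(n_devices = 4, horizon_s = 7200, ppm = c(1, -1, 2, 0),
                         n_gateways = 2, contact = "location", seed = 42)
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(cfg, tf)
  back <- read_scenario(tf)
  expect_equal(back, cfg)
  # and a round-tripped config reproduces the same simulation
  expect_identical(run_scenario(cfg)$snapshots, run_scenario(back)$snapshots)
})
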