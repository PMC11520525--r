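sniff_row <- function(gw, ev, arr, sender, rel) {
  tibble::tibble(gateway_id = gw, event_id = ev, gw_rel_arrival_ms = arr,
                 sender_id = sender, rel_ms = rel)
}

test_that("start times subtract the in-window stamp from the gateway arrival", {
  one <- start_times(sniff_row("gw1", 1, 1000, "a", 100))
  expect_equal(one$start_ms, 900)

  # two perfectly synced tags: identical start-time estimates
  s <- dplyr::bind_rows(
    sniff_row("gw1", 1, c(500, 600, 700), "a", c(0, 100, 200)),
    sniff_row("gw1", 1, c(500, 600, 700), "b", c(0, 100, 200))
  )
  st <- start_times(s)
  expect_equal(st$start_ms[st$device_id == "a"],
               st$start_ms[st$device_id == "b"])

  # the per-tag estimate is a median over messages: one corrupt row is absorbed
  cor <- dplyr::bind_rows(sniff_row("gw1", 1, c(500, 600, 9999), "a", c(0, 100, 200)))
  expect_equal(start_times(cor)$start_ms, 500)

  expect_error(start_times(sniff_row("g", 1, 1, "a", 0)[0, ]), "empty")
})

test_that("an injected offset between tags appears in their start-time gap", {
  # tag B's clock set 30 ms behind tag A's; airtime cancels in the pair
  cfg <- scenario_config(
    n_devices = 2, horizon_s = 600, ppm = c(0, 0), n_gateways = 1,
    contact = "location",
    location = list(p_start_inside = 1, p_in_to_out = 0, p_out_to_in = 0),
    noise = zero_noise_models(), meas_noise_mad_ms = 0, initial_sync = FALSE,
    gps_enabled = FALSE, threshold_ms = 1e9, seed = 8
  )
  log <- run_scenario(cfg)
  # push a -30 ms offset into tag002's sniffed stamps by shifting arrivals:
  # equivalent to tag002 waking 30 ms late (clock 30 ms behind)
  sn <- log$sniffs
  sn$gw_rel_arrival_ms[sn$sender_id == "tag002"] <-
    sn$gw_rel_arrival_ms[sn$sender_id == "tag002"] + 30
  pr <- pairwise_relative_errors(start_times(sn))
  expect_equal(unique(pr$device_a), "tag001")
  expect_equal(pr$delta_ms, rep(-30, nrow(pr)), tolerance = 1e-6)
})

test_that("pairwise differences are antisymmetric, additive, and complete", {
  st <- tibble::tibble(gateway_id = "gw1", event_id = 1,
                       device_id = c("a", "b", "c"),
                       start_ms = c(0, 30, 70), n_msgs = 8)
  pr <- pairwise_relative_errors(st)
  expect_equal(nrow(pr), 3)  # n(n-1)/2
  get <- function(x, y) {
    r <- pr[pr$device_a == x & pr$device_b == y, ]
    r$delta_ms
  }
  expect_equal(get("a", "b"), -30)
  expect_equal(get("a", "c"), -70)
  expect_equal(get("b", "c"), -40)
  # additivity within the event
  expect_equal(get("a", "c"), get("a", "b") + get("b", "c"))

  same <- pairwise_relative_errors(
    tibble::tibble(gateway_id = "g", event_id = 1,
                   device_id = c("a", "b"), start_ms = c(5, 5), n_msgs = 8))
  expect_equal(same$delta_ms, 0)

  n <- 7
  many <- pairwise_relative_errors(
    tibble::tibble(gateway_id = "g", event_id = 1,
                   device_id = sprintf("d%d", 1:n), start_ms = rnorm(n),
                   n_msgs = 8))
  expect_equal(nrow(many), n * (n - 1) / 2)

  lone <- pairwise_relative_errors(
    tibble::tibble(gateway_id = "g", event_id = 1, device_id = "a",
                   start_ms = 0, n_msgs = 8))
  expect_equal(nrow(lone), 0)
})

test_that("median and raw MAD match a sort-based oracle", {
  expect_equal(median_mad(rep(4.2, 10)),
               tibble::tibble(median = 4.2, mad = 0, n = 10L))
  expect_equal(median_mad(c(1, 2, 4, 7)),
               tibble::tibble(median = 3, mad = 1.5, n = 4L))
  set.seed(21)
  for (rep in 1:10) {
    x <- rnorm(sample(1:50, 1), sd = 10)
    got <- median_mad(x)
    want <- oracle_median_mad(x)
    expect_equal(got$median, unname(want["median"]))
    expect_equal(got$mad, unname(want["mad"]))
  }
  expect_error(median_mad(numeric(0)), "non-empty")
})

test_that("the guaranteed-error budget combines offset quantiles with worst-case drift", {
  # interval 0: the budget is just the rounded base quantile
  b0 <- error_budget_table(data.frame(level = 0.95, base_ms = 55.1),
                           ppm = 1.5, intervals_s = 0)
  expect_equal(b0$max_T_error_ms, 55)

  # wide-range clock, hourly resync: 55.2 + 10.8 = 66 exactly
  b1 <- error_budget_table(data.frame(level = 0.95, base_ms = 55.2),
                           ppm = 3, intervals_s = 3600)
  expect_equal(b1$max_T_error_ms, 66)

  # monotone in interval, level and ppm
  bases <- data.frame(level = c(0.75, 0.85, 0.95),
                      base_ms = c(17.1, 26.1, 55.1))
  tab <- error_budget_table(bases, ppm = 1.5,
                            intervals_s = c(600, 3600, 86400))
  by_level <- split(tab, tab$level)
  for (g in by_level) {
    expect_true(all(diff(g$max_T_error_ms[order(g$resync_interval_s)]) >= 0))
  }
  by_int <- split(tab, tab$resync_interval_s)
  for (g in by_int) {
    expect_true(all(diff(g$max_T_error_ms[order(g$level)]) >= 0))
  }
  tab3 <- error_budget_table(bases, ppm = 3, intervals_s = c(600, 3600, 86400))
  expect_true(all(tab3$max_T_error_ms >= tab$max_T_error_ms))

  expect_error(error_budget_table(bases, ppm = -1, intervals_s = 600), ">= 0")
})

test_that("drift-rate fitting recovers known rates", {
  tr <- data.frame(t_s = 0:24 * 3600, T_error_s = 3e-6 * 0:24 * 3600)
  fit <- fit_ppm(tr)
  expect_equal(fit$ppm, 3, tolerance = 1e-9)

  # Laplace-noised 16-day hourly trace at 2 ppm: within 5 %
  set.seed(31)
  t <- 0:(16 * 24) * 3600
  err <- 2e-6 * t + sample_offset(offset_noise_model("M", 0, 2), length(t)) / 1000
  fitn <- fit_ppm(data.frame(t_s = t, T_error_s = err))
  expect_equal(fitn$ppm, 2, tolerance = 0.05)

  # rate reversal halfway: whole-window fit collapses towards zero
  t2 <- 0:100 * 100
  clk <- sim_clock("x", ppm = data.frame(start_s = c(0, 5000),
                                         end_s = c(5000, Inf),
                                         ppm = c(2, -2)))
  tr2 <- decompose_error(clk, t2)
  expect_lt(abs(fit_ppm(tr2)$ppm), 0.2)

  td <- tidy(fitn)
  expect_equal(td$term, c("intercept_s", "drift_ppm"))
  expect_equal(td$estimate[2], fitn$ppm)
  gl <- glance(fitn)
  expect_gt(gl$r.squared, 0.99)

  expect_error(fit_ppm(data.frame(t_s = 1, T_error_s = 0)), "two points")
  expect_error(fit_ppm(data.frame(t_s = c(1, 1), T_error_s = c(0, 0))),
               "strictly increasing")
})

test_that("gateway clock drift cancels within an event", {
  cfg <- scenario_config(
    n_devices = 3, horizon_s = 600, ppm = c(1, -2, 3), n_gateways = 2,
    gateway_ppm_max = 10, contact = "location",
    location = list(p_start_inside = 1, p_in_to_out = 0, p_out_to_in = 0),
    noise = zero_noise_models(), meas_noise_mad_ms = 0, initial_sync = FALSE,
    gps_enabled = FALSE, threshold_ms = 1e9, seed = 19
  )
  log <- run_scenario(cfg)
  pr <- pairwise_relative_errors(start_times(log$sniffs))
  wide <- tidyr::pivot_wider(pr, id_cols = c("event_id", "device_a", "device_b"),
                             names_from = "gateway_id",
                             values_from = "delta_ms")
  gws <- setdiff(names(wide), c("event_id", "device_a", "device_b"))
  # two gateways of the +/-10 ppm class disagree by < ppm x window ~ 1e-4 ms
  expect_lt(max(abs(wide[[gws[1]]] - wide[[gws[2]]])), 1e-3)
})

test_that("the full evaluation chain keeps fleet relative error inside the drift-and-noise bound", {
  cfg <- bat_scenario(seed = 23, n_devices = 8, horizon_s = 12 * 3600,
                      n_gateways = 2)
  log <- run_scenario(cfg)
  pr <- pairwise_relative_errors(start_times(log$sniffs))
  expect_gt(nrow(pr), 100)
  stats <- median_mad(abs(pr$delta_ms))
  # threshold + worst relative drift over a wake period + noise allowance
  noise_q <- stats::qexp(0.999) * (12.47 / log(2)) + 5
  bound <- 50 + 2 * 3e-6 * 300 * 1000 + 2 * noise_q
  expect_lt(stats$median, bound)
  # snapshots agree in order of magnitude with the sniff-based estimate
  snap_rel <- relative_errors(log, participating_only = TRUE)
  expect_lt(abs(median(abs(snap_rel$rel_error_ms)) - stats$median), 25)
})
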