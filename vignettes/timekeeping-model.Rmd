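---
title: "Modelling and resynchronising bio-logger clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and resynchronising bio-logger clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagsync)
library(dplyr)
```

## The time-error model

Animal-borne tags derive time by counting ticks of electronic oscillators.
`tagsync` models the time a device shows, `t'`, as the reference (UTC) time
`t` plus two error terms:

$$ t'(t) = t + T_{drift}(t) + T_{off}(t) $$

`T_off` is the constant offset a synchronisation event leaves behind (it is
a property of the method and firmware, not of the individual unit);
`T_drift` is the oscillator-rate error integrated over time since the last
clock set, and differs between units and with ambient temperature. A
`sim_clock` carries both terms explicitly, so any simulated state can be
decomposed exactly:

```{r}
clk <- sim_clock("tag001", spec = clock_spec(3, c(-40, 85)), ppm = 3,
                 t_off_s = 0.002)
decompose_error(clk, c(0, 43200, 86400))
```

Drift rates are specified in parts per million (1 ppm is 86.4 ms per day)
and modelled as piecewise-constant in time, the natural shape when the rate
is driven by a piecewise-constant temperature profile
(`ppm_from_temperature()`). Integration over such profiles is exact, which
is what makes the "noise off implies exact arithmetic" tests possible.
Rated clock specifications give only a worst-case |ppm| over a temperature
range, never a curve, so by default each simulated device draws one
constant rate uniformly from the rated interval; a user can supply any
piecewise profile instead. `drift_budget(ppm, duration)` gives the
worst-case accumulated drift, a hard bound that no admissible trajectory
can exceed.

Two conventions in the budget tables deserve a note, both forced by
back-solving the printed values the package reproduces: a month is 31 days
(2,678,400 s), and cells round half away from zero at the printed precision
of each cell. One printed week cell (the 20,000 ppm row) disagrees with its
own arithmetic by 27 s; `clock_drift_examples()` flags it and the package
reproduces the arithmetic, not the misprint.

## Storing time: the RTC and the 5-byte timestamp

The reference hardware stores time on a temperature-compensated RTC with
10 ms read resolution; every stored timestamp passes through that
quantisation (`rtc_read()`, `rtc_quantize()`). Sensor records are annotated
with a 5-byte compressed timestamp: 4 bytes of UNIX seconds plus 1 byte of
centi-milliseconds (`floor(ms/10)`, 0–99). Two choices are not determined
by the format description and are therefore package decisions, stated here
once: byte order is big-endian, so byte-lexicographic order equals
chronological order; and sub-resolution milliseconds are floored, matching
the semantics of a counter that has simply not ticked yet (rounding to
nearest would claim time that has not elapsed). Round-trip error is
strictly below 10 ms and zero on the grid.

Setting the RTC happens on a full second: the device waits on a high
accuracy timer until the next full UTC second of the delivered time and
then issues the set command, which zeroes the milliseconds field. The only
residual errors are the command transfer time — 9 bytes at 400 kbit/s,
i.e. 0.18 ms (`set_latency()`) — plus whatever error the delivered time
itself carried. `set_clock()` implements exactly this, and also restarts
drift accumulation at the set instant.

## The three synchronisation methods

**GPS.** GPS delivers UTC with ns-scale potential, but the time reaches the
microcontroller late: serial transfer plus module-internal processing that
varies with the number of visible satellites. `gps_compensated_time()` adds
a linear delay model `c0 + c1 * n_sats` back onto the reported time. The
coefficients are module-specific calibration values and default to zero; a
fix is a precondition (no fix, no time).

**WiFi/NTP.** `ntp_offset()` implements the four-timestamp offset estimate
`((t2-t1)+(t3-t4))/2` with round-trip delay `(t4-t1)-(t3-t2)`. Under
symmetric path delays the estimate is exact; otherwise its error is half
the delay asymmetry — both facts are closed-form and tested as such. Only
one exchange is used, because each request costs energy.

**Proximity messages.** Tags wake at shared full-UTC-second schedule
points and exchange messages inside an 800 ms window, one every 100 ms.
Each message carries a relative millisecond stamp within the window, the
sender's UTC at second resolution, and the UTC of the sender's last
synchronisation. A receiver compares the airtime-corrected received stamp
with its own relative timestamp; whole-second disagreements ride on the
UTC-seconds field. If any deviation exceeds 50 ms (strictly), the group
collectively adopts the clock with the most recent synchronisation stamp,
and adopters also take over that stamp — this is what propagates a trusted
time through a contact network whose members never all meet at once. The
gossip-convergence property (everyone in a connected component ends at the
component's most recent stamp) is tested against a brute-force propagation
oracle on random graphs.

Three protocol details were genuinely open and are resolved as follows.
First, the timing convention: the sender's stamp refers to a point one
airtime *later* than the receiver's latch point, which is the only reading
under which subtracting the estimated airtime (5.2 ms) from the received
stamp makes two perfect clocks measure zero deviation; the simulator keeps
the true airtime and the protocol's estimate as separate parameters so the
mis-estimation error can be studied. Second, in-window transmissions are
driven by a fixed-rate timer while stamps are read from the drifting
clock, so a +100 ppm clock stamps `100k (1 + 1e-4)` ms. Third, a receiver
aggregates the up-to-8 per-message deviations per sender by their median,
robust to one corrupted message; ties in the last-sync stamp break to the
lowest device id, which is deterministic and order-independent.

Synchronisation accuracy is injected through `offset_noise_model()`s.
Accuracy measurements of this kind are reported as a median and a raw
(unscaled) median absolute deviation, which pins down location and spread
but not a family; the package uses a Laplace distribution scaled so that
MAD = scale · ln 2, a conservative, heavy-tailed choice for timing
residuals. The defaults are the stationary-test figures of the reference
system: GPS 2.72 ms (MAD 12.47), WiFi/NTP 0.43 ms (MAD 1.51), proximity
residual 5 ms (MAD 2), plus a 2 ms per-message measurement MAD.

## The fleet simulator

`run_scenario()` advances a fleet through its wake schedule. Per window it:
steps each device's inside/outside state (a two-state Markov chain whose
dwell parameters are placeholders — real movement statistics are
study-specific and not encoded here), computes each clock's error and true
wake instant, exchanges messages among devices whose windows overlap (two
clocks that disagree by more than the window length cannot hear each
other), lets continuously-listening gateways sniff every awake tag onto
their own ±10 ppm relative clocks, applies the collective resync rule, and
finally lets tags that heard no gateway attempt GPS (`gps_gate()`) with a
location-dependent fix probability (defaults 0.9 outside, 0 inside — fix
failures are real but were only reported qualitatively, so Bernoulli per
attempt is the simplest faithful model). Every wakeup records an exact
error decomposition snapshot.

Determinism: a run is a pure function of `(config, seed)`. Per-device
constant drift rates are drawn under sub-seeds hashed from the device id,
so a device keeps its rate when the fleet grows; all event-time draws come
from the master stream in fixed event order. Relative stamps are kept at
full precision by default (`quantize_ms = FALSE`) so that a noise-free run
reduces to exact drift arithmetic; millisecond flooring can be switched on
to emulate the hardware counters.

The default study conditions are those of the system the package models:
`bat_scenario()` is 99 tags, 4 in-roost gateways, 10 days, wakeups every
full five UTC minutes (288 per day); `two_tag_config()` is the 16-day
stationary pair with hourly exchanges and the 50 ms rule, with a ±1.5 ppm
rate split giving the worst-case 3 ppm relative drift admitted by the RTC
spec. For routine testing and the bundled acceptance script the same
generators are run at reduced size — 20 tags over 2 days for the fleet
replicate, and 5–8 tags over hours inside the test suite — purely to keep
the suite quick; nothing about the mechanics changes with size.

What the generator does *not* emulate: radio propagation and
signal-strength-versus-distance (contact is a boolean audibility), real
bat movement statistics, GPS ephemeris/hot-start behaviour, oscillator
aging and voltage dependence, and network traffic for NTP. Passing tests
therefore validate the protocol logic and error accounting, not
radio-layer or ecological realism.

## The gateway-based evaluation chain

Gateways cannot serve as UTC ground truth (their clocks drift too), so
relative accuracy between tags is estimated entirely in each gateway's
frame: per sniffed message, `arrival - rel_ms` estimates the sender's
window start time; per tag and event the median over its messages is
taken; `pairwise_relative_errors()` then differences all tag pairs within
an event. Radio airtime cancels exactly in the pairwise difference, and
gateway drift cancels to first order across one 800 ms event (of order
ppm × 0.8 ms ≈ 1e-5 ms at 10 ppm) — both properties are asserted
numerically rather than assumed. Summaries use `median_mad()`, the raw-MAD
reporting convention. `fit_ppm()` recovers drift rates from error traces
by least squares; drift is only locally linear, so fits should be windowed
— a rate-reversal example in the tests shows a whole-window fit collapsing
to zero.

`error_budget_table()` produces guaranteed worst-case UTC error budgets:
an offset-distribution quantile plus the rated drift over a
resynchronisation interval. The offset sample underlying the published
base quantiles is not available, so the bases are configuration inputs;
the natural reconstruction backs them out of the shortest-interval
(10-minute) row of each temperature range. Under the additive model those
bases reproduce the wide-range 60-minute row and the narrow-range 24-hour
row exactly; the remaining cells disagree with any single base triple by
±1 ms, so the published table is not reproducible in full from one base
set — the package asserts exactly the consistent cells and no more.

## Numerical and degenerate-input choices

Clock inversion (`wake_time()`) solves `local_time(t*) = target` by
fixed-point iteration; at ppm-scale rates each sweep contracts by ~1e-6,
so six sweeps land far below double precision. Budget-table rounding is
half-away-from-zero with a 1e-9 guard against binary ties. Empty inputs
fail loudly (`median_mad()`, `start_times()`, `resync_decide()` on an
empty participant set); events with a single tag produce no pairs;
malformed NTP exchanges (negative computed delay) and out-of-range codec
inputs are errors, not silent clamps. Messages whose relative stamp falls
outside the window are dropped with a warning.

## Limitations

The 10 ms storage resolution bounds achievable annotation accuracy
regardless of synchronisation quality. Noise families are an assumption
(Laplace via median/MAD), so tail-sensitive conclusions should be checked
against other families. The movement model is a placeholder; anyone using
the fleet simulator to plan a deployment should substitute dwell
statistics for their system. Energy accounting covers timekeeping only
(RTC keep-alive at 720 nW, 6.5 uWh per RTC set, 412.5 uWh per WiFi
synchronisation), not sensing or data transfer.
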