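Package: tagsync
Title: Clock Drift Modelling and Wireless Time Synchronisation for Bio-Loggers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for timekeeping on animal-borne sensor tags.
    Models each device clock as reference time plus oscillator drift (in parts
    per million) plus a synchronisation offset, implements three onboard
    resynchronisation protocols (GPS with delay compensation, NTP over WiFi
    with symmetric-delay correction, and gossip-style relative synchronisation
    via proximity messages), a compact 5-byte UTC timestamp codec with 10 ms
    resolution, a discrete-event simulator for fleets of tags and sniffing
    gateways, and the gateway-based relative time-error evaluation chain with
    median/MAD summaries, drift-rate fitting, and analytic drift and
    guaranteed-error budget tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
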