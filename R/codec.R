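#' Encode a UTC timestamp into the compact 5-byte record
#'
#' Sensor data are annotated with a 5-byte compressed timestamp: bytes 0-3
#' are the UNIX seconds (since 1970-01-01T00:00:00Z) as an unsigned 32-bit
#' big-endian integer, byte 4 is the milliseconds at 10 ms resolution
#' (`floor(ms / 10)`, 0-99). Milliseconds below the 10 ms grid are truncated
#' (floored), matching the counting semantics of an RTC with 10 ms
#' resolution. Big-endian byte order makes byte-lexicographic order equal
#' chronological order.
#'
#' @param utc_seconds integer vector, `0 <= utc_seconds < 2^32`.
#' @param ms integer vector (recycled), `0 <= ms <= 999`.
#' @return a raw vector of `5 * length(utc_seconds)` bytes (records
#'   concatenated in input order).
#' @export
#' @examples
#' ts_encode(1672531200, 570)  # 63 b0 cd 00 39
ts_encode <- function(utc_seconds, ms = 0) {
  if (!is.numeric(utc_seconds) || any(utc_seconds < 0) ||
      any(utc_seconds >= 2^32) || any(utc_seconds %% 1 != 0)) {
    abort("`utc_seconds` must be integers in [0, 2^32).")
  }
  if (!is.numeric(ms) || any(ms < 0) || any(ms > 999)) {
    abort("`ms` must be in [0, 999].")
  }
  n <- length(utc_seconds)
  ms <- rep_len(ms, n)
  s <- as.numeric(utc_seconds)
  bytes <- rbind(
    s %/% 16777216 %% 256,
    s %/% 65536 %% 256,
    s %/% 256 %% 256,
    s %% 256,
    floor(ms / 10)
  )
  as.raw(as.vector(bytes))
}

#' Decode 5-byte compressed timestamps
#'
#' Inverse of [ts_encode()]. Milliseconds are recovered on the 10 ms grid,
#' so `decode(encode(s, ms))` returns `(s, 10 * floor(ms / 10))` and the
#' round-trip error is strictly below 10 ms.
#'
#' @param blob a raw vector whose length is a multiple of 5.
#' @return a tibble with columns `utc_seconds` and `ms` (one row per
#'   record).
#' @export
#' @examples
#' ts_decode(ts_encode(1672531200, 570))
ts_decode <- function(blob) {
  if (!is.raw(blob) || length(blob) == 0 || length(blob) %% 5 != 0) {
    abort("`blob` must be a non-empty raw vector with length a multiple of 5.")
  }
  m <- matrix(as.integer(blob), nrow = 5)
  if (any(m[5, ] > 99)) abort("Invalid record: milliseconds byte exceeds 99.")
  tibble(
    utc_seconds = m[1, ] * 16777216 + m[2, ] * 65536 + m[3, ] * 256 + m[4, ],
    ms = m[5, ] * 10L
  )
}

#' Quantise milliseconds to the RTC's 10 ms grid
#'
#' `10 * floor(ms / 10)`: the value an RTC with 10 ms resolution reports
#' for a true sub-second reading of `ms` milliseconds.
#'
#' @param ms integer vector, `0 <= ms <= 999`.
#' @return quantised milliseconds (multiples of 10, 0-990).
#' @export
#' @examples
#' rtc_quantize(c(0, 57, 994))
rtc_quantize <- function(ms) {
  if (!is.numeric(ms) || any(ms < 0) || any(ms > 999)) {
    abort("`ms` must be in [0, 999].")
  }
  10 * floor(ms / 10)
}

#' Write / read a blob file of concatenated 5-byte timestamp records
#'
#' @param timestamps a data frame with columns `utc_seconds` and `ms`.
#' @param path file path.
#' @return `write_timestamp_blob()` returns `path` invisibly;
#'   `read_timestamp_blob()` returns the decoded tibble.
#' @export
write_timestamp_blob <- function(timestamps, path) {
  timestamps <- as_tibble(timestamps)
  writeBin(ts_encode(timestamps$utc_seconds, timestamps$ms), path)
  invisible(path)
}

#' @rdname write_timestamp_blob
#' @export
read_timestamp_blob <- function(path) {
  ts_decode(readBin(path, "raw", n = file.size(path)))
}
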