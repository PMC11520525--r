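#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so `round_half_away(0.265, 2)` is 0.27 and `round_half_away(-0.265, 2)`
#' is -0.27), the convention used by the printed drift and error-budget
#' tables. Base R's `round()` rounds half to even and cannot reproduce them.
#'
#' @param x numeric vector.
#' @param digits integer scalar or vector (recycled), decimal places.
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_away(0.2592, 2)
#' round_half_away(12.096, 1)
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits))
  p <- 10^digits
  # small eps guards against binary representation of exact .5 ties
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit sub-seed from a master seed and a device label.
# Stable against fleet-size changes: each device's stream depends only on
# its own id and the master seed.
device_subseed <- function(master_seed, device_id) {
  h <- sum(utf8ToInt(as.character(device_id)) * seq_along(utf8ToInt(as.character(device_id))))
  as.integer((as.numeric(master_seed) * 48271 + h * 69621) %% 2147483647)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
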