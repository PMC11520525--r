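# Independent oracles used across the suite. Each is deliberately naive
# and shares no code with the implementation it checks.

# Riemann-sum quadrature of a piecewise-constant ppm profile at fixed steps,
# sampling the rate at sub-interval midpoints.
oracle_riemann_drift <- function(segments, t0, t1, step = 1) {
  if (t1 <= t0) return(0)
  grid <- seq(t0, t1, by = step)
  if (grid[length(grid)] < t1) grid <- c(grid, t1)
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  widths <- diff(grid)
  rate <- vapply(mids, function(tm) {
    hit <- segments$start_s <= tm & tm < segments$end_s
    if (!any(hit)) 0 else segments$ppm[which(hit)[1]]
  }, numeric(1))
  sum(rate * 1e-6 * widths)
}

# Sort-based median and raw MAD.
oracle_median_mad <- function(x) {
  srt <- sort(x)
  n <- length(srt)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  dev <- sort(abs(x - med))
  mad <- if (n %% 2 == 1) dev[(n + 1) / 2] else (dev[n / 2] + dev[n / 2 + 1]) / 2
  c(median = med, mad = mad)
}

# Brute-force propagation of the maximum sync stamp over a contact graph:
# within each connected component every node ends up with the component's
# maximum.
oracle_propagated_stamps <- function(edges, stamps) {
  n <- length(stamps)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      i <- edges$from[k]; j <- edges$to[k]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  vapply(seq_len(n), function(i) max(stamps[comp == comp[i]]), numeric(1))
}

# A random connected graph: spanning tree plus extra random edges.
random_connected_graph <- function(n, extra = 2) {
  from <- integer(0); to <- integer(0)
  for (i in 2:n) {
    from <- c(from, sample.int(i - 1, 1)); to <- c(to, i)
  }
  for (k in seq_len(extra)) {
    p <- sample.int(n, 2)
    from <- c(from, p[1]); to <- c(to, p[2])
  }
  data.frame(from = from, to = to)
}
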