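# Shared fixtures and independent brute-force oracles.

# Brute-force segment enumeration, independent of the run-based detector:
# tests every interval for a negative velocity product with explicit loops,
# grows maximal runs, then walks samples cutting wherever sign(d) changes
# (zero-disparity samples are boundaries), and applies the dwell rule.
# Returns a data.frame of (start_index, end_index) sample pairs.
oracle_segments <- function(rec, min_samples = 3L) {
  t <- rec$t; xl <- rec$xl; xr <- rec$xr
  n <- length(t)
  neg <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    vl <- (xl[i + 1] - xl[i]) / (t[i + 1] - t[i])
    vr <- (xr[i + 1] - xr[i]) / (t[i + 1] - t[i])
    neg[i] <- (vl * vr) < 0
  }
  d <- xl - xr
  out <- list()
  i <- 1L
  while (i <= n - 1) {
    if (!neg[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= n - 1 && neg[j + 1L]) j <- j + 1L
    # samples i .. j+1; cut at disparity sign changes
    a <- i
    for (s in i:(j + 1L)) {
      cut_here <- s == j + 1L || sign(d[s + 1L]) != sign(d[s])
      if (cut_here) {
        # trim zero-sign samples off both ends, then emit each nonzero block
        blk <- a:s
        blk <- blk[sign(d[blk]) != 0]
        if (length(blk))
          out[[length(out) + 1L]] <- c(blk[1], blk[length(blk)])
        a <- s + 1L
      }
    }
    i <- j + 1L
  }
  if (!length(out))
    return(data.frame(start_index = integer(), end_index = integer()))
  m <- do.call(rbind, out)
  df <- data.frame(start_index = m[, 1], end_index = m[, 2])
  df[df$end_index - df$start_index + 1L >= min_samples, , drop = FALSE]
}

# Random binocular walk with discrete steps (including exact zeros and
# frequent disparity sign changes) to exercise the zero/boundary rules.
random_walk_rec <- function(seed, n = 50, rate = 200) {
  set.seed(seed)
  t <- (0:(n - 1)) / rate
  xl <- cumsum(sample(c(-2, -1, 0, 1, 2), n, replace = TRUE)) * 0.01
  xr <- cumsum(sample(c(-2, -1, 0, 1, 2), n, replace = TRUE)) * 0.01
  binocular_recording(t, xl, xr, rate = rate)
}

# Continuous (tie-free) binocular random walk for symmetry/invariance tests.
smooth_walk_rec <- function(seed, n = 150, rate = 200) {
  set.seed(seed)
  t <- (0:(n - 1)) / rate
  xl <- cumsum(rnorm(n, 0, 0.01))
  xr <- cumsum(rnorm(n, 0, 0.01))
  binocular_recording(t, xl, xr, rate = rate)
}

# Flat conjugate trace with constant disparity d0 (no motion at all).
flat_rec <- function(n = 600, rate = 200, d0 = 0.2) {
  t <- (0:(n - 1)) / rate
  binocular_recording(t, rep(d0 / 2, n), rep(-d0 / 2, n), rate = rate)
}

# Build a recording whose velocity-product sequence has prescribed signs:
# the left eye always moves at +1 deg/s, the right eye at dv_sign deg/s,
# with unit timestamps, so dv has exactly the requested signs.
rec_from_dv_signs <- function(dv_signs, d_offset = 10) {
  n <- length(dv_signs) + 1L
  xl <- cumsum(c(0, rep(1, n - 1L)))
  xr <- cumsum(c(0, dv_signs))
  binocular_recording(0:(n - 1L), xl + d_offset, xr)
}

# Minimum-jerk conjugate saccade of amplitude `amp` (deg) lasting `dur` (s),
# embedded in `pad` s of fixation either side. Peak velocity 1.875*amp/dur.
minjerk_rec <- function(amp = 10, dur = 0.05, pad = 1, rate = 200,
                        start = 0) {
  dt <- 1 / rate
  t <- seq(0, 2 * pad + dur, by = dt)
  pos <- numeric(length(t))
  tau <- pmin(pmax((t - pad) / dur, 0), 1)
  pos <- start + amp * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  binocular_recording(t, pos, pos, rate = rate)
}

# Saccade-event data.frame with the full descriptor columns, n empty rows.
empty_events_df <- function(n = 2) {
  cols <- c("onset_s", "offset_s", "onset_index", "offset_index",
            "amplitude", "signed_amplitude", "duration", "peak_velocity",
            "average_velocity", "drift1", "drift2", "total_amplitude",
            "fixation_duration")
  df <- as.data.frame(matrix(NA_real_, nrow = n, ncol = length(cols)))
  names(df) <- cols
  df
}

# One packaged seed-42 cohort with its DGI feature table, computed once and
# reused across test files.
packaged_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(sim_config(seed = 42))
      co$dgi <- dgi_features(co$recordings)
      cache <<- co
    }
    cache
  }
})
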