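# Disconjugacy Global Index: detection of binocular opposite-direction
# micro-segments from the sign of the per-interval velocity product.

#' Disparity and velocity-product series
#'
#' Computes the two derived signals the segment detector works on:
#' the disparity `d = xl - xr` (one value per sample, degrees) and the
#' velocity product `dv` (one value per inter-sample interval, (deg/s)^2),
#' where each eye's velocity on interval i is its raw first difference
#' divided by the actual timestamp difference. No smoothing is applied:
#' the detector is meant to see every raw opposite-direction interval.
#'
#' An interval with `dv < 0` is one where the eyes moved in opposite
#' directions; e.g. left at +10 deg/s and right at -10 deg/s gives
#' dv = -100 (deg/s)^2, while +10 and +20 deg/s give +200 (deg/s)^2.
#'
#' @param rec a [binocular_recording()] with no gap samples (split first with
#'   [split_on_gaps()] if needed).
#' @return An object of class `disconjugacy_series`: list with `t`, `d`
#'   (length n), `dv` (length n-1).
#' @export
compute_series <- function(rec) {
  stopifnot(inherits(rec, "binocular_recording"))
  if (length(rec$t) < 2)
    stop("empty recording: need at least 2 samples", call. = FALSE)
  if (any(rec$gap))
    stop("series requires a gap-free recording; use split_on_gaps()",
         call. = FALSE)
  dt <- diff(rec$t)
  structure(list(t = rec$t,
                 d = rec$xl - rec$xr,
                 dv = (diff(rec$xl) / dt) * (diff(rec$xr) / dt)),
            class = "disconjugacy_series")
}

#' Maximal runs of negative velocity product
#'
#' A candidate disconjugacy segment is any maximal run of consecutive
#' intervals with `dv < 0`. Runs touching the recording boundary are kept;
#' intervals with `dv == 0` (one eye momentarily static) are not
#' disconjugate and terminate runs.
#'
#' @param series a [compute_series()] result.
#' @return Integer matrix with columns `start`, `end`: inclusive interval
#'   indices (interval i joins samples i and i+1). Zero rows when no interval
#'   is negative.
#' @export
find_candidate_segments <- function(series) {
  stopifnot(inherits(series, "disconjugacy_series"))
  neg <- series$dv < 0
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Split candidate runs at disparity sign changes
#'
#' Within one negative-velocity-product run the eyes keep moving in opposite
#' directions, but the disparity signal `d` may cross zero; each crossing
#' separates an elementary micro-converging or micro-diverging movement, so
#' the run is partitioned into maximal blocks of constant `sign(d)`. Samples
#' with `d == 0` act as block boundaries and belong to no block. A block with
#' shrinking `|d|` from first to last sample is labelled `converging`,
#' otherwise (growing or tied) `diverging`.
#'
#' @param runs matrix from [find_candidate_segments()].
#' @param series the matching [compute_series()] result.
#' @return data.frame with one row per sub-segment: `start_index`,
#'   `end_index` (sample indices, inclusive), `start_s`, `end_s`,
#'   `duration_ms`, `amplitude_deg` (`|d[end] - d[start]|`), `direction`,
#'   `n_samples`.
#' @export
split_by_direction <- function(runs, series) {
  stopifnot(inherits(series, "disconjugacy_series"))
  d <- series$d; t <- series$t
  aa <- integer(0); bb <- integer(0)
  for (k in seq_len(nrow(runs))) {
    a0 <- runs[k, 1L]          # first sample of run = first interval index
    b0 <- runs[k, 2L] + 1L     # last sample of run
    sg <- sign(d[a0:b0])
    r <- rle(sg)
    ends <- cumsum(r$lengths) + a0 - 1L
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0      # zero-disparity samples are pure boundaries
    aa <- c(aa, starts[keep]); bb <- c(bb, ends[keep])
  }
  if (!length(aa)) return(empty_segments())
  data.frame(
    start_index = aa, end_index = bb,
    start_s = t[aa], end_s = t[bb],
    duration_ms = (t[bb] - t[aa]) * 1000,
    amplitude_deg = abs(d[bb] - d[aa]),
    direction = ifelse(abs(d[bb]) < abs(d[aa]), "converging", "diverging"),
    n_samples = bb - aa + 1L,
    stringsAsFactors = FALSE)
}

empty_segments <- function() {
  data.frame(start_index = integer(), end_index = integer(),
             start_s = numeric(), end_s = numeric(),
             duration_ms = numeric(), amplitude_deg = numeric(),
             direction = character(), n_samples = integer(),
             stringsAsFactors = FALSE)
}

#' Dwell filter on disconjugacy segments
#'
#' Retains segments spanning at least `min_samples` position samples
#' (i.e. at least `min_samples - 1` consecutive negative intervals). The
#' default of 3 discards one-interval flickers that are indistinguishable
#' from tracker noise.
#'
#' @param segments data.frame from [split_by_direction()].
#' @param min_samples minimum spanned samples (>= 1).
#' @return The filtered data.frame, order preserved.
#' @export
filter_segments <- function(segments, min_samples = 3L) {
  stopifnot(min_samples >= 1)
  segments[segments$n_samples >= min_samples, , drop = FALSE]
}

#' Disconjugacy Global Index of a recording
#'
#' Full pipeline: gap splitting, disparity/velocity-product series, maximal
#' negative runs, direction splitting, dwell filter, then
#' `dgi = count / total_duration` with the per-segment mean duration (ms) and
#' mean amplitude (deg). `total_duration` is the summed span of the analysed
#' gap-free stretches, so the index stays a rate (segments per second) in the
#' presence of blinks or dropouts.
#'
#' @param rec a [binocular_recording()].
#' @param min_samples dwell filter, see [filter_segments()].
#' @param max_gap gap-splitting threshold in seconds, see [split_on_gaps()].
#' @return Object of class `dgi_result`: list with `dgi` (segments/s),
#'   `count`, `mean_duration_ms`, `mean_amplitude_deg`, `total_duration_s`,
#'   `segments` (data.frame), and `label` carried from the recording.
#' @examples
#' t <- seq(0, 2, by = 0.005)
#' rec <- binocular_recording(t, sin(t), sin(t))   # perfectly conjugate
#' compute_dgi(rec)$count                          # 0
#' @export
compute_dgi <- function(rec, min_samples = 3L, max_gap = 3 / rec$rate) {
  stopifnot(inherits(rec, "binocular_recording"))
  parts <- split_on_gaps(rec, max_gap)
  total <- sum(vapply(parts, span_seconds, numeric(1)))
  if (!length(parts) || total <= 0)
    stop("degenerate input: no usable duration after gap handling",
         call. = FALSE)
  segs <- lapply(parts, function(p) {
    s <- compute_series(p)
    filter_segments(split_by_direction(find_candidate_segments(s), s),
                    min_samples)
  })
  segs <- do.call(rbind, segs)
  count <- nrow(segs)
  structure(list(
    dgi = count / total,
    count = count,
    mean_duration_ms = if (count) mean(segs$duration_ms) else 0,
    mean_amplitude_deg = if (count) mean(segs$amplitude_deg) else 0,
    total_duration_s = total,
    segments = segs,
    label = rec$meta$label), class = "dgi_result")
}

#' @method print dgi_result
#' @export
print.dgi_result <- function(x, ...) {
  cat(sprintf(
    "<dgi_result> %d segments over %.3f s: DGI = %.3f /s\n  mean duration %.2f ms, mean amplitude %.5f deg\n",
    x$count, x$total_duration_s, x$dgi, x$mean_duration_ms,
    x$mean_amplitude_deg))
  invisible(x)
}

#' Per-group amplitude histogram of disconjugacy segments
#'
#' Pools segment amplitudes from a list of DGI results and bins them into
#' equal-width bins over the pooled range, counting separately per group
#' label. Used to compare the amplitude distribution of the dyslexic and
#' control populations (the bulk of segments sits below 0.005 deg, with
#' separate micro-convergence and micro-divergence modes).
#'
#' @param results list of `dgi_result` objects.
#' @param bins number of equal-width bins (default 100).
#' @return list with `breaks` (length bins+1) and `counts`, a matrix with one
#'   row per group label.
#' @export
amplitude_histogram <- function(results, bins = 100L) {
  stopifnot(length(results) >= 1)
  amp <- unlist(lapply(results, function(r) r$segments$amplitude_deg))
  grp <- unlist(lapply(results, function(r)
    rep(r$label, nrow(r$segments))))
  if (!length(amp))
    stop("no segments at all: empty histogram", call. = FALSE)
  rng <- range(amp)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * 1e-9
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  groups <- sort(unique(grp))
  counts <- t(vapply(groups, function(g) {
    idx <- findInterval(amp[grp == g], breaks,
                        rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = bins)
  }, integer(bins)))
  rownames(counts) <- groups
  list(breaks = breaks, counts = counts)
}
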