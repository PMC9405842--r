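# Velocity-threshold saccade detection on the conjugate signal and the
# eight per-saccade oculomotor descriptors with mean/SD/CV/N aggregation.

DESCRIPTORS <- c("amplitude", "duration", "peak_velocity", "average_velocity",
                 "drift1", "drift2", "total_amplitude", "fixation_duration")

#' Conjugate gaze signal and smoothed velocity
#'
#' The conjugate signal is the per-sample average of the two eyes,
#' `(xl + xr)/2`, representing the shared gaze direction. Velocity is
#' estimated by a central difference followed by a 5-sample moving average
#' (25 ms at 200 Hz) so that tracker noise does not fragment threshold
#' crossings; the endpoints use one-sided differences. This smoothed
#' estimator is used for event detection only — the disconjugacy detector in
#' [compute_series()] deliberately works on raw differences.
#'
#' @param rec a gap-free [binocular_recording()] with at least 3 samples.
#' @return Object of class `conjugate_series`: list with `t`, `pos` (deg),
#'   `vel` (deg/s), and the source recording.
#' @export
conjugate <- function(rec) {
  stopifnot(inherits(rec, "binocular_recording"))
  n <- length(rec$t)
  if (n < 3) stop("too short: need at least 3 samples", call. = FALSE)
  if (any(rec$gap))
    stop("conjugate series requires a gap-free recording", call. = FALSE)
  pos <- (rec$xl + rec$xr) / 2
  t <- rec$t
  v <- numeric(n)
  v[2:(n - 1)] <- (pos[3:n] - pos[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v[1] <- (pos[2] - pos[1]) / (t[2] - t[1])
  v[n] <- (pos[n] - pos[n - 1]) / (t[n] - t[n - 1])
  if (n >= 5) {
    sm <- stats::filter(v, rep(1 / 5, 5), sides = 2)
    v[3:(n - 2)] <- sm[3:(n - 2)]
  }
  structure(list(t = t, pos = pos, vel = v, rec = rec),
            class = "conjugate_series")
}

#' Detect saccades by velocity threshold
#'
#' Candidate saccades are contiguous stretches where the absolute conjugate
#' velocity reaches `peak_floor` (40 deg/s by default). For each candidate
#' peak, onset is the last sample before the peak where `|v|` is below 10%
#' of the peak velocity and offset the first such sample after it, so each
#' event is trimmed to its own velocity profile. Events whose extended
#' windows overlap are merged (the larger peak wins).
#'
#' @param series a [conjugate()] result.
#' @param peak_floor minimum absolute peak velocity in deg/s.
#' @return data.frame of event kinematics: `onset_s`, `offset_s`,
#'   `onset_index`, `offset_index`, `amplitude` (deg, absolute),
#'   `signed_amplitude`, `duration` (ms), `peak_velocity` (deg/s),
#'   `average_velocity` (deg/s). Zero rows when nothing crosses the floor.
#' @export
detect_saccades <- function(series, peak_floor = 40) {
  stopifnot(inherits(series, "conjugate_series"))
  av <- abs(series$vel)
  n <- length(av)
  # peak velocity is read from the raw per-interval difference: the smoothed
  # series only gates detection, and smoothing flattens short saccade peaks
  pos <- series$pos; t <- series$t
  vint <- abs(diff(pos) / diff(t))
  r <- rle(av >= peak_floor)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (!nrow(runs)) return(empty_events())
  ev <- lapply(seq_len(nrow(runs)), function(k) {
    seg <- runs[k, 1L]:runs[k, 2L]
    p <- seg[which.max(av[seg])]
    ints <- max(1L, seg[1L] - 1L):min(n - 1L, seg[length(seg)])
    pv_raw <- max(vint[ints])
    thr <- 0.1 * pv_raw
    below_l <- which(av[1:p] < thr)
    onset <- if (length(below_l)) max(below_l) else 1L
    below_r <- which(av[p:n] < thr)
    offset <- if (length(below_r)) p + min(below_r) - 1L else n
    c(onset = onset, offset = offset, peak = p, pv = pv_raw)
  })
  ev <- do.call(rbind, ev)
  # merge overlapping extended windows, keeping the larger peak
  ord <- order(ev[, "pv"], decreasing = TRUE)
  keep <- logical(nrow(ev))
  claimed <- logical(n)
  for (i in ord) {
    win <- ev[i, "onset"]:ev[i, "offset"]
    if (!any(claimed[win])) {
      keep[i] <- TRUE
      claimed[win] <- TRUE
    }
  }
  ev <- ev[keep, , drop = FALSE]
  ev <- ev[order(ev[, "onset"]), , drop = FALSE]
  on <- as.integer(ev[, "onset"]); off <- as.integer(ev[, "offset"])
  samp <- series$pos[off] - series$pos[on]
  dur_ms <- (series$t[off] - series$t[on]) * 1000
  data.frame(onset_s = series$t[on], offset_s = series$t[off],
             onset_index = on, offset_index = off,
             amplitude = abs(samp), signed_amplitude = samp,
             duration = dur_ms, peak_velocity = ev[, "pv"],
             average_velocity = abs(samp) / (dur_ms / 1000),
             row.names = NULL)
}

empty_events <- function() {
  data.frame(onset_s = numeric(), offset_s = numeric(),
             onset_index = integer(), offset_index = integer(),
             amplitude = numeric(), signed_amplitude = numeric(),
             duration = numeric(), peak_velocity = numeric(),
             average_velocity = numeric())
}

#' Complete saccade events with drift and fixation descriptors
#'
#' Adds the disconjugate post-saccadic drift over the 80 ms (`drift1`) and
#' 160 ms (`drift2`) windows starting at each offset — the left eye's
#' displacement minus the right eye's over the window, in degrees — plus
#' `total_amplitude` (saccade amplitude + |drift2|) and `fixation_duration`
#' (ms from this offset to the next onset). Windows running past the end of
#' the recording and the last event's fixation duration are aberrant:
#' recorded as `NA` here and zeroed at aggregation, since such values carry
#' information (blinks, artifacts) and must not be imputed from the
#' population.
#'
#' An event is kinematically aberrant when `|amplitude| > 40` deg, peak
#' velocity exceeds 1000 deg/s, or duration lies outside [10, 400] ms; the
#' affected descriptors (and those derived from them) are also set `NA`.
#'
#' @param events kinematics from [detect_saccades()].
#' @param rec the source [binocular_recording()].
#' @return The events data.frame with `drift1`, `drift2`, `total_amplitude`,
#'   `fixation_duration` columns appended (NA = aberrant).
#' @export
event_features <- function(events, rec) {
  stopifnot(inherits(rec, "binocular_recording"))
  m <- nrow(events)
  if (!m) {
    events$drift1 <- events$drift2 <- events$total_amplitude <-
      events$fixation_duration <- numeric(0)
    return(events)
  }
  t <- rec$t; tn <- t[length(t)]
  d1 <- d2 <- tot <- fx <- rep(NA_real_, m)
  for (k in seq_len(m)) {
    i0 <- events$offset_index[k]
    if (events$offset_s[k] + 0.16 <= tn) {
      j1 <- max(which(t <= t[i0] + 0.08))
      j2 <- max(which(t <= t[i0] + 0.16))
      d1[k] <- (rec$xl[j1] - rec$xl[i0]) - (rec$xr[j1] - rec$xr[i0])
      d2[k] <- (rec$xl[j2] - rec$xl[i0]) - (rec$xr[j2] - rec$xr[i0])
      tot[k] <- events$amplitude[k] + abs(d2[k])
    }
    if (k < m) fx[k] <- (events$onset_s[k + 1] - events$offset_s[k]) * 1000
  }
  events$drift1 <- d1; events$drift2 <- d2
  events$total_amplitude <- tot; events$fixation_duration <- fx
  bad <- events$amplitude > 40 | events$peak_velocity > 1000 |
    events$duration > 400 | events$duration < 10
  events$amplitude[bad] <- NA_real_
  events$duration[bad] <- NA_real_
  events$peak_velocity[events$peak_velocity > 1000] <- NA_real_
  events$average_velocity[bad] <- NA_real_
  events$total_amplitude[bad] <- NA_real_
  events
}

#' Aggregate saccade descriptors over a recording
#'
#' For each of the eight descriptors, computes the mean, the population
#' standard deviation, the coefficient of variation (SD/mean x 100, 0 when
#' the mean is 0) and the number of events. Aberrant (`NA`) values are set
#' to 0 before aggregation rather than imputed — aberrances are treated as
#' informative — and the event count is unchanged by them.
#'
#' @param events completed events from [event_features()].
#' @return Named numeric vector of length 32 (`<descriptor>_<stat>` with
#'   stats `mean`, `sd`, `cv`, `n`), class `recording_feature_summary`.
#' @export
summarize_events <- function(events) {
  out <- numeric(0)
  for (d in DESCRIPTORS) {
    x <- if (nrow(events)) events[[d]] else numeric(0)
    x[is.na(x)] <- 0
    n <- length(x)
    m <- if (n) mean(x) else 0
    s <- if (n) sqrt(mean((x - m)^2)) else 0
    cv <- if (m != 0) s / m * 100 else 0
    v <- c(m, s, cv, n)
    names(v) <- paste(d, c("mean", "sd", "cv", "n"), sep = "_")
    out <- c(out, v)
  }
  structure(out, class = "recording_feature_summary")
}

#' @method print recording_feature_summary
#' @export
print.recording_feature_summary <- function(x, ...) {
  cat("<recording_feature_summary>", unname(x["amplitude_n"]), "events\n")
  print(unclass(round(x, 4)))
  invisible(x)
}

#' Extract the full oculomotor feature summary of a recording
#'
#' Pipeline: [conjugate()] -> [detect_saccades()] -> [event_features()] ->
#' [summarize_events()]. Deterministic: the same recording always yields the
#' same summary.
#'
#' @param rec a [binocular_recording()].
#' @param peak_floor velocity floor in deg/s, see [detect_saccades()].
#' @return A `recording_feature_summary` (32 named statistics).
#' @export
extract_features <- function(rec, peak_floor = 40) {
  parts <- split_on_gaps(rec)
  parts <- parts[vapply(parts, n_samples, integer(1)) >= 3]
  if (!length(parts)) return(summarize_events(empty_full_events()))
  evs <- lapply(parts, function(p)
    event_features(detect_saccades(conjugate(p), peak_floor), p))
  summarize_events(do.call(rbind, evs))
}

empty_full_events <- function() {
  ev <- empty_events()
  ev$drift1 <- ev$drift2 <- ev$total_amplitude <-
    ev$fixation_duration <- numeric(0)
  ev
}
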