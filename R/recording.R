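# Data model and CSV I/O for binocular horizontal gaze recordings.

#' Construct a binocular gaze recording
#'
#' A `binocular_recording` holds time-stamped horizontal positions of the left
#' and right eye in degrees. Positive x is rightward gaze. Samples with a
#' non-finite position in either eye are flagged as gaps and excluded from
#' analysis by [split_on_gaps()]; they are kept in place so sample indices and
#' timestamps are preserved.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param xl,xr numeric vectors of left/right eye horizontal position (deg).
#' @param rate nominal sampling rate in Hz; inferred as `1/median(diff(t))`
#'   when `NULL`.
#' @param subject subject identifier.
#' @param label group label: `"dyslexic"`, `"control"` or `"unknown"`.
#' @param painting stimulus (painting) identifier, 1-7 in the free-viewing
#'   protocol, or `NA`.
#' @return An object of class `binocular_recording`: a list with elements
#'   `t`, `xl`, `xr`, `gap` (logical), `rate` and `meta`.
#' @examples
#' rec <- binocular_recording(seq(0, 1, by = 0.005), rnorm(201, 0, 0.01),
#'                            rnorm(201, 0, 0.01))
#' rec
#' @export
binocular_recording <- function(t, xl, xr, rate = NULL,
                                subject = NA_character_,
                                label = "unknown", painting = NA_integer_) {
  t <- as.numeric(t); xl <- as.numeric(xl); xr <- as.numeric(xr)
  n <- length(t)
  if (length(xl) != n || length(xr) != n)
    stop("timestamps and position vectors must have equal length", call. = FALSE)
  if (n < 2)
    stop("empty recording: fewer than 2 samples", call. = FALSE)
  if (anyNA(t) || any(!is.finite(t)))
    stop("timestamps must be finite", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  label <- match.arg(label, c("unknown", "control", "dyslexic"))
  gap <- !is.finite(xl) | !is.finite(xr)
  if (is.null(rate)) rate <- 1 / stats::median(diff(t))
  structure(list(t = t, xl = xl, xr = xr, gap = gap, rate = rate,
                 meta = list(subject = subject, label = label,
                             painting = painting)),
            class = "binocular_recording")
}

#' @method print binocular_recording
#' @export
print.binocular_recording <- function(x, ...) {
  cat(sprintf(
    "<binocular_recording> %d samples, %.3f s span, %.1f Hz nominal, %d gap(s)\n",
    length(x$t), diff(range(x$t)), x$rate, sum(x$gap)))
  if (!is.na(x$meta$subject) || x$meta$label != "unknown")
    cat(sprintf("  subject=%s label=%s painting=%s\n", x$meta$subject,
                x$meta$label, x$meta$painting))
  invisible(x)
}

n_samples <- function(rec) length(rec$t)

span_seconds <- function(rec) rec$t[length(rec$t)] - rec$t[1]

#' Read a binocular recording from CSV
#'
#' Expects a header with columns `timestamp_s`, `left_x_deg`, `right_x_deg`;
#' optional `subject`, `label` and `painting` columns carry metadata (the first
#' row's value is used). Vertical channels (`left_y_deg`, `right_y_deg`), if
#' present, are ignored: the analysis is strictly horizontal. Rows with a
#' missing or non-finite position are kept but flagged as gaps.
#'
#' @param path CSV file path.
#' @return A [binocular_recording()].
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_s", "left_x_deg", "right_x_deg")
  if (!all(need %in% names(df)))
    stop("malformed header: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sub <- if ("subject" %in% names(df)) as.character(df$subject[1]) else NA_character_
  lab <- if ("label" %in% names(df)) as.character(df$label[1]) else "unknown"
  pai <- if ("painting" %in% names(df)) as.integer(df$painting[1]) else NA_integer_
  binocular_recording(df$timestamp_s, df$left_x_deg, df$right_x_deg,
                      subject = sub, label = lab, painting = pai)
}

#' Write a binocular recording to CSV
#'
#' Positions and timestamps round-trip through [read_recording()] to better
#' than 1e-9. Metadata is stored in `subject`/`label`/`painting` columns.
#'
#' @param rec a [binocular_recording()].
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "binocular_recording"))
  df <- data.frame(timestamp_s = rec$t, left_x_deg = rec$xl,
                   right_x_deg = rec$xr)
  if (!is.na(rec$meta$subject)) df$subject <- rec$meta$subject
  if (rec$meta$label != "unknown") df$label <- rec$meta$label
  if (!is.na(rec$meta$painting)) df$painting <- rec$meta$painting
  # format() at 17 significant digits keeps doubles exact on re-read
  for (col in c("timestamp_s", "left_x_deg", "right_x_deg"))
    df[[col]] <- format(df[[col]], digits = 17, trim = TRUE, scientific = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Split a recording at gaps
#'
#' Blink dropouts and tracker artifacts enter the data either as non-finite
#' samples (flagged at construction) or as abnormally long inter-sample
#' intervals. Both would create spurious velocity spikes, so the recording is
#' cut there and each contiguous clean stretch is analysed separately. DGI
#' denominators then use the sum of the retained spans.
#'
#' @param rec a [binocular_recording()].
#' @param max_gap maximum tolerated inter-sample interval in seconds; default
#'   three nominal sample periods.
#' @return A list of gap-free `binocular_recording` objects (possibly empty).
#'   No sample is altered or fabricated: every output sample is an input
#'   sample.
#' @export
split_on_gaps <- function(rec, max_gap = 3 / rec$rate) {
  stopifnot(inherits(rec, "binocular_recording"), max_gap > 0)
  keep <- which(!rec$gap)
  if (length(keep) < 2) return(list())
  t <- rec$t[keep]; xl <- rec$xl[keep]; xr <- rec$xr[keep]
  brk <- which(diff(t) > max_gap)           # cut after these positions
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(t))
  out <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]:ends[k]
    if (length(i) < 2) next
    out[[length(out) + 1L]] <- binocular_recording(
      t[i], xl[i], xr[i], rate = rec$rate,
      subject = rec$meta$subject, label = rec$meta$label,
      painting = rec$meta$painting)
  }
  out
}

#' Summarize a recording for quick validation
#'
#' @param rec a [binocular_recording()].
#' @return list with `n`, `span_s`, `n_gaps`, `rate_hz`.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "binocular_recording"))
  list(n = length(rec$t), span_s = span_seconds(rec),
       n_gaps = sum(rec$gap), rate_hz = rec$rate)
}

#' Read a cohort manifest
#'
#' A manifest lists one recording file per (subject, painting) pair with its
#' binary group label (1 = dyslexic, 0 = control).
#'
#' @param path CSV with columns `path`, `subject`, `label`, `painting`.
#' @return data.frame with those columns, validated.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "subject", "label", "painting")
  if (!all(need %in% names(df)))
    stop("malformed manifest header: need ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$label %in% c(0L, 1L)))
    stop("manifest labels must be 0 (control) or 1 (dyslexic)", call. = FALSE)
  if (!all(df$painting %in% 1:7))
    stop("manifest painting ids must be in 1..7", call. = FALSE)
  if (anyDuplicated(df[c("subject", "painting")]))
    stop("manifest must have one row per (subject, painting)", call. = FALSE)
  df[need]
}
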