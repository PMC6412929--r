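#' Centred moving average with reflected edges
#'
#' Uniform (boxcar) moving average of width `width`. The window is centred on
#' each sample; the signal is extended by symmetric reflection at both ends so
#' the output has the same length as the input. A running cumulative sum keeps
#' the cost linear in the signal length.
#'
#' @param signal Numeric vector.
#' @param width Window width in samples (integer, `1 <= width <= length(signal)`).
#' @return Numeric vector, same length as `signal`.
#' @examples
#' moving_average(rep(2, 10), 5)      # constants are preserved
#' moving_average(c(rep(0, 5), 1, rep(0, 5)), 10)  # impulse -> 1/width plateau
#' @export
moving_average <- function(signal, width) {
  signal <- as.numeric(signal)
  n <- length(signal)
  width <- as.integer(width)
  if (is.na(width) || width < 1L) {
    stop("`width` must be a positive integer", call. = FALSE)
  }
  if (width > n) {
    stop("`width` must not exceed the signal length", call. = FALSE)
  }
  if (width == 1L) return(signal)
  pl <- (width - 1L) %/% 2L           # samples added on the left
  pr <- width - 1L - pl               # and on the right
  padded <- c(rev(signal[seq_len(pl)]), signal, rev(signal[n - seq_len(pr) + 1L]))
  cs <- cumsum(c(0, padded))
  (cs[(width + 1L):(n + width)] - cs[seq_len(n)]) / width
}

#' Remove baseline wander from an ECG record
#'
#' Estimates the low-frequency baseline as a wide moving average (default 500
#' samples, i.e. 0.5 s at 1 kHz) and subtracts it from the signal. Respiratory
#' and movement drift (typically below 0.5 Hz) sits well inside the passband
#' of such a wide average, so the subtraction removes it while leaving the
#' QRS complex essentially untouched.
#'
#' @param record An [ecg_record()].
#' @param width Baseline-estimation window in samples (default 500).
#' @return The record with detrended samples.
#' @export
remove_baseline <- function(record, width = 500L) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$samples) <= width) {
    stop("record must be longer than the baseline window", call. = FALSE)
  }
  record$samples <- record$samples - moving_average(record$samples, width)
  record
}

#' Suppress high-frequency noise in an ECG record
#'
#' Smooths the signal with a short moving average (default 10 samples, 10 ms
#' at 1 kHz). At a 1 kHz sampling rate the length-10 boxcar has a null at
#' exactly 100 Hz and strong attenuation at mains frequencies, which is where
#' powerline interference lives.
#'
#' @inheritParams remove_baseline
#' @param width Smoothing window in samples (default 10).
#' @return The record with smoothed samples.
#' @export
smooth_highfreq <- function(record, width = 10L) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$samples) <= width) {
    stop("record must be longer than the smoothing window", call. = FALSE)
  }
  record$samples <- moving_average(record$samples, width)
  record
}

#' Trim filter-distorted edges from a record
#'
#' Drops the first and last `n` samples (default 600), discarding the regions
#' where the moving-average filters were fed reflected rather than measured
#' data.
#'
#' @inheritParams remove_baseline
#' @param n Number of samples to drop at each end (non-negative integer).
#' @return The shortened record.
#' @export
trim_edges <- function(record, n = 600L) {
  stopifnot(inherits(record, "ecg_record"))
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("`n` must be a non-negative integer", call. = FALSE)
  len <- length(record$samples)
  if (len <= 2L * n) {
    stop("record must be longer than twice the trim length", call. = FALSE)
  }
  if (n > 0L) {
    record$samples <- record$samples[(n + 1L):(len - n)]
  }
  record
}

#' Detect R-peaks in a preprocessed ECG record
#'
#' Pan-Tompkins-style detector: differentiation, squaring and a
#' moving-window integration (~120 ms) produce a QRS energy envelope;
#' regions where the envelope exceeds an adaptive threshold are localised to
#' the absolute-amplitude maximum of the signal, and a refractory period
#' suppresses double detections. Detection runs on the absolute amplitude so
#' records with inverted polarity still anchor on the R wave.
#'
#' @param record A preprocessed [ecg_record()] (baseline removed, smoothed).
#' @param refractory_s Minimum separation between detections in seconds
#'   (default 0.25 s).
#' @param threshold_frac Fraction of the high-quantile envelope level used as
#'   detection threshold (default 0.3).
#' @return Integer vector of strictly increasing R-peak sample indices
#'   (possibly empty).
#' @export
detect_r_peaks <- function(record, refractory_s = 0.25, threshold_frac = 0.3) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  if (!all(is.finite(x))) stop("record contains non-finite samples", call. = FALSE)
  fs <- record$fs
  refractory <- max(1L, as.integer(round(refractory_s * fs)))
  n <- length(x)
  if (n < refractory || all(x == 0)) return(integer(0))

  # QRS energy envelope: light band-limiting (15 ms average) before the
  # derivative keeps broadband noise out of the slope estimate
  xd <- moving_average(x, max(2L, min(n, as.integer(round(0.015 * fs)))))
  d <- c(0, diff(xd))
  integ_w <- max(2L, min(n, as.integer(round(0.12 * fs))))
  env <- moving_average(d^2, integ_w)

  # threshold sits a fraction of the way from the envelope floor (median,
  # i.e. the between-beat level) up to its peak level, so a raised noise
  # floor does not push it above the QRS peaks
  floor_lvl <- stats::median(env)
  peak_lvl <- stats::quantile(env, 0.99, names = FALSE)
  thr <- floor_lvl + threshold_frac * (peak_lvl - floor_lvl)
  if (thr <= 0) return(integer(0))

  above <- env > thr
  if (!any(above)) return(integer(0))

  # contiguous above-threshold regions -> one candidate each
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]

  half <- as.integer(round(0.05 * fs))
  cand <- integer(length(starts))
  strength <- numeric(length(starts))
  for (i in seq_along(starts)) {
    lo <- max(1L, starts[i] - half)
    hi <- min(n, ends[i] + half)
    seg <- lo:hi
    cand[i] <- seg[which.max(abs(x[seg]))]
    strength[i] <- max(env[starts[i]:ends[i]])
  }

  # merge candidates that localised to the same sample
  o <- order(cand)
  cand <- cand[o]; strength <- strength[o]
  dup <- duplicated(cand)
  cand <- cand[!dup]; strength <- strength[!dup]

  # refractory: greedily keep the strongest of any pair closer than the period
  keep <- rep(TRUE, length(cand))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2L) break
    gaps <- diff(cand[idx])
    viol <- which(gaps < refractory)
    if (length(viol) == 0L) break
    j <- viol[1L]
    a <- idx[j]; b <- idx[j + 1L]
    keep[if (strength[a] >= strength[b]) b else a] <- FALSE
  }
  cand[keep]
}

#' Cut fixed-length beat segments around R-peaks
#'
#' Extracts a window of `beat_length` samples centred on each R-peak:
#' `[r - floor(L/2), r - floor(L/2) + L)`. Peaks whose window would cross a
#' record boundary are dropped.
#'
#' @param record An [ecg_record()].
#' @param peaks Integer vector of R-peak indices into `record`.
#' @param beat_length Segment length in samples (default 784).
#' @return A tibble with one row per retained beat: `subject_id`, `r_index`
#'   and a `samples` list-column of length-`beat_length` numeric vectors.
#' @export
segment_beats <- function(record, peaks, beat_length = 784L) {
  stopifnot(inherits(record, "ecg_record"))
  beat_length <- as.integer(beat_length)
  if (is.na(beat_length) || beat_length < 1L) {
    stop("`beat_length` must be a positive integer", call. = FALSE)
  }
  peaks <- as.integer(peaks)
  n <- length(record$samples)
  if (any(peaks < 1L | peaks > n)) {
    stop("`peaks` must lie inside the record", call. = FALSE)
  }
  half <- beat_length %/% 2L
  starts <- peaks - half
  ok <- starts >= 1L & (starts + beat_length - 1L) <= n
  peaks <- peaks[ok]; starts <- starts[ok]
  tibble::tibble(
    subject_id = rep(record$subject_id, length(peaks)),
    r_index = peaks,
    samples = purrr::map2(starts, peaks, function(s, p) {
      record$samples[s:(s + beat_length - 1L)]
    })
  )
}

#' Run the full beat-extraction chain on a raw record
#'
#' Convenience wrapper: baseline removal, high-frequency smoothing, edge
#' trimming, R-peak detection and beat segmentation, with the standard
#' parameter set (window widths in samples).
#'
#' @param record Raw [ecg_record()].
#' @param baseline_width,smooth_width,trim_n,beat_length Stage parameters; see
#'   the individual stage functions.
#' @return A tibble of beats as returned by [segment_beats()].
#' @export
preprocess_record <- function(record, baseline_width = 500L, smooth_width = 10L,
                              trim_n = 600L, beat_length = 784L) {
  rec <- record |>
    remove_baseline(baseline_width) |>
    smooth_highfreq(smooth_width) |>
    trim_edges(trim_n)
  peaks <- detect_r_peaks(rec)
  segment_beats(rec, peaks, beat_length)
}
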