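# Physiological defaults for the Gaussian-sum beat model (amplitudes in mV,
# centres/widths in seconds relative to the R wave). Inter-subject sampling
# ranges are multiplicative jitter around these values; kept in one place so
# tests can reason about separability.
wave_defaults <- function() {
  tibble::tibble(
    wave = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.12, -0.12, 1.0, -0.18, 0.30),
    center = c(-0.200, -0.030, 0.000, 0.030, 0.250),
    width = c(0.025, 0.010, 0.012, 0.010, 0.040)
  )
}

#' Draw a synthetic subject's beat-morphology template
#'
#' Samples per-wave parameters (amplitude, centre offset from the R wave,
#' width) for the five ECG waves P, Q, R, S, T around physiological defaults,
#' plus a mean RR interval and its standard deviation. Amplitudes and widths
#' get +/-30% uniform jitter, centres +/-20%; the R amplitude is drawn from
#' 0.8-1.4 mV, so it is always the largest wave in magnitude. Templates are
#' deterministic given the seed, and distinct seeds give distinct templates
#' with probability ~1.
#'
#' @param seed Integer RNG seed.
#' @param subject_id Label attached to the template (default `"S<seed>"`).
#' @return An object of class `subject_template`: list with `waves` (tibble of
#'   wave parameters), `rr_mean`, `rr_sd` (seconds) and `subject_id`.
#' @export
sample_subject_template <- function(seed, subject_id = paste0("S", seed)) {
  withr::with_seed(as.integer(seed), {
    w <- wave_defaults()
    jitter_amp <- stats::runif(5, 0.7, 1.3)
    jitter_cen <- stats::runif(5, 0.8, 1.2)
    jitter_wid <- stats::runif(5, 0.7, 1.3)
    w$amplitude <- w$amplitude * jitter_amp
    w$amplitude[w$wave == "R"] <- stats::runif(1, 0.8, 1.4)
    w$center <- w$center * jitter_cen
    w$width <- w$width * jitter_wid
    rr_mean <- stats::runif(1, 0.7, 1.1)
  })
  structure(
    list(waves = w, rr_mean = rr_mean, rr_sd = 0.03,
         subject_id = as.character(subject_id)),
    class = "subject_template"
  )
}

#' @export
print.subject_template <- function(x, ...) {
  cat(sprintf("<subject_template> %s, RR %.3f +/- %.3f s, R amplitude %.2f mV\n",
              x$subject_id, x$rr_mean, x$rr_sd,
              x$waves$amplitude[x$waves$wave == "R"]))
  invisible(x)
}

#' Noise specification for synthetic recordings
#'
#' Additive noise model: sinusoidal baseline wander (respiration/movement
#' band), sinusoidal mains interference, and white Gaussian noise.
#'
#' @param baseline_mv,baseline_hz Baseline-wander amplitude (mV) and frequency
#'   (Hz); defaults 0.1 mV at 0.3 Hz.
#' @param mains_mv,mains_hz Powerline amplitude (mV) and frequency (Hz);
#'   defaults 0.05 mV at 60 Hz.
#' @param white_sd White-noise standard deviation (mV, default 0.05).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_mv = 0.1, baseline_hz = 0.3,
                       mains_mv = 0.05, mains_hz = 60,
                       white_sd = 0.05) {
  vals <- c(baseline_mv, mains_mv, white_sd)
  if (any(vals < 0)) stop("noise amplitudes must be >= 0", call. = FALSE)
  if (baseline_hz <= 0 || mains_hz <= 0) stop("noise frequencies must be > 0", call. = FALSE)
  structure(
    list(baseline_mv = baseline_mv, baseline_hz = baseline_hz,
         mains_mv = mains_mv, mains_hz = mains_hz, white_sd = white_sd),
    class = "noise_spec"
  )
}

#' Synthesize a single noiseless beat from a template
#'
#' Evaluates the five-wave Gaussian sum
#' \eqn{\sum_w A_w \exp(-(t - \mu_w)^2 / 2\sigma_w^2)} at the sampling rate,
#' with the R wave at the centre sample `floor(length/2) + 1`.
#'
#' @param template A [sample_subject_template()] object.
#' @param fs Sampling rate (Hz).
#' @param length Beat length in samples (>= 8).
#' @return Numeric vector of `length` samples.
#' @export
synthesize_beat <- function(template, fs = 1000, length = 784L) {
  stopifnot(inherits(template, "subject_template"))
  length <- as.integer(length)
  if (is.na(length) || length < 8L) stop("`length` must be >= 8", call. = FALSE)
  center <- length %/% 2L + 1L
  t <- (seq_len(length) - center) / fs
  w <- template$waves
  out <- numeric(length)
  for (i in seq_len(nrow(w))) {
    out <- out + w$amplitude[i] * exp(-(t - w$center[i])^2 / (2 * w$width[i]^2))
  }
  out
}

#' Synthesize a single-lead recording with ground-truth R-peaks
#'
#' Places beats at RR intervals drawn as `rr_mean + rr_sd * N(0,1)` (seeded),
#' the first R at `rr_mean / 2`, sums the Gaussian waves over the whole
#' record, then adds baseline wander, mains interference and white noise.
#'
#' @param template A [sample_subject_template()] object.
#' @param duration Recording length in seconds (>= 2 x mean RR).
#' @param fs Sampling rate (Hz, default 1000).
#' @param noise A [noise_spec()]; use zero amplitudes for a clean record.
#' @param seed Integer RNG seed (drives RR jitter and white noise).
#' @return List with `record` (an [ecg_record()]) and `r_peaks` (integer
#'   ground-truth R-peak sample indices).
#' @export
synthesize_recording <- function(template, duration, fs = 1000,
                                 noise = noise_spec(), seed = 1L) {
  stopifnot(inherits(template, "subject_template"), inherits(noise, "noise_spec"))
  if (duration < 2 * template$rr_mean) {
    stop("`duration` must cover at least two mean RR intervals", call. = FALSE)
  }
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  withr::with_seed(as.integer(seed), {
    # beat placement
    r_times <- numeric(0)
    cur <- template$rr_mean / 2
    while (cur < duration) {
      r_times <- c(r_times, cur)
      cur <- cur + template$rr_mean + template$rr_sd * stats::rnorm(1)
    }
    white <- stats::rnorm(n, sd = noise$white_sd)
  })
  # drop beats whose R lies outside the sampled range
  r_idx <- as.integer(round(r_times * fs)) + 1L
  keep <- r_idx >= 1L & r_idx <= n
  r_times <- r_times[keep]; r_idx <- r_idx[keep]

  x <- numeric(n)
  w <- template$waves
  for (r in r_times) {
    for (i in seq_len(nrow(w))) {
      mu <- r + w$center[i]; sd <- w$width[i]
      lo <- max(1L, as.integer(floor((mu - 6 * sd) * fs)))
      hi <- min(n, as.integer(ceiling((mu + 6 * sd) * fs)) + 1L)
      if (lo > hi) next
      seg <- lo:hi
      x[seg] <- x[seg] + w$amplitude[i] * exp(-(t[seg] - mu)^2 / (2 * sd^2))
    }
  }
  x <- x +
    noise$baseline_mv * sin(2 * pi * noise$baseline_hz * t) +
    noise$mains_mv * sin(2 * pi * noise$mains_hz * t) +
    if (noise$white_sd > 0) white else 0
  list(
    record = ecg_record(x, fs = fs, subject_id = template$subject_id),
    r_peaks = r_idx
  )
}

#' Synthesize a balanced multi-subject beat cohort
#'
#' Draws one template per subject, synthesizes a recording long enough to
#' carry the requested number of beats plus the edges consumed by filtering,
#' and cuts beats centred on the ground-truth R-peaks of the (noisy) record.
#' The result is exactly balanced: `beats_per_subject` segments per subject.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param beats_per_subject Beats per subject (default 60, matching a
#'   per-subject session of about one minute of rhythm).
#' @param fs Sampling rate (Hz, default 1000).
#' @param noise A [noise_spec()].
#' @param seed Integer master seed; subject templates use `seed + subject`.
#' @param beat_length Segment length in samples (default 784).
#' @return A tibble with columns `subject_id`, `beat` (index within subject),
#'   `samples` (list-column of length-`beat_length` vectors) and `r_index`.
#'   The per-subject templates are attached as attribute `"templates"`.
#' @export
synthesize_cohort <- function(n_subjects, beats_per_subject = 60L, fs = 1000,
                              noise = noise_spec(), seed = 1L,
                              beat_length = 784L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) {
    stop("`n_subjects` must be >= 2", call. = FALSE)
  }
  half <- beat_length %/% 2L
  out <- vector("list", n_subjects)
  templates <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    tpl <- sample_subject_template(seed + s, subject_id = sprintf("S%02d", s))
    templates[[s]] <- tpl
    # margin: trim + half a window each side, plus RR slack
    duration <- (beats_per_subject + 4) * tpl$rr_mean + 2 * (600 + half) / fs
    sim <- synthesize_recording(tpl, duration, fs, noise, seed = seed * 1000L + s)
    rec <- sim$record
    n <- length(rec$samples)
    ok <- sim$r_peaks - half >= 1L & sim$r_peaks - half + beat_length - 1L <= n
    peaks <- sim$r_peaks[ok]
    if (length(peaks) < beats_per_subject) {
      stop("internal: recording produced too few beats", call. = FALSE)
    }
    peaks <- peaks[seq_len(beats_per_subject)]
    beats <- segment_beats(rec, peaks, beat_length)
    beats$beat <- seq_len(nrow(beats))
    out[[s]] <- beats[, c("subject_id", "beat", "samples", "r_index")]
  }
  res <- dplyr::bind_rows(out)
  attr(res, "templates") <- templates
  res
}
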