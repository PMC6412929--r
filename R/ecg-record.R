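#' Construct a single-lead ECG record
#'
#' Lightweight container for a single-channel ECG sample sequence together
#' with its sampling rate, subject label and lead name. All preprocessing
#' functions take and return `ecg_record` objects.
#'
#' @param samples Numeric vector of amplitudes (mV, arbitrary offset). Must be
#'   finite and non-empty.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Opaque subject label (coerced to character).
#' @param lead Lead name; defaults to `"I"`, the lead used throughout the
#'   biometric pipeline.
#' @return An object of class `ecg_record`: a list with elements `samples`,
#'   `fs`, `subject_id` and `lead`.
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 100)), fs = 100)
#' print(rec)
#' @export
ecg_record <- function(samples, fs, subject_id = NA_character_, lead = "I") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("`samples` must contain at least one value", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      fs = as.numeric(fs),
      subject_id = as.character(subject_id),
      lead = as.character(lead)
    ),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> lead %s, %d samples @ %g Hz (%.2f s), subject %s\n",
    x$lead, length(x$samples), x$fs, length(x$samples) / x$fs, x$subject_id
  ))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

# Internal: accept an ecg_record or bare numeric vector; return the record
# (bare vectors get a 1 Hz placeholder rate, only used by pure sample ops).
as_ecg_record <- function(x, fs = 1) {
  if (inherits(x, "ecg_record")) return(x)
  ecg_record(x, fs = fs)
}
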