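#' Generalized Morse wavelet parameters
#'
#' The generalized Morse wavelet family is defined in the frequency domain by
#' \deqn{\Psi_{\beta,\gamma}(\omega) = U(\omega)\, a_{\beta,\gamma}\,
#'   \omega^{\beta} e^{-\omega^{\gamma}}}
#' where \eqn{U} is the unit step (the wavelet is analytic: zero response at
#' negative frequencies), \eqn{\gamma} controls symmetry and \eqn{\beta}
#' decay/compactness. Practitioners usually parameterise by the
#' time-bandwidth product \eqn{P^2 = \beta\gamma}. The defaults
#' (\eqn{\gamma = 3}, \eqn{P^2 = 60}, 12 voices per octave) give the
#' zero-skewness, minimum-Heisenberg-area member commonly used for ECG
#' time-frequency analysis. Cauchy wavelets are the \eqn{\gamma = 1} case and
#' Bessel wavelets are approximately \eqn{\beta = 8, \gamma = 1/4}.
#'
#' The normalization constant is the analytic-wavelet peak normalization
#' \eqn{a_{\beta,\gamma} = 2 (e\gamma/\beta)^{\beta/\gamma}}, which sets the
#' filter's maximum value to 2.
#'
#' @param gamma Symmetry parameter (> 0, default 3).
#' @param tbp Time-bandwidth product \eqn{P^2} (> 0, default 60).
#' @param voices_per_octave Number of geometrically spaced scales per octave
#'   (default 12).
#' @return An object of class `morse_params` with fields `gamma`, `beta`,
#'   `tbp`, `voices_per_octave`, `norm_constant` and `peak_omega` (the
#'   frequency-domain maximiser, rad/sample at unit scale).
#' @examples
#' p <- morse_params()
#' p$beta          # 20 = 60 / 3
#' p$peak_omega    # (beta/gamma)^(1/gamma)
#' @export
morse_params <- function(gamma = 3, tbp = 60, voices_per_octave = 12L) {
  if (!is.numeric(gamma) || gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  if (!is.numeric(tbp) || tbp <= 0) stop("`tbp` must be > 0", call. = FALSE)
  voices_per_octave <- as.integer(voices_per_octave)
  if (is.na(voices_per_octave) || voices_per_octave < 1L) {
    stop("`voices_per_octave` must be a positive integer", call. = FALSE)
  }
  beta <- beta_from_tbp(tbp, gamma)
  structure(
    list(
      gamma = gamma,
      tbp = tbp,
      beta = beta,
      voices_per_octave = voices_per_octave,
      norm_constant = 2 * (exp(1) * gamma / beta)^(beta / gamma),
      peak_omega = (beta / gamma)^(1 / gamma)
    ),
    class = "morse_params"
  )
}

#' @export
print.morse_params <- function(x, ...) {
  cat(sprintf(
    "<morse_params> gamma=%g, beta=%g (P^2=%g), %d voices/octave, peak omega=%.5f\n",
    x$gamma, x$beta, x$tbp, x$voices_per_octave, x$peak_omega
  ))
  invisible(x)
}

#' Decay parameter from the time-bandwidth product
#'
#' Inverts \eqn{P^2 = \beta\gamma}: returns \eqn{\beta = P^2/\gamma}.
#'
#' @param tbp Time-bandwidth product \eqn{P^2} (> 0).
#' @param gamma Symmetry parameter (> 0).
#' @return The decay parameter \eqn{\beta}.
#' @examples
#' beta_from_tbp(60, 3)  # 20
#' @export
beta_from_tbp <- function(tbp, gamma) {
  if (!is.numeric(tbp) || length(tbp) != 1L || !is.finite(tbp) || tbp <= 0) {
    stop("`tbp` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    stop("`gamma` must be a single positive number", call. = FALSE)
  }
  tbp / gamma
}

#' Frequency response of the generalized Morse wavelet
#'
#' Evaluates \eqn{\Psi_{\beta,\gamma}(\omega) = U(\omega) a_{\beta,\gamma}
#' \omega^{\beta} e^{-\omega^{\gamma}}} at angular frequency `omega`
#' (rad/sample). The response is exactly zero for `omega <= 0` and has a
#' single interior maximum of value 2 at [morse_peak_frequency()].
#'
#' @param omega Numeric vector of angular frequencies (rad/sample).
#' @param params A [morse_params()] object.
#' @return Non-negative numeric vector, same length as `omega`.
#' @export
morse_psi_hat <- function(omega, params = morse_params()) {
  stopifnot(inherits(params, "morse_params"))
  out <- numeric(length(omega))
  pos <- is.finite(omega) & omega > 0
  w <- omega[pos]
  # evaluate on the log scale: omega^beta overflows for beta = 20 long before
  # the exponential term pulls the product back down
  out[pos] <- params$norm_constant *
    exp(params$beta * log(w) - w^params$gamma)
  out
}

#' Peak frequency of the Morse wavelet
#'
#' The analytic maximiser of the frequency response:
#' \eqn{\omega^* = (\beta/\gamma)^{1/\gamma}} rad/sample at unit scale. For a
#' wavelet dilated by scale `a`, the response peaks at \eqn{\omega^*/a}.
#'
#' @inheritParams morse_psi_hat
#' @return Peak angular frequency (rad/sample).
#' @examples
#' morse_peak_frequency(morse_params())  # (20/3)^(1/3) ~ 1.882
#' @export
morse_peak_frequency <- function(params = morse_params()) {
  stopifnot(inherits(params, "morse_params"))
  params$peak_omega
}

# Internal: time-domain standard deviation (in samples) of the unit-scale
# wavelet, computed once from |psi(t)|^2 moments via a fine inverse DFT.
morse_time_sd <- function(params) {
  M <- 2^14
  k <- 0:(M - 1)
  om <- 2 * pi * k / M
  psi_hat <- morse_psi_hat(om, params)
  psi_hat[k > M / 2] <- 0
  psi <- stats::fft(psi_hat, inverse = TRUE) / M
  # centre time axis on zero
  t <- ifelse(k <= M / 2, k, k - M)
  p <- Mod(psi)^2
  sqrt(sum(t^2 * p) / sum(p))
}

#' Build a voices-per-octave scale grid
#'
#' Constructs the geometric scale axis \eqn{s_j = s_{\min} 2^{j/V}} used to
#' discretise the continuous wavelet transform. The smallest scale is chosen
#' so the dilated wavelet has negligible response beyond the Nyquist
#' frequency (filter value below `nyquist_tol` at \eqn{\omega = \pi}); the
#' largest scale is limited so the wavelet's time-domain standard deviation
#' does not exceed a quarter of the signal length (boundary-effect guard).
#'
#' @param n_samples Signal length the transform will be applied to (>= 4).
#' @param fs Sampling rate in Hz, used only to label each scale with its
#'   centre frequency; it does not alter the coefficients of a given sample
#'   sequence.
#' @param params A [morse_params()] object.
#' @param nyquist_tol Maximum admissible filter value at Nyquist for the
#'   smallest scale (default 1e-8).
#' @return An object of class `scale_grid`: list with `scales` (dimensionless,
#'   strictly increasing), `center_frequencies` (Hz, strictly decreasing),
#'   `fs`, `n_samples` and `params`.
#' @export
build_scale_grid <- function(n_samples, fs, params = morse_params(),
                             nyquist_tol = 1e-8) {
  stopifnot(inherits(params, "morse_params"))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 4L) {
    stop("`n_samples` must be an integer >= 4", call. = FALSE)
  }
  wp <- params$peak_omega
  # smallest scale: peak at/below Nyquist with tail below tolerance there
  f <- function(s) morse_psi_hat(s * pi, params) - nyquist_tol
  s_lo <- wp / pi                        # peak exactly at Nyquist
  s_hi <- s_lo
  while (f(s_hi) > 0 && s_hi < 1e6) s_hi <- s_hi * 2
  s_min <- if (f(s_lo) <= 0) s_lo else stats::uniroot(f, c(s_lo, s_hi), tol = 1e-12)$root

  sd1 <- morse_time_sd(params)
  s_max <- (n_samples / 4) / sd1
  if (s_max <= s_min * 2^(1 / params$voices_per_octave)) {
    stop("`n_samples` too small to fit one voice between the scale limits",
         call. = FALSE)
  }
  V <- params$voices_per_octave
  n_scales <- floor(V * log2(s_max / s_min)) + 1
  scales <- s_min * 2^((seq_len(n_scales) - 1) / V)
  structure(
    list(
      scales = scales,
      center_frequencies = wp / (2 * pi * scales) * fs,
      fs = fs,
      n_samples = n_samples,
      params = params
    ),
    class = "scale_grid"
  )
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf(
    "<scale_grid> %d scales in [%.4g, %.4g] (%d voices/octave), centre freq %.4g-%.4g Hz @ fs=%g\n",
    length(x$scales), min(x$scales), max(x$scales),
    x$params$voices_per_octave,
    min(x$center_frequencies), max(x$center_frequencies), x$fs
  ))
  invisible(x)
}

#' Continuous wavelet transform with generalized Morse wavelets
#'
#' Computes the analytic CWT of a real signal on the scales of `grid`. The
#' transform is evaluated in the frequency domain: the signal is extended by
#' symmetric reflection at both ends, zero-padded to the next power of two,
#' and for each scale the inverse FFT of (signal spectrum x dilated wavelet
#' filter) yields one row of coefficients — one coefficient per input sample,
#' no time decimation. Negative-frequency bins carry zero filter response, so
#' the coefficients are complex analytic.
#'
#' @param signal Numeric vector whose length matches `grid$n_samples`.
#' @param grid A [build_scale_grid()] object.
#' @param boundary `"reflect"` (default) extends the signal symmetrically
#'   before padding, which suppresses edge artefacts on finite beats;
#'   `"periodic"` treats the signal as circular without extension, in which
#'   case the transform is exactly covariant under circular shifts.
#' @return Complex matrix of dimension `n_scales x n_time` (rows ordered as
#'   `grid$scales`, i.e. smallest scale / highest frequency first).
#' @export
morse_cwt <- function(signal, grid, boundary = c("reflect", "periodic")) {
  stopifnot(inherits(grid, "scale_grid"))
  boundary <- match.arg(boundary)
  signal <- as.numeric(signal)
  if (!all(is.finite(signal))) stop("`signal` must be finite", call. = FALSE)
  n <- length(signal)
  if (n != grid$n_samples) {
    stop("`signal` length does not match the grid's `n_samples`", call. = FALSE)
  }
  params <- grid$params
  if (boundary == "reflect") {
    ext <- n %/% 2                     # reflected extension on each side
    left <- signal[ext:1]
    right <- signal[n:(n - ext + 1L)]
    x <- c(left, signal, right)
    M <- 2^ceiling(log2(length(x)))
    x <- c(x, numeric(M - length(x)))
  } else {
    ext <- 0L
    x <- signal
    M <- n                             # no padding: keep exact circularity
  }
  X <- stats::fft(x)
  k <- 0:(M - 1)
  om <- 2 * pi * k / M
  pos <- k <= M / 2                    # analytic: keep only non-negative bins
  out <- matrix(0 + 0i, nrow = length(grid$scales), ncol = n)
  sel <- (ext + 1L):(ext + n)
  for (j in seq_along(grid$scales)) {
    filt <- numeric(M)
    filt[pos] <- morse_psi_hat(grid$scales[j] * om[pos], params)
    w <- stats::fft(X * filt, inverse = TRUE) / M
    out[j, ] <- w[sel]
  }
  out
}

#' Scalogram of a CWT coefficient matrix
#'
#' The scalogram is the entrywise absolute value of the continuous wavelet
#' transform coefficients: a non-negative scale-by-time matrix.
#'
#' @param coeffs Complex (or numeric) coefficient matrix, scales in rows.
#' @param grid The [build_scale_grid()] the coefficients were computed on.
#' @return An object of class `scalogram`: list with `magnitude` (matrix),
#'   `scale_axis` (the grid) and `time_axis` (sample indices).
#' @export
scalogram <- function(coeffs, grid) {
  stopifnot(inherits(grid, "scale_grid"))
  if (!is.matrix(coeffs)) stop("`coeffs` must be a matrix", call. = FALSE)
  mag <- Mod(coeffs)
  if (!all(is.finite(mag))) stop("`coeffs` must be finite", call. = FALSE)
  structure(
    list(
      magnitude = mag,
      scale_axis = grid,
      time_axis = seq_len(ncol(mag))
    ),
    class = "scalogram"
  )
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf(
    "<scalogram> %d scales x %d samples, magnitude in [%.3g, %.3g]\n",
    nrow(x$magnitude), ncol(x$magnitude), min(x$magnitude), max(x$magnitude)
  ))
  invisible(x)
}

#' Compute the scalogram of a beat in one call
#'
#' Builds (or reuses) a scale grid for the beat length and returns the
#' scalogram of the beat's Morse CWT.
#'
#' @param samples Numeric beat samples.
#' @param fs Sampling rate (Hz) for axis labelling.
#' @param params A [morse_params()] object.
#' @param grid Optional precomputed [build_scale_grid()] (recomputed when
#'   `NULL`); passing one avoids rebuilding it for every beat of a cohort.
#' @return A `scalogram` object.
#' @export
beat_scalogram <- function(samples, fs = 1000, params = morse_params(), grid = NULL) {
  if (is.null(grid)) grid <- build_scale_grid(length(samples), fs, params)
  scalogram(morse_cwt(samples, grid), grid)
}
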