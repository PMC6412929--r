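# shared fixtures and independent oracles for the test suite

# match detections to ground truth within a tolerance (seconds); one-to-one
score_detections <- function(detected, truth, fs, tol_s = 0.02) {
  tol <- tol_s * fs
  matched <- 0L
  used <- rep(FALSE, length(detected))
  for (r in truth) {
    d <- abs(detected - r)
    j <- which(!used & d <= tol)
    if (length(j) > 0L) {
      matched <- matched + 1L
      used[j[which.min(d[j])]] <- TRUE
    }
  }
  list(
    sensitivity = matched / length(truth),
    ppv = if (length(detected)) matched / length(detected) else 0
  )
}

# solid-intensity image with small texture noise: the two classes are
# separable by a single global threshold
solid_image <- function(level, jitter = 0.05) {
  array(pmin(1, pmax(0, level + stats::runif(28 * 28 * 3, -jitter, jitter))),
        dim = c(28L, 28L, 3L))
}

separable_image_data <- function(n_per_class = 100L, seed = 9L) {
  withr::with_seed(seed, tibble::tibble(
    image = c(lapply(seq_len(n_per_class), function(i) solid_image(0.2)),
              lapply(seq_len(n_per_class), function(i) solid_image(0.8))),
    label = rep(c("dark", "bright"), each = n_per_class)
  ))
}

# independent time-domain CWT oracle: direct summation of the discretized
# transform over the same reflect-extended signal morse_cwt uses, with the
# dilated wavelet's time samples obtained by trapezoid quadrature of the
# frequency-domain definition (no FFT anywhere).
direct_cwt_oracle <- function(x, scales, params) {
  n <- length(x)
  ext <- n %/% 2
  xe <- c(x[ext:1], x, x[n:(n - ext + 1)])
  K <- 2^15
  w <- seq(0, pi, length.out = K + 1)
  toff <- -(2 * n - 1):(2 * n - 1)
  out <- matrix(0 + 0i, length(scales), n)
  for (j in seq_along(scales)) {
    Psi <- morse_psi_hat(scales[j] * w, params)
    h <- vapply(toff, function(t0) {
      integrand <- Psi * exp(1i * w * t0)
      (sum(integrand) - (integrand[1] + integrand[K + 1]) / 2) *
        (pi / K) / (2 * pi)
    }, complex(1))
    for (b in seq_len(n)) {
      offs <- seq_along(xe) - (b + ext)
      out[j, b] <- sum(xe * Conj(h[offs + 2 * n]))
    }
  }
  out
}

# brute-force ROC: enumerate every threshold candidate and recompute rates
# from first principles (strictly-greater decision rule)
brute_roc <- function(scores, labels) {
  y <- as.logical(labels)
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
           u[length(u)] + 1)
  t(vapply(thr, function(th) {
    pred <- scores > th
    c(threshold = th,
      fpr = sum(pred & !y) / sum(!y),
      tpr = sum(pred & y) / sum(y))
  }, numeric(3)))
}

# brute-force EER on the brute-force ROC by scanning for the fpr = fnr
# crossing with linear interpolation
brute_eer <- function(scores, labels) {
  pts <- brute_roc(scores, labels)
  pts <- pts[order(-pts[, "threshold"]), , drop = FALSE]
  fpr <- pts[, "fpr"]; fnr <- 1 - pts[, "tpr"]
  d <- fpr - fnr
  hit <- which(d == 0)
  if (length(hit)) return(fpr[hit[1]])
  k <- which(d[-length(d)] < 0 & d[-1] > 0)
  if (!length(k)) {
    i <- which.min(abs(d))
    return((fpr[i] + fnr[i]) / 2)
  }
  i <- k[1]
  t <- -d[i] / (d[i + 1] - d[i])
  fpr[i] + t * (fpr[i + 1] - fpr[i])
}

# small pipeline config for fast end-to-end tests
tiny_pipeline_config <- function(seed = 1L) {
  cfg <- default_pipeline_config()
  cfg$n_subjects <- 3L
  cfg$beats_per_subject <- 12L
  cfg$epochs <- 2L
  cfg$seed <- as.integer(seed)
  cfg
}
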