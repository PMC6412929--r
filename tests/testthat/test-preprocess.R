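test_that("moving_average matches direct window means and handles edges", {
  # constant signal is preserved for any width
  for (w in c(1, 3, 10)) {
    expect_equal(moving_average(rep(2.5, 20), w), rep(2.5, 20))
  }
  # unit impulse spreads to a 1/width plateau
  x <- c(rep(0, 20), 1, rep(0, 20))
  out <- moving_average(x, 10)
  expect_equal(sum(out > 0), 10L)
  expect_equal(unique(round(out[out > 0], 12)), 0.1)
  # linear ramp: interior samples equal the window mean computed by direct
  # summation (symmetric window -> value at the centre)
  ramp <- 0:49
  out <- moving_average(ramp, 5)
  direct <- vapply(3:48, function(i) mean(ramp[(i - 2):(i + 2)]), numeric(1))
  expect_equal(out[3:48], direct)
  expect_equal(out[10], 9)  # 0-based ramp value at index 10
  # argument errors
  expect_error(moving_average(1:5, 0), "positive")
  expect_error(moving_average(1:5, 6), "exceed")
})

test_that("moving_average is linear", {
  set.seed(11)
  x <- rnorm(64); y <- rnorm(64)
  expect_equal(moving_average(2 * x - 3 * y, 7),
               2 * moving_average(x, 7) - 3 * moving_average(y, 7))
})

test_that("remove_baseline suppresses low-frequency drift", {
  fs <- 1000
  # constant maps to zero
  rec <- ecg_record(rep(1.7, 2000), fs)
  expect_equal(remove_baseline(rec)$samples, rep(0, 2000))
  # 0.3 Hz sinusoid attenuated by > 90% at interior samples
  t <- (0:9999) / fs
  drift <- sin(2 * pi * 0.3 * t)
  out <- remove_baseline(ecg_record(drift, fs), 500)$samples
  interior <- 1000:9000
  expect_lt(max(abs(out[interior])), 0.1)
  # beat train + drift: output correlates better with the clean train
  tpl <- sample_subject_template(3)
  clean <- synthesize_recording(tpl, 10, fs, noise_spec(0, 0.3, 0, 60, 0),
                                seed = 1)$record$samples
  noisy <- clean + 0.5 * drift[seq_along(clean)]
  out <- remove_baseline(ecg_record(noisy, fs), 500)$samples
  expect_gt(cor(out[interior], clean[interior]),
            cor(noisy[interior], clean[interior]))
  expect_error(remove_baseline(ecg_record(1:10, fs), 500), "longer")
})

test_that("smooth_highfreq nulls a 100 Hz tone and reduces noise variance", {
  fs <- 1000
  rec <- ecg_record(rep(-0.4, 100), fs)
  expect_equal(smooth_highfreq(rec)$samples, rep(-0.4, 100))
  t <- (0:4999) / fs
  tone <- sin(2 * pi * 100 * t)
  out <- smooth_highfreq(ecg_record(tone, fs), 10)$samples
  expect_lt(max(abs(out[500:4500])), 0.01)
  set.seed(4)
  noise <- rnorm(5000)
  out <- smooth_highfreq(ecg_record(noise, fs), 10)$samples
  expect_lt(var(out), var(noise))
})

test_that("trim_edges arithmetic is exact and composes additively", {
  rec <- ecg_record(seq_len(2000), 1000)
  expect_length(trim_edges(rec, 600)$samples, 800L)
  expect_equal(trim_edges(rec, 0)$samples, rec$samples)
  one <- trim_edges(ecg_record(seq_len(1201), 1000), 600)
  expect_equal(one$samples, 601)
  # composition: trimming n1 then n2 equals trimming n1 + n2
  expect_equal(trim_edges(trim_edges(rec, 100), 150)$samples,
               trim_edges(rec, 250)$samples)
  expect_error(trim_edges(ecg_record(1:10, 1), 5), "longer")
})

test_that("detect_r_peaks recovers ground truth on synthetic records", {
  fs <- 1000
  tpl <- sample_subject_template(7)
  # noise-free: every true R matched within +/-20 ms, no extras
  sim <- synthesize_recording(tpl, 70, fs, noise_spec(0, 0.3, 0, 60, 0), seed = 3)
  rec <- trim_edges(smooth_highfreq(remove_baseline(sim$record)))
  det <- detect_r_peaks(rec)
  truth <- sim$r_peaks - 600
  truth <- truth[truth >= 1 & truth <= length(rec$samples)]
  sc <- score_detections(det, truth, fs)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$ppv, 1)
  # strictly increasing with refractory spacing
  expect_true(all(diff(det) >= 0.25 * fs))
  # all-zero record
  expect_identical(detect_r_peaks(ecg_record(rep(0, 5000), fs)), integer(0))
  # inverted polarity still detected (absolute amplitude)
  rec_inv <- rec; rec_inv$samples <- -rec_inv$samples
  det_inv <- detect_r_peaks(rec_inv)
  expect_gte(score_detections(det_inv, truth, fs)$sensitivity, 0.99)
})

test_that("detector reaches 99% sensitivity and precision at 10 dB SNR", {
  fs <- 1000
  tpl <- sample_subject_template(7)
  clean <- synthesize_recording(tpl, 70, fs, noise_spec(0, 0.3, 0, 60, 0),
                                seed = 3)$record$samples
  sigma <- sqrt(mean(clean^2) / 10)      # 10 dB signal-to-noise
  sim <- synthesize_recording(tpl, 70, fs,
                              noise_spec(0.1, 0.3, 0.05, 60, sigma), seed = 3)
  rec <- trim_edges(smooth_highfreq(remove_baseline(sim$record)))
  det <- detect_r_peaks(rec)
  truth <- sim$r_peaks - 600
  truth <- truth[truth >= 1 & truth <= length(rec$samples)]
  expect_gte(length(truth), 60L)
  sc <- score_detections(det, truth, fs)
  expect_gte(sc$sensitivity, 0.99)
  expect_gte(sc$ppv, 0.99)
})

test_that("segment_beats centres windows and drops boundary peaks", {
  rec <- ecg_record(seq_len(784), 1000, subject_id = "A")
  # window exactly fits
  seg <- segment_beats(rec, 393, 784)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$samples[[1]], as.numeric(1:784))
  # window underflows -> dropped
  expect_equal(nrow(segment_beats(rec, 10, 784)), 0L)
  # equally spaced peaks all inside a long record
  long <- ecg_record(rnorm(784 * 70), 1000, subject_id = "B")
  peaks <- seq(1000, by = 800, length.out = 60)
  seg <- segment_beats(long, peaks, 784)
  expect_equal(nrow(seg), 60L)
  expect_true(all(lengths(seg$samples) == 784L))
  # centring: the peak sample sits at index floor(L/2) + 1 of its window
  i <- 5
  expect_equal(seg$samples[[i]][784 %/% 2 + 1],
               long$samples[seg$r_index[i]])
  expect_error(segment_beats(rec, 10000, 784), "inside")
})
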