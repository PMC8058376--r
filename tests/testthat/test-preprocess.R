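test_that("high-pass removes DC and preserves in-band amplitude", {
  rec <- recording(rep(10, 60000), 1000)
  out <- highpass_filter(rec, 0.3)
  expect_lt(abs(mean(out$samples)), 0.01)
  expect_identical(length(out$samples), length(rec$samples))

  # 10 Hz is far above the 0.3 Hz corner: analytic Butterworth magnitude
  # |H| = 1 / sqrt(1 + (0.3/10)^(2*4)) deviates from 1 by < 1e-12, and the
  # forward-backward pass squares it; amplitude must survive within 1%
  sine <- sine_recording(10, duration_s = 10)
  filt <- highpass_filter(sine, 0.3)
  mid <- 2000:8000
  expect_equal(max(abs(filt$samples[mid])), 1, tolerance = 0.01)
})

test_that("high-pass rejects cutoffs at or above Nyquist", {
  rec <- noise_recording(1, 1000)
  expect_error(highpass_filter(rec, 600), "rate_hz / 2", fixed = TRUE)
})

test_that("filtering is linear within float tolerance", {
  rec <- noise_recording(5, 1000, seed = 7)
  scaled <- rec
  scaled$samples <- 3.5 * rec$samples
  f1 <- highpass_filter(rec)$samples
  f2 <- highpass_filter(scaled)$samples
  expect_equal(f2, 3.5 * f1, tolerance = 1e-10)
})

test_that("epoching forms non-overlapping windows and drops the remainder", {
  rec <- noise_recording(300, 1000)
  es <- epoch_recording(rec, 30)
  expect_identical(dim(es$epochs), c(10L, 30000L))
  expect_true(all(es$keep))

  es2 <- epoch_recording(noise_recording(305, 1000), 30)
  expect_identical(nrow(es2$epochs), 10L)

  expect_error(epoch_recording(noise_recording(10, 1000), 30), "shorter")
})

test_that("epoched samples reproduce the analyzed span sample-for-sample", {
  rec <- noise_recording(65, 1000, seed = 3)
  es <- epoch_recording(rec, 30)
  flat <- as.vector(t(es$epochs))
  expect_identical(flat, rec$samples[1:60000])
})

test_that("artifact rejection flags only offending epochs and keeps values intact", {
  rec <- noise_recording(60, 1000, sd = 30, seed = 5)
  es <- epoch_recording(rec, 10)
  clean <- reject_artifacts(es, 500)
  expect_identical(clean$keep, rep(TRUE, 6))

  es$epochs[3, 1234] <- 1000
  flagged <- suppressMessages(reject_artifacts(es, 500))
  expect_identical(which(!flagged$keep), 3L)
  expect_identical(flagged$epochs, es$epochs)

  expect_error(reject_artifacts(es, 0.001), "nothing left")
  expect_error(reject_artifacts(es, -5), "positive")
})
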