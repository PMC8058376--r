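test_that("integrated Welch PSD satisfies Parseval on white noise", {
  rec <- noise_recording(300, 1000, seed = 11)
  ps <- compute_psd(epoch_recording(rec, 30))
  total <- sum(ps$psd) * attr(ps, "resolution_hz")
  expect_equal(total, var(rec$samples), tolerance = 0.05)
  expect_true(all(ps$psd >= 0))
  expect_equal(attr(ps, "resolution_hz"), 0.5)
})

test_that("a pure sine concentrates its power at the nearest grid point", {
  amp <- 3
  rec <- sine_recording(10, duration_s = 60, amplitude = amp)
  ps <- compute_psd(epoch_recording(rec, 30))
  total <- sum(ps$psd) * attr(ps, "resolution_hz")
  expect_equal(total, amp^2 / 2, tolerance = 0.02)
  expect_equal(ps$freq_hz[which.max(ps$psd)], 10)
})

test_that("too-coarse segment lengths are a parameter error", {
  es <- epoch_recording(noise_recording(10, 1000), 5)
  expect_error(compute_psd(es, seg_s = 0.5), "resolution")
  expect_error(compute_psd(es, seg_s = 2, overlap_frac = 1), "overlap")
})

test_that("band powers are rectangle sums with half-open edges", {
  # synthesize a flat spectrum object directly
  ps <- compute_psd(epoch_recording(noise_recording(10, 1000), 10))
  flat <- ps
  flat$psd <- rep(1, nrow(flat))
  expect_equal(band_power(flat, "delta"), 3)
  expect_equal(band_power(flat, "theta"), 4)
  expect_equal(band_power(flat, "reference"), 39)
  expect_equal(band_power(flat, c(0, 40)), 40)
  zero <- ps
  zero$psd <- rep(0, nrow(zero))
  for (b in qeeg_bands()$band) expect_equal(band_power(zero, b), 0)
  expect_error(band_power(ps, c(400, 600)), "outside")
})

test_that("relative band powers sum to one and scale out amplitude", {
  rec <- noise_recording(60, 1000, seed = 2)
  ps <- compute_psd(epoch_recording(rec, 30))
  bp <- relative_bandpower(ps)
  expect_equal(sum(bp$rel_power), 1, tolerance = 1e-9)
  expect_equal(bp$abs_power, bp$rel_power * attr(bp, "reference_power"),
               tolerance = 1e-12)
  # band additivity: disjoint bands tile the reference exactly
  expect_equal(sum(bp$abs_power), band_power(ps, "reference"), tolerance = 1e-12)

  scaled <- rec
  scaled$samples <- 5 * rec$samples
  bp2 <- relative_bandpower(compute_psd(epoch_recording(scaled, 30)))
  expect_equal(bp2$rel_power, bp$rel_power, tolerance = 1e-12)
  expect_equal(bp2$abs_power, 25 * bp$abs_power, tolerance = 1e-9)
})

test_that("flat spectrum gives relative delta 3/39", {
  ps <- compute_psd(epoch_recording(noise_recording(10, 1000), 10))
  ps$psd <- rep(1, nrow(ps))
  bp <- relative_bandpower(ps)
  expect_equal(bp$rel_power[bp$band == "delta"], 3 / 39, tolerance = 1e-12)
})

test_that("a band-centered sine dominates its band after high-pass", {
  rec <- sine_recording(2, duration_s = 60)
  es <- epoch_recording(highpass_filter(rec), 30)
  bp <- relative_bandpower(compute_psd(es))
  expect_gte(bp$rel_power[bp$band == "delta"], 0.99)
})

test_that("spectra with no reference-band power are a degenerate input", {
  rec <- sine_recording(100, duration_s = 10) # all power above 40 Hz
  ps <- compute_psd(epoch_recording(rec, 10))
  ps$psd[ps$freq_hz < 40] <- 0
  expect_error(relative_bandpower(ps), "degenerate|zero power")
})

test_that("Welch with one full-length segment equals the direct periodogram", {
  rec <- noise_recording(4, 1000, seed = 9)
  ps <- compute_psd(epoch_recording(rec, 4), seg_s = 4, overlap_frac = 0)
  x <- rec$samples * qeegstroke:::hann_window(4000)
  X <- fft(x)
  n <- 2001
  direct <- Mod(X[1:n])^2 / (1000 * sum(qeegstroke:::hann_window(4000)^2))
  direct[2:(n - 1)] <- 2 * direct[2:(n - 1)]
  expect_equal(ps$psd, direct, tolerance = 1e-12)
  expect_identical(attr(ps, "n_segments"), 1L)
})

test_that("frequency distribution restricts the grid below the ceiling", {
  ps <- compute_psd(epoch_recording(noise_recording(10, 1000), 10))
  fd <- frequency_distribution(ps, 40)
  expect_identical(nrow(fd), 80L) # floor(40 / 0.5)
  expect_true(all(fd$freq_hz < 40))
  expect_identical(fd$psd, ps$psd[ps$freq_hz < 40])
  expect_error(frequency_distribution(ps, 600), "Nyquist")
})
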