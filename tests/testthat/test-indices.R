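bp_of <- function(d, t, a, b, r = 0) {
  tibble::tibble(band = c("delta", "theta", "alpha", "beta", "residual"),
                 rel_power = c(d, t, a, b, r))
}

test_that("indices follow their defining ratios", {
  qi <- compute_indices(bp_of(0.25, 0.25, 0.25, 0.25))
  expect_equal(unlist(qi), c(dtr = 1, dar = 1, dtabr = 1))

  qi2 <- compute_indices(bp_of(0.4, 0.2, 0.2, 0.2))
  expect_equal(qi2$dtr, 2)
  expect_equal(qi2$dar, 2)
  expect_equal(qi2$dtabr, 1.5)
})

test_that("indices from absolute powers equal indices from relative powers", {
  rec <- noise_recording(60, 1000, seed = 4)
  bp <- relative_bandpower(compute_psd(epoch_recording(rec, 30)))
  rel <- compute_indices(bp)
  abs_only <- bp[, c("band", "abs_power")]
  expect_equal(compute_indices(abs_only), rel, tolerance = 1e-12)
})

test_that("increasing delta with other bands fixed raises all three indices", {
  base <- compute_indices(bp_of(0.3, 0.25, 0.2, 0.25))
  up <- compute_indices(bp_of(0.4, 0.25, 0.2, 0.25))
  expect_true(all(unlist(up) > unlist(base)))
})

test_that("fractions inverted from the anesthetized index row round-trip exactly", {
  f <- invert_indices_to_fractions(1.62, 6.45, 4.95, residual = 0.05)
  qi <- compute_indices(tibble::tibble(band = names(f), rel_power = unname(f)))
  expect_equal(qi$dtr, 1.62, tolerance = 1e-12)
  expect_equal(qi$dar, 6.45, tolerance = 1e-12)
  expect_equal(qi$dtabr, 4.95, tolerance = 1e-12)
})

test_that("zero denominator bands are named in the error", {
  expect_error(compute_indices(bp_of(0.5, 0, 0.25, 0.25)), "theta")
  expect_error(compute_indices(bp_of(0.5, 0.5, 0, 0)), "alpha")
})

test_that("classification uses strict exceedance of the published thresholds", {
  qi <- tibble::tibble(dar = c(13.07, 3.08, 3.7), dtabr = c(8.68, 2.80, 3.5))
  out <- classify_ischemia(qi)
  expect_identical(out$dar_ischemic, c(TRUE, FALSE, FALSE))
  expect_identical(out$dtabr_ischemic, c(TRUE, FALSE, FALSE))
  expect_error(classify_ischemia(qi, dar_threshold = -1), "positive")
})

test_that("indices are invariant to overall amplitude scaling", {
  rec <- noise_recording(60, 1000, seed = 6)
  scaled <- rec
  scaled$samples <- 0.1 * rec$samples
  q1 <- compute_indices(relative_bandpower(compute_psd(epoch_recording(rec, 30))))
  q2 <- compute_indices(relative_bandpower(compute_psd(epoch_recording(scaled, 30))))
  expect_equal(q1, q2, tolerance = 1e-10)
})
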