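test_that("index inversion is the exact identity for feasible triples", {
  grid <- expand.grid(dtr = c(0.5, 1, 2, 5, 10), dar = c(0.5, 1, 2, 5, 10),
                      dtabr = c(0.5, 1, 2, 5, 10))
  n_feasible <- 0
  for (i in seq_len(nrow(grid))) {
    tri <- grid[i, ]
    feasible <- (tri$dar + tri$dar / tri$dtr) / tri$dtabr > 1
    if (!feasible) {
      expect_error(invert_indices_to_fractions(tri$dtr, tri$dar, tri$dtabr),
                   "infeasible")
      next
    }
    n_feasible <- n_feasible + 1
    f <- invert_indices_to_fractions(tri$dtr, tri$dar, tri$dtabr, residual = 0.05)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    qi <- compute_indices(tibble::tibble(band = names(f), rel_power = unname(f)))
    expect_equal(qi$dtr, tri$dtr, tolerance = 1e-12)
    expect_equal(qi$dar, tri$dar, tolerance = 1e-12)
    expect_equal(qi$dtabr, tri$dtabr, tolerance = 1e-12)
  }
  expect_gt(n_feasible, 50)
})

test_that("the symmetric triple inverts to equal fractions", {
  f <- invert_indices_to_fractions(1, 1, 1, residual = 0)
  expect_equal(unname(f), c(0.25, 0.25, 0.25, 0.25, 0), tolerance = 1e-12)
})

test_that("acute presets forward to their defining index rows", {
  pp <- phase_presets()
  rows <- list(ISP = c(4.20, 13.07, 8.68), IRP = c(0.74, 3.08, 2.80),
               anesthetized = c(1.62, 6.45, 4.95))
  for (ph in names(rows)) {
    f <- pp[[ph]]$fractions
    qi <- compute_indices(tibble::tibble(band = names(f), rel_power = unname(f)))
    expect_equal(c(qi$dtr, qi$dar, qi$dtabr), rows[[ph]], tolerance = 1e-12)
  }
  for (p in pp) expect_equal(sum(p$fractions), 1, tolerance = 1e-9)
  expect_identical(sort(names(pp)),
                   sort(phase_labels()$phase))
})

test_that("preset table CSV round-trips at full precision", {
  pp <- phase_presets()
  path <- withr::local_tempfile(fileext = ".csv")
  write_preset_table(pp, path)
  back <- read_preset_table(path)
  expect_identical(names(back), names(pp))
  for (ph in names(pp)) {
    expect_equal(back[[ph]]$fractions, pp[[ph]]$fractions, tolerance = 1e-12)
    expect_equal(back[[ph]]$total_power_uv2, pp[[ph]]$total_power_uv2)
  }
})

test_that("generated recordings are deterministic with the requested shape", {
  prof <- phase_presets()$ISP
  r1 <- generate_recording(prof, duration_s = 30, seed = 5)
  r2 <- generate_recording(prof, duration_s = 30, seed = 5)
  expect_identical(r1$samples, r2$samples)
  expect_identical(length(r1$samples), 30000L)
  r3 <- generate_recording(prof, duration_s = 30, seed = 6)
  expect_false(identical(r1$samples, r3$samples))
  expect_error(generate_recording(prof, duration_s = 5), "at least 10")
})

test_that("generated variance matches the profile's total power", {
  prof <- phase_presets()$anesthetized
  rec <- generate_recording(prof, duration_s = 300, seed = 3)
  expect_equal(var(rec$samples), prof$total_power_uv2, tolerance = 0.05)
})

test_that("the pipeline recovers profile fractions within 0.02 on 5-min traces", {
  prof <- jitter_free(phase_presets()$ISP)
  rec <- generate_recording(prof, duration_s = 300, seed = 2)
  bp <- relative_bandpower(compute_psd(epoch_recording(highpass_filter(rec), 30)))
  est <- setNames(bp$rel_power, bp$band)
  expect_lt(max(abs(est[names(prof$fractions)] - prof$fractions)), 0.02)
})

test_that("cohort generation is reproducible, jitter-aware and complete", {
  design <- study_design(n_per_group = 2, phases = c("ISP", "IRP"), seed = 99)
  c1 <- generate_cohort(design)
  c2 <- generate_cohort(design)
  expect_identical(nrow(c1), 8L) # 2 groups x 2 animals x 2 phases
  expect_identical(purrr::map(c1$recording, "samples"),
                   purrr::map(c2$recording, "samples"))
  # sham animals draw from the control preset even in occlusion phases
  sham_isp <- c1$recording[[which(c1$group == "sham" & c1$phase == "ISP")[1]]]
  a <- analyze_recording(sham_isp)
  expect_lt(a$dar, 10) # anesthetized regime (DAR ~6.45), not ISP (~13)

  expect_error(study_design(n_per_group = 1), "at least 2")
  expect_error(study_design(phases = c("ISP", "D9")), "unknown")
})

test_that("sub-seed derivation is deterministic and spreads across cells", {
  s1 <- qeegstroke:::derive_seed(42, "mcao", 1, 3)
  s2 <- qeegstroke:::derive_seed(42, "mcao", 1, 3)
  s3 <- qeegstroke:::derive_seed(42, "mcao", 2, 3)
  s4 <- qeegstroke:::derive_seed(42, "sham", 1, 3)
  expect_identical(s1, s2)
  expect_gt(length(unique(c(s1, s3, s4))), 2)
  expect_true(s1 >= 0 && s1 < 2^31)
})

test_that("missing presets for a phase are an error", {
  design <- study_design(n_per_group = 2, phases = c("ISP", "D3"), seed = 1)
  pp <- phase_presets()
  pp$D3 <- NULL
  expect_error(generate_cohort(design, pp), "no preset")
})
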