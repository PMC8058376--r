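# Synthetic phase-labeled ECoG cohorts. Recordings are mixtures of
# band-limited Gaussian noise whose band-power composition is calibrated so
# that the analysis pipeline recovers prescribed spectral profiles; the
# acute-phase profiles are exact inversions of published index triples.

#' Invert an index triple into band-power fractions
#'
#' Given a (DTR, DAR, DTABR) triple, finds relative band-power fractions
#' whose forward indices reproduce the triple exactly. Setting alpha as the
#' unit, `delta = DAR`, `theta = DAR / DTR`, and
#' `beta = (delta + theta) / DTABR - 1`; the four values are then scaled to
#' sum to `1 - residual`. The triple is feasible iff the implied beta power
#' is positive.
#'
#' @param dtr,dar,dtabr Positive index values.
#' @param residual Fraction of reference power assigned to the 28--40 Hz
#'   residual band, in `[0, 1)`; default 0.05.
#' @return A named numeric vector of fractions
#'   `(delta, theta, alpha, beta, residual)` summing to one.
#' @examples
#' f <- invert_indices_to_fractions(1.62, 6.45, 4.95)
#' compute_indices(tibble::tibble(band = names(f), rel_power = f))
#' @export
invert_indices_to_fractions <- function(dtr, dar, dtabr, residual = 0.05) {
  dtr <- unname(dtr); dar <- unname(dar); dtabr <- unname(dtabr)
  if (any(c(dtr, dar, dtabr) <= 0)) stop("indices must be positive", call. = FALSE)
  if (residual < 0 || residual >= 1) stop("residual must lie in [0, 1)", call. = FALSE)
  d <- dar
  t <- dar / dtr
  a <- 1
  b <- (d + t) / dtabr - a
  if (b <= 0) {
    stop(sprintf(
      "infeasible index triple: DTABR = %g requires non-positive beta power given DTR = %g, DAR = %g",
      dtabr, dtr, dar), call. = FALSE)
  }
  v <- c(delta = d, theta = t, alpha = a, beta = b)
  v <- v / sum(v) * (1 - residual)
  c(v, residual = residual)
}

#' Construct a spectral profile
#'
#' The generator's ground truth for one phase: target relative band-power
#' fractions, total signal power, and the log-normal inter-animal jitter of
#' the fractions.
#'
#' @param fractions Named fractions over
#'   `delta, theta, alpha, beta, residual`, non-negative, summing to 1.
#' @param total_power_uv2 Target signal variance in microvolts squared.
#' @param jitter_sigma Standard deviation of the log-normal multiplicative
#'   jitter applied per animal to each fraction (then renormalized);
#'   0 disables jitter.
#' @param phase Phase label the profile describes.
#' @return A `spectral_profile` object.
#' @export
spectral_profile <- function(fractions, total_power_uv2 = 2000,
                             jitter_sigma = 0.1, phase = NA_character_) {
  need <- analysis_band_names()
  if (!all(need %in% names(fractions))) {
    stop("fractions must be named over ", paste(need, collapse = ", "), call. = FALSE)
  }
  fractions <- fractions[need]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (total_power_uv2 <= 0) stop("total_power_uv2 must be positive", call. = FALSE)
  if (jitter_sigma < 0) stop("jitter_sigma must be non-negative", call. = FALSE)
  structure(
    list(fractions = fractions, total_power_uv2 = total_power_uv2,
         jitter_sigma = jitter_sigma, phase = phase),
    class = "spectral_profile"
  )
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("<spectral_profile> phase %s, total %g uV^2, jitter %g\n",
              x$phase, x$total_power_uv2, x$jitter_sigma))
  print(round(x$fractions, 4))
  invisible(x)
}

# index triples (DTR, DAR, DTABR) behind the acute presets; the anesthetized
# recording is the control for the acute phases
acute_index_triples <- function() {
  list(
    anesthetized = c(dtr = 1.62, dar = 6.45, dtabr = 4.95),
    ISP = c(dtr = 4.20, dar = 13.07, dtabr = 8.68),
    IRP = c(dtr = 0.74, dar = 3.08, dtabr = 2.80)
  )
}

#' Per-phase spectral profiles of the study
#'
#' The generator's preset table, one [spectral_profile()] per phase:
#'
#' * Acute presets (`anesthetized`, `ISP`, `IRP`) are exact inversions of the
#'   published acute-phase index triples (residual fraction 0.05), so the
#'   pipeline should recover those index values from generated cohorts.
#' * `baseline_awake` is a plausible awake rodent composition (theta-rich).
#' * Subacute presets (`D1`--`D7`) are qualitative: all four canonical bands
#'   sit below the awake control trajectory (the residual band absorbs the
#'   deficit), with theta elevated on D3--D4, alpha elevated on D4/D6/D7, a
#'   DTABR trough on D1--D2 and peak on D3, and DTR/DAR peaks on D5.
#'
#' Total power is 2000 uV^2 anesthetized, doubled (4000) in immediate
#' reperfusion where absolute power rises sharply, and suppressed (1200) on
#' the subacute days. Absolute levels are placeholders: every downstream
#' index and relative power is insensitive to them.
#'
#' @param jitter_sigma Inter-animal fraction jitter applied to all presets
#'   (default 0.1).
#' @return A named list of [spectral_profile()]s keyed by phase, with a
#'   `version` attribute.
#' @seealso [write_preset_table()], [read_preset_table()]
#' @export
phase_presets <- function(jitter_sigma = 0.1) {
  acute <- acute_index_triples()
  subacute <- list(
    #        delta theta alpha  beta
    D1 = c(0.16, 0.15, 0.100, 0.110),
    D2 = c(0.17, 0.15, 0.100, 0.110),
    D3 = c(0.22, 0.20, 0.075, 0.095),
    D4 = c(0.23, 0.21, 0.130, 0.155),
    D5 = c(0.26, 0.13, 0.095, 0.135),
    D6 = c(0.25, 0.16, 0.140, 0.175),
    D7 = c(0.26, 0.16, 0.140, 0.170)
  )
  total <- c(baseline_awake = 1500, anesthetized = 2000, ISP = 1800, IRP = 4000,
             stats::setNames(rep(1200, 7), paste0("D", 1:7)))
  out <- list()
  out$baseline_awake <- spectral_profile(
    c(delta = 0.30, theta = 0.30, alpha = 0.17, beta = 0.18, residual = 0.05),
    total[["baseline_awake"]], jitter_sigma, "baseline_awake")
  for (ph in names(acute)) {
    tri <- acute[[ph]]
    out[[ph]] <- spectral_profile(
      invert_indices_to_fractions(tri["dtr"], tri["dar"], tri["dtabr"]),
      total[[ph]], jitter_sigma, ph)
  }
  for (ph in names(subacute)) {
    v <- subacute[[ph]]
    fr <- c(delta = v[1], theta = v[2], alpha = v[3], beta = v[4],
            residual = 1 - sum(v))
    names(fr) <- analysis_band_names()
    out[[ph]] <- spectral_profile(fr, total[[ph]], jitter_sigma, ph)
  }
  attr(out, "version") <- "1"
  out
}

#' Export / import the preset table as CSV
#'
#' Interchange format for the preset table:
#' `phase,delta,theta,alpha,beta,residual,total_power_uv2,jitter_sigma`.
#' Values are written at full float precision so a round trip preserves the
#' exact acute-phase calibration.
#'
#' @param presets A preset list from [phase_presets()].
#' @param path CSV path.
#' @return `write_preset_table()` the path invisibly; `read_preset_table()`
#'   a preset list.
#' @export
write_preset_table <- function(presets, path) {
  rows <- purrr::map_dfr(presets, function(p) {
    tibble::tibble(
      phase = p$phase, delta = p$fractions[["delta"]],
      theta = p$fractions[["theta"]], alpha = p$fractions[["alpha"]],
      beta = p$fractions[["beta"]], residual = p$fractions[["residual"]],
      total_power_uv2 = p$total_power_uv2, jitter_sigma = p$jitter_sigma
    )
  })
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_preset_table
#' @export
read_preset_table <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    phase = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  out <- lapply(seq_len(nrow(d)), function(i) {
    spectral_profile(
      c(delta = d$delta[i], theta = d$theta[i], alpha = d$alpha[i],
        beta = d$beta[i], residual = d$residual[i]),
      d$total_power_uv2[i], d$jitter_sigma[i], d$phase[i])
  })
  names(out) <- d$phase
  out
}

# ---- leakage-aware calibration -------------------------------------------

# Expected band-leakage matrix M[i, j]: the fraction of a unit-variance
# band-j noise component's power that the analysis pipeline measures in band
# i. Accounts for (a) the finite roll-off of the zero-phase Butterworth
# band filters (power response |H|^4) and (b) smearing by the Welch/Hann
# spectral window. Deterministic; cached per (rate, seg_s) pair.
leakage_cache <- new.env(parent = emptyenv())

leakage_matrix <- function(rate_hz = 1000, seg_s = 2, order = 4) {
  key <- paste(rate_hz, seg_s, order, sep = "|")
  if (!is.null(leakage_cache[[key]])) return(leakage_cache[[key]])
  bands <- qeeg_bands()
  bands <- bands[bands$band %in% analysis_band_names(), ]
  df <- 0.01
  fmax <- min(rate_hz / 2, 2 * max(bands$hi_hz))
  fgrid <- seq(0, fmax, by = df)
  nper <- as.integer(round(seg_s * rate_hz))
  win <- hann_window(nper)
  # Welch spectral window (squared magnitude of the window transform),
  # normalized to unit area
  offs <- seq(-4, 4, by = df)
  K <- vapply(offs, function(d) {
    Mod(sum(win * exp(-2i * pi * d * (0:(nper - 1)) / rate_hz)))^2
  }, numeric(1))
  K <- K / sum(K)
  bins <- seq(0, max(bands$hi_hz) + 4, by = rate_hz / nper)
  M <- matrix(0, nrow(bands), nrow(bands),
              dimnames = list(bands$band, bands$band))
  for (j in seq_len(nrow(bands))) {
    sos <- butter_sos(order, c(bands$lo_hz[j], bands$hi_hz[j]), rate_hz, "pass")
    S <- sos_response2(sos, fgrid, rate_hz)^2 # filtfilt: |H|^4
    S <- S / (sum(S) * df)                    # unit total variance
    # expected Welch density at each analysis bin
    Ew <- vapply(bins, function(fk) {
      idx <- as.integer(round((fk - offs) / df)) + 1L
      ok <- idx >= 1L & idx <= length(fgrid)
      sum(S[idx[ok]] * K[ok])
    }, numeric(1))
    for (i in seq_len(nrow(bands))) {
      sel <- bins >= bands$lo_hz[i] & bins < bands$hi_hz[i]
      M[i, j] <- sum(Ew[sel]) * rate_hz / nper
    }
  }
  leakage_cache[[key]] <- M
  M
}

# component variances w solving M w = target fractions, so the pipeline's
# measured relative band powers land on the target
calibrate_weights <- function(fractions, rate_hz, seg_s = 2) {
  M <- leakage_matrix(rate_hz, seg_s)
  w <- solve(M, fractions[analysis_band_names()])
  if (any(w < 0)) {
    stop("spectral profile infeasible for the band filters (negative component variance)",
         call. = FALSE)
  }
  w
}

#' Generate a synthetic ECoG recording from a spectral profile
#'
#' The trace is a sum of independent Gaussian noise components, one per
#' analysis band, each band-passed with a zero-phase 4th-order Butterworth
#' filter and scaled to a calibrated variance so that the analysis pipeline's
#' measured relative band powers reproduce the profile's target fractions
#' (the calibration solves a deterministic band-leakage system; see the
#' methods vignette). The full trace is then rescaled to the profile's total
#' power. Deterministic given the seed.
#'
#' @param profile A [spectral_profile()].
#' @param duration_s Recording length in seconds (>= 10).
#' @param rate_hz Sampling rate (default 1000 Hz; must exceed 80 Hz so the
#'   40 Hz ceiling is below Nyquist).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return A [recording()] with the profile's phase label.
#' @examples
#' prof <- phase_presets()$ISP
#' rec <- generate_recording(prof, duration_s = 60, seed = 1)
#' var(rec$samples) # ~ prof$total_power_uv2
#' @export
generate_recording <- function(profile, duration_s = 300, rate_hz = 1000,
                               seed = 1) {
  stopifnot(inherits(profile, "spectral_profile"))
  if (duration_s < 10) stop("duration_s must be at least 10 s", call. = FALSE)
  if (rate_hz < 80) stop("rate_hz must be at least 2 x 40 Hz", call. = FALSE)
  n <- as.integer(round(duration_s * rate_hz))
  w <- calibrate_weights(profile$fractions, rate_hz)
  bands <- qeeg_bands()
  x <- withr::with_seed(as.integer(seed), {
    acc <- numeric(n)
    for (b in analysis_band_names()) {
      lo <- bands$lo_hz[bands$band == b]
      hi <- bands$hi_hz[bands$band == b]
      sos <- butter_sos(4, c(lo, hi), rate_hz, "pass")
      # burn-in on both sides so the retained span is stationary band noise,
      # free of filter startup transients
      burn <- as.integer(ceiling(6 * sos_time_constant(sos)))
      u <- stats::rnorm(n + 2 * burn)
      y <- sos_filtfilt(sos, u)[(burn + 1):(burn + n)]
      acc <- acc + sqrt(w[[b]]) * (y / stats::sd(y))
    }
    acc
  })
  x <- x * sqrt(profile$total_power_uv2) / stats::sd(x)
  recording(x, rate_hz, phase = profile$phase)
}

# ---- cohorts --------------------------------------------------------------

#' Define a two-group study design
#'
#' @param n_per_group Animals per group (>= 2; the emulated study uses 6).
#' @param groups Group labels (default `sham`, `mcao`).
#' @param phases Ordered phase labels (default the full eleven-phase
#'   protocol from [phase_labels()]).
#' @param seed Master seed; per-animal, per-phase sub-seeds are derived from
#'   it deterministically, so a fixed seed yields a byte-identical cohort.
#' @return A `study_design` object.
#' @export
study_design <- function(n_per_group = 6, groups = c("sham", "mcao"),
                         phases = phase_labels()$phase, seed = 42) {
  if (n_per_group < 2) stop("n_per_group must be at least 2", call. = FALSE)
  if (length(phases) == 0) stop("phases must be non-empty", call. = FALSE)
  unknown <- setdiff(phases, phase_labels()$phase)
  if (length(unknown) > 0) {
    stop("unknown phase(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         phases = phases, seed = as.integer(seed)),
    class = "study_design"
  )
}

# Deterministic sub-seed: a splittable multiplicative hash of the master
# seed and the animal/phase coordinates, folded into [0, 2^31 - 2]. Uses
# double arithmetic below 2^53 so no integer overflow occurs.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    v <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.numeric(k)
    h <- (h * 48271 + v + 1) %% 2147483647
  }
  as.integer(h)
}

# phase -> preset lookup for one group; sham animals always receive the
# matching control preset (awake control for awake phases, anesthetized
# control for the anesthetized/occlusion/reperfusion window)
preset_for <- function(presets, group, phase) {
  key <- if (group == "sham") {
    if (phase %in% c("anesthetized", "ISP", "IRP")) "anesthetized" else "baseline_awake"
  } else {
    phase
  }
  p <- presets[[key]]
  if (is.null(p)) stop("no preset for phase '", key, "'", call. = FALSE)
  p
}

jitter_fractions <- function(fractions, sigma) {
  if (sigma == 0) return(fractions)
  f <- fractions * stats::rlnorm(length(fractions), 0, sigma)
  f / sum(f)
}

#' Generate a synthetic study cohort
#'
#' One recording per animal per phase. Each animal/phase cell gets a
#' deterministic sub-seed derived from the design's master seed; inter-animal
#' variability enters as log-normal multiplicative jitter of the preset
#' fractions (renormalized), drawn from the same sub-seeded stream as the
#' noise, so cohorts are reproducible and order-independent.
#'
#' @param design A [study_design()].
#' @param presets Named preset list from [phase_presets()] (or
#'   [read_preset_table()]).
#' @param rate_hz Sampling rate (default 1000 Hz).
#' @return A tibble with one row per recording: `animal`, `group`, `phase`,
#'   `seed`, and a `recording` list-column of [recording()] objects.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(study_design(n_per_group = 2, phases = c("ISP", "IRP")))
#' nrow(cohort) # 2 groups x 2 animals x 2 phases = 8
#' }
#' @export
generate_cohort <- function(design, presets = phase_presets(), rate_hz = 1000) {
  stopifnot(inherits(design, "study_design"))
  durations <- stats::setNames(phase_labels()$duration_s, phase_labels()$phase)
  grid <- tidyr::expand_grid(
    group = design$groups,
    animal_idx = seq_len(design$n_per_group),
    phase = design$phases
  )
  rows <- purrr::pmap(grid, function(group, animal_idx, phase) {
    prof <- preset_for(presets, group, phase)
    sub <- derive_seed(design$seed, group, animal_idx, match(phase, design$phases))
    jfrac <- withr::with_seed(sub, jitter_fractions(prof$fractions, prof$jitter_sigma))
    jprof <- spectral_profile(jfrac, prof$total_power_uv2, prof$jitter_sigma, phase)
    rec <- generate_recording(jprof, durations[[phase]], rate_hz,
                              seed = derive_seed(sub, "trace"))
    rec$animal_id <- sprintf("%s_%02d", group, animal_idx)
    rec$group <- group
    tibble::tibble(animal = rec$animal_id, group = group, phase = phase,
                   seed = sub, recording = list(rec))
  })
  dplyr::bind_rows(rows)
}
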