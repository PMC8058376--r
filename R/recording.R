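#' Construct a single-channel ECoG recording
#'
#' The raw unit of analysis: a uniformly sampled voltage trace (microvolts)
#' with its sampling rate and study metadata (animal, group, experimental
#' phase, session clock offset). Recordings are collected continuously at
#' 1 kHz in the emulated acquisition setup, but any positive rate is accepted.
#'
#' @param samples Numeric vector of voltages in microvolts. Must be non-empty
#'   and finite.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param animal_id Animal label, e.g. `"mcao_01"`.
#' @param group Experimental group, `"sham"` or `"mcao"` (free-form labels are
#'   accepted but the standard study design uses these two).
#' @param phase Phase label, one of [phase_labels()] or `NA`.
#' @param start_s Session clock offset in seconds from phase onset.
#' @return An object of class `qeeg_recording`.
#' @seealso [read_recording()], [validate_recording()], [generate_recording()]
#' @examples
#' rec <- recording(sin(2 * pi * 10 * seq(0, 1, by = 1e-3)), rate_hz = 1000)
#' rec
#' @export
recording <- function(samples, rate_hz, animal_id = NA_character_,
                      group = NA_character_, phase = NA_character_,
                      start_s = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  if (!all(is.finite(samples))) stop("samples must all be finite", call. = FALSE)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0) {
    stop("rate_hz must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      samples = samples, rate_hz = as.numeric(rate_hz),
      animal_id = as.character(animal_id), group = as.character(group),
      phase = as.character(phase), start_s = as.numeric(start_s)
    ),
    class = "qeeg_recording"
  )
}

#' @export
print.qeeg_recording <- function(x, ...) {
  cat(sprintf(
    "<qeeg_recording> %d samples @ %g Hz (%.1f s)\n  animal: %s  group: %s  phase: %s  start_s: %g\n",
    length(x$samples), x$rate_hz, duration_s(x),
    x$animal_id, x$group, x$phase, x$start_s
  ))
  invisible(x)
}

duration_s <- function(rec) length(rec$samples) / rec$rate_hz

#' Phase labels and nominal durations of the study design
#'
#' The monitoring protocol has eleven phases: an awake baseline and an
#' anesthetized control recording (10 min each), the ischemic stroke phase
#' (ISP, the last 5 min of the occlusion), the immediate reperfusion phase
#' (IRP, the first 10 min of reperfusion), and one 5-min awake session per
#' day for seven days (D1--D7).
#'
#' @return A tibble with columns `phase` and `duration_s`.
#' @examples
#' phase_labels()
#' @export
phase_labels <- function() {
  tibble::tibble(
    phase = c("baseline_awake", "anesthetized", "ISP", "IRP", paste0("D", 1:7)),
    duration_s = c(600, 600, 300, 600, rep(300, 7))
  )
}

#' Validate a recording against its contract
#'
#' Pure reporting operation: checks that all samples are finite, that the
#' phase label is known, and that the recording length matches the phase's
#' nominal duration. The recording is never modified.
#'
#' @param rec A [recording()].
#' @param duration_tol_s Allowed absolute deviation from the nominal phase
#'   duration in seconds before a duration-mismatch violation is reported.
#' @return A tibble of violations with columns `check` and `message`;
#'   zero rows means the recording is valid.
#' @examples
#' rec <- recording(rnorm(300000), 1000, phase = "ISP")
#' validate_recording(rec) # no violations
#' @export
validate_recording <- function(rec, duration_tol_s = 1) {
  stopifnot(inherits(rec, "qeeg_recording"))
  bad <- list()
  if (!all(is.finite(rec$samples))) {
    bad <- c(bad, list(c("finite_samples",
                         sprintf("%d non-finite sample(s)", sum(!is.finite(rec$samples))))))
  }
  known <- phase_labels()
  if (!is.na(rec$phase)) {
    if (!rec$phase %in% known$phase) {
      bad <- c(bad, list(c("known_phase", sprintf("unknown phase '%s'", rec$phase))))
    } else {
      nominal <- known$duration_s[known$phase == rec$phase]
      if (abs(duration_s(rec) - nominal) > duration_tol_s) {
        bad <- c(bad, list(c("phase_duration",
                             sprintf("duration %.1f s does not match nominal %g s for phase %s",
                                     duration_s(rec), nominal, rec$phase))))
      }
    }
  }
  if (length(bad) == 0) {
    tibble::tibble(check = character(), message = character())
  } else {
    tibble::tibble(
      check = vapply(bad, `[`, "", 1),
      message = vapply(bad, `[`, "", 2)
    )
  }
}
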