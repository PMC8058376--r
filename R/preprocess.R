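# Conditioning of raw recordings before spectral analysis: zero-phase
# high-pass filtering (replicating the 0.3 Hz acquisition high-pass
# digitally), epoching into equal windows, and amplitude-based artifact
# rejection. No notch filter is applied: mains frequency lies above the
# 40 Hz analysis ceiling.

#' Zero-phase high-pass filter a recording
#'
#' Applies a 4th-order Butterworth high-pass forward and backward (zero phase,
#' so band-power estimates are unaffected by filter delay), with
#' odd-reflection padding of six filter time constants to suppress edge
#' transients. Removes the DC component.
#'
#' @param rec A [recording()].
#' @param cutoff_hz High-pass corner frequency in Hz; default 0.3 Hz, the
#'   acquisition hardware high-pass. Must lie below the Nyquist frequency.
#' @param order Filter order (default 4).
#' @return A filtered [recording()] of the same length and metadata.
#' @examples
#' rec <- recording(10 + rnorm(5000), 1000)
#' filt <- highpass_filter(rec)
#' mean(filt$samples) # ~0: DC removed
#' @export
highpass_filter <- function(rec, cutoff_hz = 0.3, order = 4) {
  stopifnot(inherits(rec, "qeeg_recording"))
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1 || cutoff_hz <= 0 ||
      cutoff_hz >= rec$rate_hz / 2) {
    stop("cutoff_hz must lie in (0, rate_hz / 2)", call. = FALSE)
  }
  sos <- butter_sos(order, cutoff_hz, rec$rate_hz, "high")
  rec$samples <- sos_filtfilt(sos, rec$samples)
  rec
}

#' Split a recording into non-overlapping epochs
#'
#' Consecutive equal-length windows; a trailing partial window is dropped.
#' All epochs start out accepted.
#'
#' @param rec A [recording()].
#' @param epoch_s Epoch length in seconds (default 30 s: ten epochs per 5-min
#'   session, enough for spectral averaging while keeping artifacts isolated).
#' @return A `qeeg_epochs` object: epochs stored as rows of a matrix, with a
#'   logical `keep` flag per epoch and the source recording's metadata.
#' @examples
#' es <- epoch_recording(recording(rnorm(300000), 1000, phase = "ISP"))
#' nrow(es$epochs) # 10
#' @export
epoch_recording <- function(rec, epoch_s = 30) {
  stopifnot(inherits(rec, "qeeg_recording"))
  if (!is.numeric(epoch_s) || length(epoch_s) != 1 || epoch_s <= 0) {
    stop("epoch_s must be a single positive duration", call. = FALSE)
  }
  len <- as.integer(round(epoch_s * rec$rate_hz))
  n_ep <- length(rec$samples) %/% len
  if (n_ep < 1) {
    stop(sprintf("recording (%.1f s) shorter than one epoch (%g s)",
                 duration_s(rec), epoch_s), call. = FALSE)
  }
  m <- matrix(rec$samples[seq_len(n_ep * len)], nrow = n_ep, byrow = TRUE)
  structure(
    list(
      epochs = m, epoch_s = epoch_s, rate_hz = rec$rate_hz,
      keep = rep(TRUE, n_ep),
      meta = rec[c("animal_id", "group", "phase", "start_s")]
    ),
    class = "qeeg_epochs"
  )
}

#' @export
print.qeeg_epochs <- function(x, ...) {
  cat(sprintf("<qeeg_epochs> %d x %g s epochs @ %g Hz (%d kept)\n",
              nrow(x$epochs), x$epoch_s, x$rate_hz, sum(x$keep)))
  invisible(x)
}

#' Flag artifact-contaminated epochs by amplitude threshold
#'
#' Epochs containing any sample exceeding the absolute amplitude threshold
#' are flagged rejected. Sample values are never modified, only the keep
#' mask. The rejected fraction is reported via `message()`when any epoch
#' is dropped.
#'
#' @param es A `qeeg_epochs` object from [epoch_recording()].
#' @param amp_threshold_uv Absolute amplitude bound in microvolts
#'   (default 500, a typical rodent ECoG artifact bound).
#' @return The epoch set with an updated `keep` mask.
#' @examples
#' es <- epoch_recording(recording(rnorm(60000), 1000), epoch_s = 10)
#' es$epochs[2, 100] <- 1000
#' sum(reject_artifacts(es)$keep) # 5: the spiked epoch is dropped
#' @export
reject_artifacts <- function(es, amp_threshold_uv = 500) {
  stopifnot(inherits(es, "qeeg_epochs"))
  if (!is.numeric(amp_threshold_uv) || amp_threshold_uv <= 0) {
    stop("amp_threshold_uv must be positive", call. = FALSE)
  }
  peak <- apply(abs(es$epochs), 1, max)
  newly <- es$keep & (peak > amp_threshold_uv)
  es$keep <- es$keep & (peak <= amp_threshold_uv)
  if (!any(es$keep)) {
    stop(sprintf("all %d epochs exceed %g uV: nothing left to analyze",
                 nrow(es$epochs), amp_threshold_uv), call. = FALSE)
  }
  if (any(newly)) {
    message(sprintf("rejected %d/%d epochs (%.0f%%) above %g uV",
                    sum(newly), nrow(es$epochs),
                    100 * sum(newly) / nrow(es$epochs), amp_threshold_uv))
  }
  es
}
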