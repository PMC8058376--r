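# Welch power spectral density estimation and band-power decomposition.
# One PSD per recording session (all kept epochs pooled) is the unit of
# analysis; band powers are rectangle sums over half-open frequency bands,
# and relative powers are fractions of the 1-40 Hz reference band.

#' Welch power spectral density of an epoch set
#'
#' Averages Hann-windowed, overlapping periodogram segments across all kept
#' epochs (segments never straddle epoch boundaries). The one-sided density
#' is normalized so that `sum(psd) * resolution_hz` over the full grid equals
#' the signal variance (Parseval, within windowing tolerance).
#'
#' @param es A `qeeg_epochs` object from [epoch_recording()] (or a
#'   [recording()], which is treated as a single epoch).
#' @param seg_s Welch segment length in seconds; default 2 s, giving the
#'   0.5 Hz resolution needed to resolve the 1 Hz delta band edge.
#' @param overlap_frac Fractional overlap of consecutive segments in
#'   `[0, 1)`; default 0.5.
#' @param max_resolution_hz Coarsest admissible grid spacing; `seg_s` shorter
#'   than `1 / max_resolution_hz` is a parameter error.
#' @return A `qeeg_psd` object: a tibble with columns `freq_hz` and `psd`
#'   (microvolts squared per Hz), with attributes `rate_hz`, `resolution_hz`,
#'   `n_segments` and the source metadata.
#' @examples
#' es <- epoch_recording(recording(rnorm(60000), 1000), epoch_s = 10)
#' ps <- compute_psd(es)
#' sum(ps$psd) * attr(ps, "resolution_hz") # ~1: variance of white noise
#' @export
compute_psd <- function(es, seg_s = 2, overlap_frac = 0.5,
                        max_resolution_hz = 0.5) {
  if (inherits(es, "qeeg_recording")) {
    es <- epoch_recording(es, epoch_s = duration_s(es))
  }
  stopifnot(inherits(es, "qeeg_epochs"))
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("overlap_frac must lie in [0, 1)", call. = FALSE)
  }
  if (1 / seg_s > max_resolution_hz + 1e-12) {
    stop(sprintf(
      "seg_s = %g s gives %.2f Hz resolution; need <= %.2f Hz to resolve the band edges",
      seg_s, 1 / seg_s, max_resolution_hz), call. = FALSE)
  }
  rate <- es$rate_hz
  nper <- as.integer(round(seg_s * rate))
  if (nper > ncol(es$epochs)) {
    stop("seg_s exceeds the epoch length", call. = FALSE)
  }
  win <- hann_window(nper)
  step <- max(1L, as.integer(round(nper * (1 - overlap_frac))))
  norm <- rate * sum(win^2)
  n_freq <- nper %/% 2 + 1
  acc <- numeric(n_freq)
  n_seg <- 0L
  for (e in which(es$keep)) {
    x <- es$epochs[e, ]
    starts <- seq(1L, ncol(es$epochs) - nper + 1L, by = step)
    for (s in starts) {
      X <- stats::fft(x[s:(s + nper - 1L)] * win)
      acc <- acc + (Mod(X[seq_len(n_freq)])^2) / norm
      n_seg <- n_seg + 1L
    }
  }
  psd <- acc / n_seg
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- 2:(if (nper %% 2 == 0) n_freq - 1 else n_freq)
  psd[dbl] <- 2 * psd[dbl]
  out <- tibble::tibble(freq_hz = (seq_len(n_freq) - 1) * rate / nper, psd = psd)
  structure(
    out,
    class = c("qeeg_psd", class(out)),
    rate_hz = rate, resolution_hz = rate / nper, n_segments = n_seg,
    meta = es$meta
  )
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

psd_resolution <- function(ps) attr(ps, "resolution_hz")

#' Absolute power in a frequency band
#'
#' Rectangle-rule integral of the PSD over grid points with
#' `lo_hz <= f < hi_hz` (half-open, so adjacent bands never double-count a
#' bin).
#'
#' @param ps A `qeeg_psd` from [compute_psd()].
#' @param band A band name from [qeeg_bands()] or a numeric `c(lo_hz, hi_hz)`.
#' @return Absolute power in microvolts squared.
#' @examples
#' ps <- compute_psd(epoch_recording(recording(rnorm(30000), 1000), 10))
#' band_power(ps, "delta")
#' @export
band_power <- function(ps, band) {
  stopifnot(inherits(ps, "qeeg_psd"))
  edges <- resolve_band(band)
  nyq <- attr(ps, "rate_hz") / 2
  if (edges[1] < 0 || edges[2] > nyq + 1e-9) {
    stop(sprintf("band [%g, %g) outside the spectrum's [0, %g] Hz grid",
                 edges[1], edges[2], nyq), call. = FALSE)
  }
  sel <- ps$freq_hz >= edges[1] & ps$freq_hz < edges[2]
  sum(ps$psd[sel]) * psd_resolution(ps)
}

#' Absolute and relative band power in the canonical bands
#'
#' Computes absolute power in delta, theta, alpha, beta and residual
#' (28--40 Hz), plus the reference band (1--40 Hz), and expresses each band
#' as a fraction of reference power. The five disjoint band powers sum to the
#' reference power exactly (same grid, half-open edges), so the relative
#' fractions sum to one.
#'
#' @param ps A `qeeg_psd` from [compute_psd()].
#' @return A `qeeg_bandpower` tibble with columns `band`, `lo_hz`, `hi_hz`,
#'   `abs_power`, `rel_power`, and attribute `reference_power`.
#' @examples
#' ps <- compute_psd(epoch_recording(recording(rnorm(30000), 1000), 10))
#' relative_bandpower(ps)
#' @export
relative_bandpower <- function(ps) {
  stopifnot(inherits(ps, "qeeg_psd"))
  bands <- qeeg_bands()
  bands <- bands[bands$band %in% analysis_band_names(), ]
  absp <- vapply(bands$band, function(b) band_power(ps, b), numeric(1))
  ref <- sum(absp)
  if (ref <= 0) {
    stop("zero power in the 1-40 Hz reference band: degenerate input", call. = FALSE)
  }
  out <- tibble::tibble(
    band = bands$band, lo_hz = bands$lo_hz, hi_hz = bands$hi_hz,
    abs_power = unname(absp), rel_power = unname(absp) / ref
  )
  structure(out, class = c("qeeg_bandpower", class(out)),
            reference_power = ref, meta = attr(ps, "meta"))
}

#' Restrict a PSD to the analysis ceiling for reporting
#'
#' @param ps A `qeeg_psd`.
#' @param max_hz Upper frequency bound (exclusive); must not exceed Nyquist.
#' @return A plain tibble `freq_hz`, `psd` restricted to `[0, max_hz)`.
#' @export
frequency_distribution <- function(ps, max_hz = 40) {
  stopifnot(inherits(ps, "qeeg_psd"))
  if (max_hz > attr(ps, "rate_hz") / 2 + 1e-9) {
    stop("max_hz exceeds the Nyquist frequency", call. = FALSE)
  }
  tibble::tibble(freq_hz = ps$freq_hz[ps$freq_hz < max_hz],
                 psd = ps$psd[ps$freq_hz < max_hz])
}
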