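# Butterworth design in zero-pole-gain form with second-order-section
# filtering. Transfer-function-form designs are numerically unstable for
# narrow low-frequency bands relative to the sampling rate (e.g. a 1-4 Hz
# bandpass at 1 kHz), so the design is done on poles and zeros and the
# filtering cascaded through biquads, each of which is well conditioned.
# The recursive part of each biquad runs through stats::filter's C loop.

# analog Butterworth prototype poles (unit cutoff, gain 1, no zeros)
butter_prototype <- function(order) {
  m <- seq(-order + 1, order - 1, by = 2)
  -exp(1i * pi * m / (2 * order))
}

#' Design a digital Butterworth filter as second-order sections
#'
#' Designs a low-pass, high-pass or band-pass Butterworth filter by bilinear
#' transform of the analog prototype (with frequency pre-warping) and returns
#' the cascade as a matrix of second-order sections, one row per biquad
#' (`b0 b1 b2 a0 a1 a2`). The overall gain is folded into the first section.
#'
#' @param order Filter order (the band-pass realization has `2 * order` poles).
#' @param w_hz Corner frequency in Hz (scalar for `low`/`high`, length-2
#'   `c(lo, hi)` for `pass`).
#' @param rate_hz Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"pass"`.
#' @return Numeric matrix with 6 columns, one biquad per row.
#' @keywords internal
butter_sos <- function(order, w_hz, rate_hz, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  stopifnot(order >= 1, rate_hz > 0, all(w_hz > 0), all(w_hz < rate_hz / 2))
  p <- butter_prototype(order)
  z <- complex(0)
  warp <- function(f) 2 * rate_hz * tan(pi * f / rate_hz)
  if (type == "low") {
    wo <- warp(w_hz)
    p <- p * wo
    k <- wo^order
  } else if (type == "high") {
    wo <- warp(w_hz)
    p <- wo / p
    z <- rep(0 + 0i, order)
    k <- 1 # Butterworth denominator has unit constant term
  } else {
    if (length(w_hz) != 2 || w_hz[1] >= w_hz[2]) {
      stop("band-pass design needs w_hz = c(lo, hi) with lo < hi", call. = FALSE)
    }
    w1 <- warp(w_hz[1]); w2 <- warp(w_hz[2])
    wo <- sqrt(w1 * w2); bw <- w2 - w1
    plp <- p * bw / 2
    p <- c(plp + sqrt(plp^2 - wo^2), plp - sqrt(plp^2 - wo^2))
    z <- rep(0 + 0i, order)
    k <- bw^order
  }
  # bilinear transform
  fs2 <- 2 * rate_hz
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c((fs2 + z) / (fs2 - z), rep(-1 + 0i, length(p) - length(z)))
  pd <- (fs2 + p) / (fs2 - p)
  zpk_to_sos(zd, pd, kd)
}

# Pair poles (closest to the unit circle first) with their conjugates and the
# nearest remaining zeros; each pair becomes one biquad.
zpk_to_sos <- function(z, p, k) {
  stopifnot(length(z) == length(p), length(p) %% 2 == 0)
  p <- p[order(-Mod(p))]
  used_p <- logical(length(p))
  used_z <- logical(length(z))
  sos <- matrix(0, nrow = length(p) / 2, ncol = 6)
  for (s in seq_len(nrow(sos))) {
    i <- which(!used_p)[1]
    used_p[i] <- TRUE
    if (abs(Im(p[i])) > 1e-10) {
      j <- which(!used_p & abs(p - Conj(p[i])) < 1e-6 * (1 + Mod(p[i])))[1]
    } else {
      cand <- which(!used_p & abs(Im(p)) <= 1e-10)
      j <- cand[which.min(abs(p[cand] - p[i]))]
    }
    if (is.na(j)) stop("internal error: could not pair poles into biquads")
    used_p[j] <- TRUE
    pp <- c(p[i], p[j])
    zz <- complex(2)
    for (r in 1:2) {
      cand <- which(!used_z)
      kk <- cand[which.min(abs(z[cand] - pp[r]))]
      used_z[kk] <- TRUE
      zz[r] <- z[kk]
    }
    b <- Re(c(1, -(zz[1] + zz[2]), zz[1] * zz[2]))
    a <- Re(c(1, -(pp[1] + pp[2]), pp[1] * pp[2]))
    sos[s, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

# forward filtering through the biquad cascade (zero initial conditions);
# FIR part vectorized, IIR part via stats::filter(method = "recursive")
sos_filter <- function(sos, x) {
  n <- length(x)
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    v <- b[1] * x
    if (n > 1) v[2:n] <- v[2:n] + b[2] * x[1:(n - 1)]
    if (n > 2) v[3:n] <- v[3:n] + b[3] * x[1:(n - 2)]
    x <- as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
  }
  x
}

# Zero-phase forward-backward filtering with odd-reflection padding. The
# default pad covers six time constants of the filter's slowest pole, so
# startup transients decay below ~0.3% before the retained span begins.
sos_filtfilt <- function(sos, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 6 * sos_time_constant(sos)
  padlen <- max(1L, min(as.integer(ceiling(padlen)), n - 1L))
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  y <- c(pre, x, post)
  y <- sos_filter(sos, y)
  y <- rev(sos_filter(sos, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

# impulse-response time constant (samples) of the slowest pole in the cascade
sos_time_constant <- function(sos) {
  r <- 0
  for (s in seq_len(nrow(sos))) {
    r <- max(r, Mod(polyroot(rev(sos[s, 4:6]))))
  }
  if (r >= 1) stop("unstable filter section", call. = FALSE)
  -1 / log(r)
}

# squared magnitude response |H(f)|^2 of a biquad cascade
sos_response2 <- function(sos, freq_hz, rate_hz) {
  w <- 2 * pi * freq_hz / rate_hz
  e1 <- exp(-1i * w); e2 <- exp(-2i * w)
  H <- rep(1 + 0i, length(w))
  for (s in seq_len(nrow(sos))) {
    H <- H * (sos[s, 1] + sos[s, 2] * e1 + sos[s, 3] * e2) /
      (sos[s, 4] + sos[s, 5] * e1 + sos[s, 6] * e2)
  }
  Mod(H)^2
}
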