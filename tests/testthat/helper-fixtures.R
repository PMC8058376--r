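# Shared fixtures: short deterministic signals built in code.

sine_recording <- function(freq_hz, duration_s = 10, rate_hz = 1000,
                           amplitude = 1, ...) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  recording(amplitude * sin(2 * pi * freq_hz * t), rate_hz, ...)
}

noise_recording <- function(duration_s = 60, rate_hz = 1000, sd = 1,
                            seed = 1, ...) {
  withr::with_seed(seed, recording(rnorm(duration_s * rate_hz, sd = sd),
                                   rate_hz, ...))
}

# three-group data with prescribed means and a fixed zero-mean, unit-variance
# within-group pattern, so Tukey outcomes are deterministic
letter_chain_data <- function(means = c(a = 0, b = 1.5, c = 3)) {
  pattern <- c(-1, 0, 1)
  tibble::tibble(
    g = rep(names(means), each = length(pattern)),
    y = rep(unname(means), each = length(pattern)) + rep(pattern, length(means))
  )
}

jitter_free <- function(profile) {
  profile$jitter_sigma <- 0
  profile
}
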