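#' Canonical qEEG frequency bands
#'
#' The analysis decomposes ECoG power into four canonical bands --- delta
#' (1--4 Hz), theta (4--8 Hz), alpha (8--12 Hz) and beta (12--28 Hz) --- up to
#' an analysis ceiling of 40 Hz. Power between 28 and 40 Hz is tracked as the
#' `residual` band so that the five disjoint bands tile the `reference` band
#' (1--40 Hz) exactly; relative band powers are fractions of reference-band
#' power and sum to one. Band edges are half-open `[lo, hi)` so each spectral
#' bin is counted exactly once.
#'
#' @return A tibble with columns `band`, `lo_hz`, `hi_hz`. The `reference`
#'   band row is included last.
#' @examples
#' qeeg_bands()
#' @export
qeeg_bands <- function() {
  tibble::tibble(
    band  = c("delta", "theta", "alpha", "beta", "residual", "reference"),
    lo_hz = c(1, 4, 8, 12, 28, 1),
    hi_hz = c(4, 8, 12, 28, 40, 40)
  )
}

# five disjoint analysis bands (excludes the reference envelope)
analysis_band_names <- function() c("delta", "theta", "alpha", "beta", "residual")

# look up band edges; band may be a name or a numeric c(lo, hi)
resolve_band <- function(band) {
  if (is.character(band)) {
    tbl <- qeeg_bands()
    row <- tbl[tbl$band == band, ]
    if (nrow(row) != 1) {
      stop("unknown band '", band, "'; known bands: ",
           paste(tbl$band, collapse = ", "), call. = FALSE)
    }
    c(row$lo_hz, row$hi_hz)
  } else if (is.numeric(band) && length(band) == 2) {
    if (band[1] >= band[2]) stop("band lower edge must be below upper edge", call. = FALSE)
    as.numeric(band)
  } else {
    stop("band must be a band name or a numeric c(lo_hz, hi_hz)", call. = FALSE)
  }
}
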