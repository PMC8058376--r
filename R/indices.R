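# The three qEEG stroke-severity indices. Because all three are ratios of
# band powers they are identical whether computed from absolute or relative
# powers, and invariant to overall signal amplitude.

#' Compute the DTR, DAR and DTABR indices from band powers
#'
#' * DTR = delta / theta
#' * DAR = delta / alpha
#' * DTABR = (delta + theta) / (alpha + beta)
#'
#' @param bp A `qeeg_bandpower` tibble from [relative_bandpower()], or any
#'   data frame with columns `band` and `rel_power` (or `abs_power`) covering
#'   delta, theta, alpha and beta.
#' @return A one-row tibble with columns `dtr`, `dar`, `dtabr` (plus any
#'   source metadata carried on the band-power object).
#' @examples
#' bp <- tibble::tibble(band = c("delta", "theta", "alpha", "beta"),
#'                      rel_power = c(0.4, 0.2, 0.2, 0.2))
#' compute_indices(bp) # dtr 2, dar 2, dtabr 1.5
#' @export
compute_indices <- function(bp) {
  stopifnot(is.data.frame(bp), "band" %in% names(bp))
  col <- if ("rel_power" %in% names(bp)) "rel_power" else "abs_power"
  if (!col %in% names(bp)) stop("need a rel_power or abs_power column", call. = FALSE)
  p <- function(b) {
    v <- bp[[col]][bp$band == b]
    if (length(v) != 1 || is.na(v)) stop("missing band power for '", b, "'", call. = FALSE)
    v
  }
  d <- p("delta"); t <- p("theta"); a <- p("alpha"); b <- p("beta")
  for (nm in c("theta", "alpha")) {
    if (p(nm) <= 0) stop("zero power in denominator band '", nm, "'", call. = FALSE)
  }
  if (a + b <= 0) stop("zero power in denominator bands 'alpha + beta'", call. = FALSE)
  tibble::tibble(dtr = d / t, dar = d / a, dtabr = (d + t) / (a + b))
}

#' Classify ischemic state from the qEEG indices
#'
#' Applies the published exceedance thresholds: DAR above 3.7 discriminates
#' acute ischemic stroke, and DTABR above 3.5 indicates ischemic injury with
#' reported 100% sensitivity. The comparison is strictly greater-than, so a
#' value exactly at the threshold is not flagged.
#'
#' @param qi A data frame with columns `dar` and `dtabr` (e.g. from
#'   [compute_indices()]); extra columns pass through.
#' @param dar_threshold,dtabr_threshold Positive exceedance thresholds
#'   (defaults 3.7 and 3.5).
#' @return `qi` with logical columns `dar_ischemic` and `dtabr_ischemic`
#'   appended.
#' @examples
#' classify_ischemia(tibble::tibble(dar = c(13.07, 3.08), dtabr = c(8.68, 2.80)))
#' @export
classify_ischemia <- function(qi, dar_threshold = 3.7, dtabr_threshold = 3.5) {
  stopifnot(is.data.frame(qi), all(c("dar", "dtabr") %in% names(qi)))
  if (dar_threshold <= 0 || dtabr_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  dplyr::mutate(qi,
    dar_ischemic = .data$dar > dar_threshold,
    dtabr_ischemic = .data$dtabr > dtabr_threshold
  )
}
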