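# ggplot2 views of the result objects: spectral curves, band-power bars and
# index trajectories.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power spectral density
#'
#' @param object A `qeeg_psd` from [compute_psd()].
#' @param max_hz Upper frequency limit (default the 40 Hz analysis ceiling).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qeeg_psd <- function(object, max_hz = 40, ...) {
  d <- frequency_distribution(object, max_hz)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq_hz, y = .data$psd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)",
                  y = expression(PSD ~ (mu * V^2 / Hz))) +
    ggplot2::theme_minimal()
}

#' Bar chart of relative band power
#'
#' @param bp A `qeeg_bandpower` from [relative_bandpower()], or a long table
#'   with columns `band` and `rel_power` (optionally `phase` for faceting).
#' @return A ggplot.
#' @export
plot_band_powers <- function(bp) {
  bp <- dplyr::mutate(bp, band = factor(.data$band, analysis_band_names()))
  p <- ggplot2::ggplot(bp, ggplot2::aes(x = .data$band, y = .data$rel_power)) +
    ggplot2::labs(x = NULL, y = "relative band power") +
    ggplot2::theme_minimal()
  if ("phase" %in% names(bp) && dplyr::n_distinct(bp$phase) > 1) {
    p <- p +
      ggplot2::stat_summary(fun = mean, geom = "col") +
      ggplot2::facet_wrap(~phase)
  } else {
    p <- p + ggplot2::geom_col()
  }
  p
}

#' Index trajectories across phases
#'
#' @param idx Long or wide index table with a `phase` column and `dtr`,
#'   `dar`, `dtabr` columns (e.g. the `indices` table from [run_analyze()]).
#' @param thresholds Named vector of horizontal reference lines
#'   (default `c(dar = 3.7, dtabr = 3.5)`).
#' @return A ggplot with one facet per index; points are per-animal sessions,
#'   the line tracks the phase mean.
#' @export
plot_indices <- function(idx, thresholds = c(dar = 3.7, dtabr = 3.5)) {
  stopifnot(all(c("phase", "dtr", "dar", "dtabr") %in% names(idx)))
  long <- tidyr::pivot_longer(idx, c("dtr", "dar", "dtabr"),
                              names_to = "index", values_to = "value")
  long$phase <- factor(long$phase, levels = intersect(phase_labels()$phase,
                                                      unique(long$phase)))
  thr <- tibble::tibble(index = names(thresholds), value = unname(thresholds))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean, geom = "line") +
    ggplot2::geom_hline(data = thr, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "index value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
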