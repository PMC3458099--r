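#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an epoch set
#'
#' Trial butterfly plot per channel with the trial average overlaid.
#'
#' @param object An [epoch_set()].
#' @param max_trials Trials drawn individually (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epoch_set <- function(object, max_trials = 20, ...) {
  d <- tibble::as_tibble(object)
  keep <- utils::head(unique(d$trial), max_trials)
  avg <- dplyr::summarise(dplyr::group_by(d, channel, time),
                          value = mean(value), .groups = "drop")
  ggplot2::ggplot(d[d$trial %in% keep, ],
                  ggplot2::aes(time, value, group = trial)) +
    ggplot2::geom_line(alpha = 0.2, linewidth = 0.2) +
    ggplot2::geom_line(data = avg, ggplot2::aes(group = NULL),
                       colour = "firebrick", linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = expression(paste("potential (", mu, "V)")))
}

#' Plot per-IMF response summaries
#'
#' Faceted time courses of the evoked response, induced amplitude,
#' phase-locking value and instantaneous frequency, one row per ordinal IMF,
#' with the baseline frequency band overlaid on the frequency panel.
#'
#' @param object An `imf_summary` from [summarize_imfs()].
#' @param measures Which measures to draw (default all four).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imf_summary <- function(object,
                                 measures = c("evoked", "induced", "plv",
                                              "frequency"),
                                 ...) {
  long <- tidyr::pivot_longer(object$timecourse,
                              dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  band <- tidyr::crossing(object$baseline, measure = "frequency")
  ggplot2::ggplot(long, ggplot2::aes(time, value)) +
    ggplot2::geom_rect(data = band,
                       ggplot2::aes(xmin = -Inf, xmax = Inf,
                                    ymin = ci_lo, ymax = ci_hi),
                       inherit.aes = FALSE, alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::facet_grid(imf ~ measure, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot a Welch power spectral density estimate
#'
#' @param object A `psd_estimate` from [welch_psd()].
#' @param log_power Draw power on a log10 axis (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psd_estimate <- function(object, log_power = TRUE, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(frequency, power, colour = channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)",
                  y = expression(paste("power (", mu, V^2, "/Hz)")))
  if (log_power) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a discrimination report
#'
#' Per-IMF frequency time courses of the two simulated datasets with their
#' baseline 95% confidence bands: phase-aligned data leave the band
#' (dip then rebound), additively evoked data stay inside it.
#'
#' @param object A `discrimination_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.discrimination_report <- function(object, ...) {
  tc <- purrr::imap_dfr(object$summaries, function(s, nm) {
    dplyr::mutate(s$timecourse, dataset = nm)
  })
  band <- purrr::imap_dfr(object$summaries, function(s, nm) {
    dplyr::mutate(s$baseline, dataset = nm)
  })
  ggplot2::ggplot(tc, ggplot2::aes(time, frequency)) +
    ggplot2::geom_rect(data = band,
                       ggplot2::aes(xmin = -Inf, xmax = Inf,
                                    ymin = ci_lo, ymax = ci_hi),
                       inherit.aes = FALSE, alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::facet_grid(imf ~ dataset, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "instantaneous frequency (Hz)")
}

#' Plot ERD/ERS percent-change curves
#'
#' @param erd Output of [erd_ers()], possibly row-bound across bands.
#' @return A ggplot object.
#' @export
plot_erd <- function(erd) {
  ggplot2::ggplot(erd, ggplot2::aes(time, erd, colour = band)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time (s)", y = "amplitude change (%)")
}
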