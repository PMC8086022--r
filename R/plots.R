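scalp_base <- function() {
  circ <- tibble(theta = seq(0, 2 * pi, length.out = 181)) |>
    dplyr::mutate(x = cos(.data$theta), y = sin(.data$theta))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circ, ggplot2::aes(.data$x, .data$y),
                       colour = "grey60") +
    ggplot2::coord_fixed(xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25)) +
    ggplot2::theme_void()
}

#' Topographic plot of a statistics map
#'
#' Draws the 19 electrode sites on a schematic head, coloured by the map's
#' statistic (F, t, or r), with FDR-significant channels ringed — a plain
#' rendering of the familiar statistical scalp map. Multi-band maps are
#' facetted by band.
#'
#' @param object An `eeg_stat_map` or `eeg_corr_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_stat_map <- function(object, ...) {
  kind <- attr(object, "statistic_kind")
  d <- tidy(object) |>
    dplyr::left_join(montage_1020(), by = "channel")
  val <- if ("statistic" %in% names(d)) "statistic" else "estimate"
  p <- scalp_base() +
    ggplot2::geom_point(
      data = d,
      ggplot2::aes(.data$x, .data$y, colour = .data[[val]]), size = 6) +
    ggplot2::geom_point(
      data = dplyr::filter(d, .data$significant),
      ggplot2::aes(.data$x, .data$y), shape = 21, size = 8,
      stroke = 1.1, colour = "black", fill = NA) +
    ggplot2::geom_text(
      data = d, ggplot2::aes(.data$x, .data$y, label = .data$channel),
      size = 2.2, vjust = -2.4) +
    ggplot2::labs(colour = kind,
                  title = attr(object, "analysis_id"),
                  subtitle = sprintf("q = %g, FDR threshold = %.4g",
                                     attr(object, "q"),
                                     attr(object, "fdr_threshold")))
  if ("band" %in% names(d) && dplyr::n_distinct(d$band) > 1) {
    p <- p + ggplot2::facet_wrap(~band)
  }
  if (kind %in% c("pearson", "spearman")) {
    p <- p + ggplot2::scale_colour_gradient2(limits = c(-1, 1))
  } else {
    p <- p + ggplot2::scale_colour_viridis_c()
  }
  p
}

#' Topographic plot of a Fisher-z trend map
#'
#' @param object An `eeg_trend_map` from [fisher_z_trend()].
#' @param value `"beta"` or `"r_squared"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_trend_map <- function(object, value = c("beta", "r_squared"),
                                   ...) {
  value <- match.arg(value)
  d <- dplyr::left_join(as_tibble(object), montage_1020(), by = "channel")
  scalp_base() +
    ggplot2::geom_point(data = d,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data[[value]]), size = 6) +
    ggplot2::geom_text(data = d,
                       ggplot2::aes(.data$x, .data$y, label = .data$channel),
                       size = 2.2, vjust = -2.4) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(colour = value, title = "Fisher-z trend across severity")
}

#' Hypnogram plot
#'
#' Stage-versus-time step plot with the conventional depth ordering
#' (W on top, then R, N1, N2, N3).
#'
#' @param h A [hypnogram()].
#' @return A ggplot object.
#' @export
plot_hypnogram <- function(h) {
  depth <- c(W = 0, R = -1, N1 = -2, N2 = -3, N3 = -4)
  d <- tibble(
    t_min = (h$epoch_index - 1) * attr(h, "epoch_len_s") / 60,
    depth = depth[as.character(h$stage)])
  ggplot2::ggplot(d, ggplot2::aes(.data$t_min, .data$depth)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = unname(depth),
                                labels = names(depth)) +
    ggplot2::labs(x = "time in bed (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Group band-power histogram at selected channels
#'
#' Mean log10 power with standard-error bars per group, for one state and
#' band at chosen channels — the companion to a significant map cell.
#'
#' @param bp Band-power tibble.
#' @param state,band State and band to show.
#' @param channels Channel labels.
#' @return A ggplot object.
#' @export
plot_band_power <- function(bp, state, band, channels) {
  assert_channels(channels)
  d <- bp |>
    dplyr::filter(.data$state == !!state, .data$band == !!band,
                  .data$channel %in% channels) |>
    dplyr::group_by(.data$channel, .data$group) |>
    dplyr::summarise(mean = mean(.data$log10_power),
                     sem = sd(.data$log10_power) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(group = factor(.data$group, levels = cohort_groups()))
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$mean,
                                  fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.25) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(y = sprintf("log10 %s power (%s)", band, state),
                  x = NULL) +
    ggplot2::theme_minimal()
}
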