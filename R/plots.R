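#' Plot trajectories in the xy plane
#'
#' @param tracks a [track_set()]; coloured by population when classified.
#' @param n_max plot at most this many trajectories (sampling is
#'   deterministic: the first `n_max` ids).
#' @return a ggplot object.
#' @export
plot_tracks <- function(tracks, n_max = 500) {
  df <- tibble::as_tibble(tracks)
  ids <- unique(df$id)
  if (length(ids) > n_max) df <- dplyr::filter(df, .data$id %in% ids[seq_len(n_max)])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x * 1e6, y = .data$y * 1e6,
                                        group = .data$id))
  p <- if ("label" %in% names(df)) {
    p + ggplot2::geom_path(ggplot2::aes(colour = .data$label), alpha = 0.7)
  } else {
    p + ggplot2::geom_path(alpha = 0.5)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m)),
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' Plot an MSD curve, optionally with its linear fit
#'
#' @param curve an `msd_curve` from [t_msd()] or [te_msd()].
#' @param fit optional [fit_msd()] result to overlay.
#' @return a ggplot object.
#' @export
plot_msd <- function(curve, fit = NULL) {
  df <- tibble::as_tibble(curve)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delay, y = .data$msd)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "delay time (s)", y = expression(MSD ~ (m^2))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(intercept = fit$intercept,
                                  slope = 2 * fit$d * fit$D,
                                  linetype = 2, colour = "red")
  }
  p
}

#' Plot an MSD fit over the points used in the fit
#'
#' @param object an `msd_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.msd_fit <- function(object, ...) {
  plot_msd(object$data, fit = object) +
    ggplot2::ggtitle(sprintf("D = %.3g m²/s (%s)", object$D, object$kind))
}

#' Semi-log survival plot of squared displacements
#'
#' @param sample squared displacements (vector or tibble from
#'   [squared_displacements()]); when a `label` column is present one curve
#'   is drawn per population.
#' @return a ggplot object with logarithmic y axis.
#' @export
plot_survival <- function(sample) {
  if (is.data.frame(sample) && "label" %in% names(sample)) {
    df <- sample |>
      dplyr::group_by(.data$label) |>
      dplyr::group_modify(~ empirical_survival(.x)) |>
      dplyr::ungroup()
    p <- ggplot2::ggplot(dplyr::filter(df, .data$survival > 0),
                         ggplot2::aes(x = .data$r2, y = .data$survival,
                                      colour = .data$label)) +
      ggplot2::geom_step()
  } else {
    df <- empirical_survival(sample)
    p <- ggplot2::ggplot(dplyr::filter(df, .data$survival > 0),
                         ggplot2::aes(x = .data$r2, y = .data$survival)) +
      ggplot2::geom_step()
  }
  p + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(r^2 ~ (m^2)), y = "1 - CDF",
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' Histogram of a trajectory property
#'
#' @param props property table from [compute_properties()].
#' @param property property column name to plot.
#' @param bins histogram bin count.
#' @return a ggplot object (log-x, faceted by label when present).
#' @export
plot_property_histogram <- function(props, property = "mbcr", bins = 40) {
  stopifnot(property %in% names(props))
  df <- dplyr::filter(props, is.finite(.data[[property]]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[property]])) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::theme_minimal()
  if (all(df[[property]] > 0)) p <- p + ggplot2::scale_x_log10()
  if ("label" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$label), ncol = 1)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
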