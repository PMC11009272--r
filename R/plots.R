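#' Plot AOA vs NOB abundances with the theoretical band
#'
#' Scatter of per-sample AOA against NOB absolute abundance for one
#' reattribution arm, with the OLS fit and the theoretical-band envelope
#' (dashed lines of slope `band$low` and `band$high`).
#'
#' @param x An `nb_reattribution` object.
#' @param arm `"with"` or `"without"` the candidate lineage.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_reattribution <- function(x, arm = c("with", "without"), ...) {
  arm <- match.arg(arm)
  a <- x[[arm]]
  band <- a$summary$band
  df <- a$ratios
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nob, y = .data$aoa)) +
    ggplot2::geom_abline(slope = band$low, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = band$high, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "purple") +
    ggplot2::labs(
      x = "NOB absolute abundance (cells g⁻¹)",
      y = "AOA absolute abundance (cells g⁻¹)",
      title = sprintf("AOA vs NOB (%s candidate lineage)",
                      if (arm == "with") "including" else "excluding"),
      subtitle = sprintf("slope = %.1f, R² = %.2f; dashed: band %.1f-%.1f",
                         a$regression$slope, a$regression$r_squared,
                         band$low, band$high)
    ) +
    ggplot2::theme_minimal()
}

#' Boxplot of AOA:NOB ratios for both reattribution arms
#'
#' Mirrors the ratio panel of the balance analysis: per-sample ratio
#' distributions with and without the candidate lineage on a log axis, the
#' theoretical band shaded.
#'
#' @param x An `nb_reattribution` object.
#' @return A ggplot object.
#' @export
plot_ratio_arms <- function(x) {
  stopifnot(inherits(x, "nb_reattribution"))
  band <- x$with$summary$band
  df <- dplyr::bind_rows(
    dplyr::mutate(x$without$ratios, arm = "without candidate"),
    dplyr::mutate(x$with$ratios, arm = "with candidate")
  ) |> dplyr::filter(!.data$excluded)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$ratio)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = band$low, ymax = band$high, alpha = 0.15) +
    ggplot2::geom_boxplot(width = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "AOA:NOB abundance ratio",
                  subtitle = sprintf("shaded: theoretical band %.1f-%.1f",
                                     band$low, band$high)) +
    ggplot2::theme_minimal()
}

#' Depth profiles of guild absolute abundances per core
#'
#' Abundance-versus-depth profiles (depth increasing downwards, log
#' abundance axis) for the nitrifier guilds, with the oxygen penetration
#' depth marked per core.
#'
#' @param absolute Long tibble from [absolute_abundances()].
#' @param zones Tibble from [split_redox_zones()].
#' @param guilds Guild labels to draw.
#' @return A ggplot object.
#' @export
plot_depth_profiles <- function(absolute, zones,
                                guilds = c("AOA", NOB_ALL)) {
  df <- absolute |>
    dplyr::filter(.data$guild %in% guilds) |>
    dplyr::left_join(dplyr::select(zones, "sample_id", "core_id",
                                   "depth_cm", "opd_cm"),
                     by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_abund, y = .data$depth_cm,
                                   colour = .data$guild)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$opd_cm),
                        linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(ggplot2::vars(.data$core_id)) +
    ggplot2::labs(x = "absolute abundance (cells g⁻¹)",
                  y = "depth (cm below seafloor)",
                  subtitle = "dotted line: oxygen penetration depth") +
    ggplot2::theme_minimal()
}

#' Stacked NOB composition versus depth
#'
#' Per-sample fractions of the three NOB lineages among total NOB, stacked
#' by depth for each core.
#'
#' @param x An [nob_composition()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_nob_composition <- function(x, ...) {
  ggplot2::ggplot(x$per_sample,
                  ggplot2::aes(x = .data$fraction, y = .data$depth_cm,
                               fill = .data$guild)) +
    ggplot2::geom_col(orientation = "y", width = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(ggplot2::vars(.data$core_id)) +
    ggplot2::labs(x = "fraction of NOB community",
                  y = "depth (cm below seafloor)") +
    ggplot2::theme_minimal()
}
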