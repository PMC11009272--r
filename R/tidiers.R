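#' Tidy and glance methods
#'
#' Broom-style one-row-per-term (`tidy()`) and one-row-per-object
#' (`glance()`) summaries for the fitted objects in this package.
#'
#' @param x A fitted object (`nb_regression`, `nb_ratio_summary`,
#'   `nb_reattribution`, or `nb_band`).
#' @param ... Unused.
#' @return A tibble.
#' @name nitribalance-tidiers
NULL

#' @rdname nitribalance-tidiers
#' @export
tidy.nb_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                 std.error = s[, "Std. Error"],
                 statistic = s[, "t value"], p.value = s[, "Pr(>|t|)"])
}

#' @rdname nitribalance-tidiers
#' @export
glance.nb_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, n = x$n,
                 with_intercept = x$with_intercept)
}

#' @rdname nitribalance-tidiers
#' @export
glance.nb_ratio_summary <- function(x, ...) {
  tibble::tibble(n = x$n, median = x$median, ci_level = x$ci_level,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n_above_band = x$n_above_band, n_below_band = x$n_below_band,
                 n_excluded = x$n_excluded)
}

#' @rdname nitribalance-tidiers
#' @export
tidy.nb_ratio_summary <- function(x, ...) {
  tibble::tibble(ratio = x$ratios)
}

#' @rdname nitribalance-tidiers
#' @export
tidy.nb_reattribution <- function(x, ...) {
  dplyr::bind_rows(
    without_candidate = dplyr::mutate(
      glance(x$without$summary), mean = x$without$mean_ratio,
      slope = x$without$regression$slope,
      r.squared = x$without$regression$r_squared),
    with_candidate = dplyr::mutate(
      glance(x$with$summary), mean = x$with$mean_ratio,
      slope = x$with$regression$slope,
      r.squared = x$with$regression$r_squared),
    .id = "arm"
  )
}

#' @rdname nitribalance-tidiers
#' @export
glance.nb_reattribution <- function(x, ...) {
  tibble::tibble(
    n_oxic_samples = x$n_oxic_samples,
    median_without = x$without$summary$median,
    median_with = x$with$summary$median,
    median_ratio_without_over_with = x$median_ratio_without_over_with
  )
}

#' @rdname nitribalance-tidiers
#' @export
tidy.nb_band <- function(x, ...) {
  tibble::tibble(low = x$low, central = x$central, high = x$high,
                 provenance = x$provenance)
}
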