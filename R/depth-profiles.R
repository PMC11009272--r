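#' Per-sample relative abundances by guild
#'
#' Converts OTU read counts to per-sample fractions of the total community
#' and sums them over the member OTUs of each guild. Every guild label in the
#' guild map (including `other`) gets a row per sample, so per-sample
#' fractions add to 1.
#'
#' @param otu_table Tibble from [read_otu_table()] (`otu_id` + sample
#'   columns).
#' @param guild_map Tibble from [assign_guilds()].
#'
#' @return A long tibble `sample_id`, `guild`, `rel_abund`.
#' @export
relative_abundances <- function(otu_table, guild_map) {
  stopifnot(names(otu_table)[1] == "otu_id")
  long <- tidyr::pivot_longer(otu_table, -"otu_id",
                              names_to = "sample_id", values_to = "count")
  totals <- long |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero) > 0) {
    stop_format(sprintf("Sample(s) with zero total counts: %s",
                        paste(zero, collapse = ", ")))
  }
  unmapped <- setdiff(otu_table$otu_id, guild_map$otu_id)
  if (length(unmapped) > 0) {
    stop_format(sprintf("OTU(s) missing from guild map: %s",
                        paste(head(unmapped, 5), collapse = ", ")))
  }
  long |>
    dplyr::left_join(dplyr::select(guild_map, "otu_id", "guild"),
                     by = "otu_id") |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::group_by(.data$sample_id, .data$guild) |>
    dplyr::summarise(rel_abund = sum(.data$count / .data$total),
                     .groups = "drop") |>
    tidyr::complete(sample_id = unique(long$sample_id),
                    guild = unique(guild_map$guild),
                    fill = list(rel_abund = 0))
}

#' Absolute abundances from relative abundances and qPCR totals
#'
#' The absolute abundance of a group in a sample is its relative amplicon
#' abundance times the total cell number, operationalized as the sum of the
#' archaeal and bacterial 16S qPCR copies per gram (no 16S copy-number
#' correction).
#'
#' @param rel Long tibble from [relative_abundances()].
#' @param samples Tibble from [read_sample_table()].
#'
#' @return `rel` with added columns `total_cells` and `abs_abund`
#'   (cells g^-1).
#' @export
absolute_abundances <- function(rel, samples) {
  stopifnot(all(c("sample_id", "rel_abund") %in% names(rel)))
  miss <- setdiff(unique(rel$sample_id), samples$sample_id)
  if (length(miss) > 0) {
    stop_format(sprintf("Sample(s) missing from sample table: %s",
                        paste(miss, collapse = ", ")))
  }
  qp <- samples |>
    dplyr::transmute(.data$sample_id,
                     total_cells = .data$qpcr_arch + .data$qpcr_bac)
  if (any(is.na(qp$total_cells[qp$sample_id %in% rel$sample_id]))) {
    stop_format("Missing qPCR values for sample(s) present in the abundance table.")
  }
  rel |>
    dplyr::left_join(qp, by = "sample_id") |>
    dplyr::mutate(abs_abund = .data$rel_abund * .data$total_cells)
}

#' Infer the oxygen penetration depth from an O2 profile
#'
#' Returns, per core, the shallowest depth at which the linearly
#' interpolated O2 concentration crosses `threshold_uM`. If O2 never drops
#' to the threshold within the profile, the bottom depth is returned and
#' flagged `unbounded`.
#'
#' @param geochem Tibble from [read_geochem()]; must contain `o2_uM`.
#' @param threshold_uM O2 threshold (µM) defining the oxic-zone base.
#'
#' @return A tibble `core_id`, `opd_cm`, `unbounded`.
#' @export
#' @examples
#' g <- tibble::tibble(core_id = "c1", depth_cm = c(0, 9, 18, 30),
#'                     o2_uM = c(10, 5, 0, 0))
#' infer_opd(g, threshold_uM = 1)   # 16.2 cm
infer_opd <- function(geochem, threshold_uM = 1) {
  if (!"o2_uM" %in% names(geochem) || all(is.na(geochem$o2_uM))) {
    stop_format(paste("No O2 series in the geochemistry table;",
                      "supply the oxygen penetration depth directly."))
  }
  geochem |>
    dplyr::filter(!is.na(.data$o2_uM)) |>
    dplyr::group_by(.data$core_id) |>
    dplyr::group_modify(function(df, key) {
      z <- df$depth_cm
      o2 <- df$o2_uM
      if (o2[1] <= threshold_uM) {
        stop_format(sprintf(
          "Core %s: surface O2 (%.3g) is already at or below the threshold (%g).",
          key$core_id, o2[1], threshold_uM))
      }
      cross <- which(o2[-length(o2)] > threshold_uM &
                       o2[-1] <= threshold_uM)
      if (length(cross) == 0) {
        return(tibble::tibble(opd_cm = z[length(z)], unbounded = TRUE))
      }
      i <- cross[1]
      opd <- z[i] + (o2[i] - threshold_uM) / (o2[i] - o2[i + 1]) *
        (z[i + 1] - z[i])
      tibble::tibble(opd_cm = opd, unbounded = FALSE)
    }) |>
    dplyr::ungroup()
}

#' Label samples as oxic or anoxic
#'
#' A sample is oxic iff its depth midpoint is at or above the core's oxygen
#' penetration depth (`depth_cm <= opd_cm`; the boundary itself is oxic).
#'
#' @param samples Tibble from [read_sample_table()].
#' @param opd Tibble `core_id`, `opd_cm` (measured values or [infer_opd()]
#'   output).
#'
#' @return `samples` with added columns `opd_cm` and `zone`
#'   (`"oxic"`/`"anoxic"`).
#' @export
split_redox_zones <- function(samples, opd) {
  stopifnot(all(c("core_id", "opd_cm") %in% names(opd)))
  miss <- setdiff(unique(samples$core_id), opd$core_id)
  if (length(miss) > 0) {
    stop_format(sprintf("No oxygen penetration depth for core(s): %s",
                        paste(miss, collapse = ", ")))
  }
  samples |>
    dplyr::left_join(dplyr::select(opd, "core_id", "opd_cm"),
                     by = "core_id") |>
    dplyr::mutate(zone = ifelse(.data$depth_cm <= .data$opd_cm,
                                "oxic", "anoxic"))
}

#' Depth-averaged value of a sampled profile
#'
#' Trapezoidal integral of `values` against `depths` over the sampled span,
#' divided by that span. No extrapolation beyond the first and last sampled
#' depth is performed.
#'
#' @param values Numeric values at each depth.
#' @param depths Strictly increasing depths (cm); at least two.
#'
#' @return A scalar depth-averaged value.
#' @export
#' @examples
#' depth_averaged_abundance(c(1, 2, 4), c(0, 10, 40))  # 2.75
depth_averaged_abundance <- function(values, depths) {
  if (length(depths) < 2) {
    stop_param(paste("Need at least two in-zone samples to depth-average;",
                     "pass the single value through directly if intended."),
               "depths")
  }
  check_strictly_increasing(depths, "depths")
  if (length(values) != length(depths) || anyNA(values)) {
    stop_param("`values` must match `depths` with no NAs.", "values")
  }
  pracma::trapz(depths, values) / (depths[length(depths)] - depths[1])
}

#' NOB community composition per sample and depth-averaged per core
#'
#' Fractions of the three nitrite-oxidizer lineages (Nitrospiraceae,
#' Nitrospinaceae, candidate) among total NOB, per sample, and their
#' trapezoidally depth-averaged values over the oxic zone of each core.
#' Samples with zero total NOB are excluded with a warning.
#'
#' @param abundance Long tibble with `sample_id`, `guild` and a `value`
#'   column (`abs_abund` or `rel_abund`) covering the three NOB guild labels.
#' @param zones Tibble from [split_redox_zones()] (needs `sample_id`,
#'   `core_id`, `depth_cm`, `zone`).
#'
#' @return A list of class `nb_nob_composition`: `per_sample` (tibble
#'   `sample_id`, `core_id`, `depth_cm`, `zone`, `guild`, `fraction`) and
#'   `depth_averaged` (tibble `core_id`, `guild`, `fraction`, oxic samples
#'   only).
#' @export
nob_composition <- function(abundance, zones) {
  value_col <- intersect(c("abs_abund", "rel_abund", "value"),
                         names(abundance))[1]
  if (is.na(value_col)) {
    stop_param("`abundance` needs an abs_abund/rel_abund/value column.",
               "abundance")
  }
  nob <- abundance |>
    dplyr::filter(.data$guild %in% NOB_ALL) |>
    dplyr::select("sample_id", "guild", value = dplyr::all_of(value_col))
  per_sample <- nob |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(total = sum(.data$value)) |>
    dplyr::ungroup()
  zero <- unique(per_sample$sample_id[per_sample$total == 0])
  if (length(zero) > 0) {
    warn(sprintf("Excluding %d sample(s) with zero total NOB: %s",
                 length(zero), paste(head(zero, 5), collapse = ", ")))
    per_sample <- dplyr::filter(per_sample, .data$total > 0)
  }
  per_sample <- per_sample |>
    dplyr::mutate(fraction = .data$value / .data$total) |>
    dplyr::left_join(
      dplyr::select(zones, "sample_id", "core_id", "depth_cm", "zone"),
      by = "sample_id") |>
    dplyr::select("sample_id", "core_id", "depth_cm", "zone", "guild",
                  "fraction")

  depth_avg <- per_sample |>
    dplyr::filter(.data$zone == "oxic") |>
    dplyr::arrange(.data$core_id, .data$guild, .data$depth_cm) |>
    dplyr::group_by(.data$core_id, .data$guild) |>
    dplyr::summarise(
      fraction = depth_averaged_abundance(.data$fraction, .data$depth_cm),
      n_samples = dplyr::n(), .groups = "drop")

  structure(list(per_sample = per_sample, depth_averaged = depth_avg),
            class = "nb_nob_composition")
}

#' @export
print.nb_nob_composition <- function(x, ...) {
  cat("<nb_nob_composition>\nDepth-averaged oxic-zone NOB fractions:\n")
  print(x$depth_averaged)
  invisible(x)
}
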