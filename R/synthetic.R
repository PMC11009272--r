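#' Parameters for the synthetic sediment-core generator
#'
#' Bundles every knob of the simulated study into a validated list. The
#' defaults describe a small set of oligotrophic deep-sea cores: guild
#' abundances decline exponentially with depth, the true AOA:NOB cell ratio is
#' constant inside the oxic zone, and a candidate NOB lineage carries a fixed
#' fraction of all NOB cells there. Below the oxygen penetration depth (OPD),
#' AOA and the canonical NOB families are attenuated steeply toward zero while
#' the anaerotolerant candidate species persists at a constant floor.
#'
#' @param n_cores Number of sediment cores.
#' @param depths_cm Sampling depth midpoints, cm below seafloor, strictly
#'   increasing. Shared by all cores.
#' @param opd_cm Oxygen penetration depth per core (cm); recycled to
#'   `n_cores`. A sample is oxic iff `depth_cm <= opd_cm`.
#' @param o2_surface_uM Dissolved O2 at the sediment surface (µM).
#' @param r_true True AOA : total-NOB cell ratio inside the oxic zone
#'   (dimensionless, > 0).
#' @param f_candidate Fraction of total NOB cells belonging to the candidate
#'   lineage, in `[0, 1)`.
#' @param f_split_canonical Fraction of the remaining (canonical) NOB cells
#'   assigned to Nitrospiraceae; the rest go to Nitrospinaceae.
#' @param aoa_surface_cells AOA absolute abundance at the surface (cells g^-1).
#' @param decay_per_cm Exponential decline rate of all nitrifier abundances
#'   with depth (cm^-1).
#' @param anoxic_attenuation Additional exponential decay rate (cm^-1) applied
#'   to AOA and canonical NOB below the OPD, so aerobic guilds fall off
#'   steeply in anoxic sediment.
#' @param candidate_floor_frac Anoxic abundance of the anaerotolerant
#'   candidate species, expressed as a constant fraction of the candidate
#'   lineage abundance at the OPD (illustrative, not mechanistic).
#' @param background_otus Number of non-nitrifier OTUs; `0` turns the
#'   background community off.
#' @param background_mean_cells Mean surface abundance of one background OTU
#'   (cells g^-1).
#' @param background_lognorm_sigma Lognormal dispersion (sdlog) of background
#'   OTU surface abundances.
#' @param read_depth Amplicon reads per sample (>= 1).
#' @param qpcr_sigma Lognormal observation noise (sdlog) on the archaeal and
#'   bacterial qPCR totals; `0` makes qPCR exact.
#' @param amplicon_model `"multinomial"` draws integer read counts from a
#'   multinomial; `"expected"` emits the noise-free expected counts
#'   (real-valued, still summing to `read_depth`), used to study the pipeline
#'   with all stochasticity disabled.
#' @param seed Root RNG seed. Per-core streams are derived from it, so adding
#'   a core never perturbs earlier cores.
#'
#' @return A validated `nb_synthetic_params` list.
#' @seealso [generate_dataset()]
#' @export
#' @examples
#' p <- synthetic_params(r_true = 8, f_candidate = 0.6, qpcr_sigma = 0)
#' p$r_true
synthetic_params <- function(n_cores = 5,
                             depths_cm = seq(2.5, 97.5, by = 5),
                             opd_cm = 60,
                             o2_surface_uM = 150,
                             r_true = 10,
                             f_candidate = 0.65,
                             f_split_canonical = 0.5,
                             aoa_surface_cells = 2e7,
                             decay_per_cm = 0.03,
                             anoxic_attenuation = 0.2,
                             candidate_floor_frac = 0.5,
                             background_otus = 50,
                             background_mean_cells = 2e7,
                             background_lognorm_sigma = 1,
                             read_depth = 30000,
                             qpcr_sigma = 0.3,
                             amplicon_model = c("multinomial", "expected"),
                             seed = 1) {
  amplicon_model <- match.arg(amplicon_model)
  check_number(n_cores, "n_cores", lower = 1)
  check_strictly_increasing(depths_cm, "depths_cm")
  if (any(depths_cm < 0)) stop_param("`depths_cm` must be non-negative.", "depths_cm")
  if (!is.numeric(opd_cm) || any(opd_cm <= 0)) {
    stop_param("`opd_cm` must be positive.", "opd_cm")
  }
  opd_cm <- rep_len(opd_cm, n_cores)
  check_number(o2_surface_uM, "o2_surface_uM", lower = 0)
  check_number(r_true, "r_true", lower = 0, allow_zero_lower = FALSE)
  check_number(f_candidate, "f_candidate", lower = 0, upper = 1)
  if (f_candidate >= 1) stop_param("`f_candidate` must be < 1.", "f_candidate")
  check_number(f_split_canonical, "f_split_canonical", lower = 0, upper = 1)
  check_number(aoa_surface_cells, "aoa_surface_cells", lower = 0,
               allow_zero_lower = FALSE)
  check_number(decay_per_cm, "decay_per_cm", lower = 0)
  check_number(anoxic_attenuation, "anoxic_attenuation", lower = 0)
  check_number(candidate_floor_frac, "candidate_floor_frac", lower = 0, upper = 1)
  check_number(background_otus, "background_otus", lower = 0)
  check_number(background_mean_cells, "background_mean_cells", lower = 0)
  check_number(background_lognorm_sigma, "background_lognorm_sigma", lower = 0)
  check_number(read_depth, "read_depth", lower = 1)
  check_number(qpcr_sigma, "qpcr_sigma", lower = 0)
  check_number(seed, "seed")

  structure(
    list(
      n_cores = as.integer(n_cores), depths_cm = as.double(depths_cm),
      opd_cm = as.double(opd_cm), o2_surface_uM = o2_surface_uM,
      r_true = r_true, f_candidate = f_candidate,
      f_split_canonical = f_split_canonical,
      aoa_surface_cells = aoa_surface_cells, decay_per_cm = decay_per_cm,
      anoxic_attenuation = anoxic_attenuation,
      candidate_floor_frac = candidate_floor_frac,
      background_otus = as.integer(background_otus),
      background_mean_cells = background_mean_cells,
      background_lognorm_sigma = background_lognorm_sigma,
      read_depth = read_depth, qpcr_sigma = qpcr_sigma,
      amplicon_model = amplicon_model, seed = as.integer(seed)
    ),
    class = "nb_synthetic_params"
  )
}

#' Idealized dissolved-oxygen depth profile
#'
#' O2 declines linearly from `o2_surface_uM` at the sediment surface to zero
#' at the oxygen penetration depth and stays at zero below it.
#'
#' @param depths_cm Depths (cm below seafloor) at which to evaluate.
#' @param opd_cm Oxygen penetration depth (cm, > 0).
#' @param o2_surface_uM Surface O2 concentration (µM).
#' @param core_id Core label attached to the output.
#'
#' @return A tibble with columns `core_id`, `depth_cm`, `o2_uM`.
#' @export
#' @examples
#' make_o2_profile(c(0, 9, 18, 30), opd_cm = 18, o2_surface_uM = 10)
make_o2_profile <- function(depths_cm, opd_cm, o2_surface_uM, core_id = "core1") {
  if (!is.numeric(opd_cm) || length(opd_cm) != 1L || is.na(opd_cm) || opd_cm <= 0) {
    stop_param("`opd_cm` must be a single positive number.", "opd_cm")
  }
  check_number(o2_surface_uM, "o2_surface_uM", lower = 0)
  tibble::tibble(
    core_id = core_id,
    depth_cm = as.double(depths_cm),
    o2_uM = pmax(0, o2_surface_uM * (1 - depths_cm / opd_cm))
  )
}

#' Multinomial amplicon read counts
#'
#' Observation model for amplicon sequencing: reads are a single multinomial
#' draw over the community relative abundances. Uses the current RNG state;
#' seed the stream before calling for reproducibility.
#'
#' @param rel_abund Probability vector (sums to 1 within 1e-9).
#' @param read_depth Total reads to draw (>= 1).
#'
#' @return Integer count vector of the same length as `rel_abund`, summing to
#'   `read_depth`.
#' @export
#' @examples
#' withr::with_seed(1, draw_amplicon_counts(c(0.5, 0.3, 0.2), 100))
draw_amplicon_counts <- function(rel_abund, read_depth) {
  if (!is.numeric(rel_abund) || length(rel_abund) < 1L || anyNA(rel_abund)) {
    stop_param("`rel_abund` must be a numeric vector without NAs.", "rel_abund")
  }
  if (any(rel_abund < 0)) {
    stop_param("`rel_abund` contains negative probabilities.", "rel_abund")
  }
  if (abs(sum(rel_abund) - 1) > 1e-9) {
    stop_param("`rel_abund` must sum to 1 (tolerance 1e-9).", "rel_abund")
  }
  check_number(read_depth, "read_depth", lower = 1)
  drop(rmultinom(1, size = read_depth, prob = rel_abund))
}

# True cell abundances for every sample of one core, before any observation
# noise. Candidate lineage is split between an oxic specialist species and an
# anaerotolerant species that persists below the OPD at a constant floor.
core_truth <- function(p, core_idx) {
  z <- p$depths_cm
  opd <- p$opd_cm[core_idx]
  oxic <- z <= opd

  base <- p$aoa_surface_cells * exp(-p$decay_per_cm * z)
  anox_fac <- ifelse(oxic, 1, exp(-p$anoxic_attenuation * (z - opd)))

  aoa <- base * anox_fac
  nob_total_oxic <- base / p$r_true
  canonical <- nob_total_oxic * (1 - p$f_candidate) * anox_fac
  spira <- canonical * p$f_split_canonical
  spina <- canonical * (1 - p$f_split_canonical)

  cand_total_oxic <- nob_total_oxic * p$f_candidate
  cand_at_opd <- (p$aoa_surface_cells * exp(-p$decay_per_cm * opd)) /
    p$r_true * p$f_candidate
  # oxic specialist (40%) vanishes below the OPD; anaerotolerant species (60%)
  # keeps its oxic profile above the OPD and a constant floor below it
  cand_aero <- ifelse(oxic, 0.4 * cand_total_oxic, 0)
  cand_anaero <- ifelse(oxic, 0.6 * cand_total_oxic,
                        p$candidate_floor_frac * cand_at_opd)

  anammox <- ifelse(oxic, 0.002 * base,
                    0.2 * p$aoa_surface_cells * exp(-p$decay_per_cm * z))

  tibble::tibble(
    core_id = sprintf("core%02d", core_idx),
    depth_cm = z,
    zone = ifelse(oxic, "oxic", "anoxic"),
    aoa = aoa,
    nob_nitrospiraceae = spira,
    nob_nitrospinaceae = spina,
    nob_candidate_aero = cand_aero,
    nob_candidate_anaero = cand_anaero,
    anammox = anammox
  )
}

# Fixed nitrifier OTU inventory: ids, lineage columns, and which truth column
# each OTU draws its cells from (with a within-lineage split for AOA).
nitrifier_otus <- function() {
  tibble::tribble(
    ~otu_id,   ~domain,    ~phylum,            ~class,                ~order,               ~family,             ~genus,            ~truth_col,              ~share,
    "OTU_1",   "Archaea",  "Crenarchaeota",    "Nitrososphaeria",     "Nitrosopumilales",   "Nitrosopumilaceae", "Nitrosopumilus",  "aoa",                   0.7,
    "OTU_2",   "Archaea",  "Crenarchaeota",    "Nitrososphaeria",     "Nitrosopumilales",   "Nitrosopumilaceae", "unclassified",    "aoa",                   0.3,
    "OTU_3",   "Bacteria", "Nitrospirota",     "Nitrospiria",         "Nitrospirales",      "Nitrospiraceae",    "Nitrospira",      "nob_nitrospiraceae",    1,
    "OTU_5",   "Bacteria", "Nitrospinota",     "Nitrospinia",         "Nitrospinales",      "Nitrospinaceae",    "Nitrospina",      "nob_nitrospinaceae",    1,
    "OTU_235", "Bacteria", "Schekmanbacteria", "unclassified",        "unclassified",       "unclassified",      "unclassified",    "nob_candidate_aero",    1,
    "OTU_4",   "Bacteria", "Schekmanbacteria", "unclassified",        "unclassified",       "unclassified",      "unclassified",    "nob_candidate_anaero",  1,
    "OTU_9",   "Bacteria", "Planctomycetota",  "Brocadiae",           "Brocadiales",        "Scalinduaceae",     "Scalindua",       "anammox",               1
  )
}

#' Generate a synthetic sediment-core dataset
#'
#' Builds a full multi-core dataset with the statistical structure the
#' downstream analysis assumes: depth-structured true guild abundances with a
#' fixed AOA:NOB cell ratio inside the oxic zone, a candidate NOB lineage
#' carrying `f_candidate` of all NOB cells there, multinomial amplicon counts,
#' lognormal qPCR observation noise, and linear-to-zero O2 profiles. All
#' randomness derives from `params$seed` through one sub-stream per core.
#'
#' @param params A [synthetic_params()] object.
#'
#' @return An `nb_synthetic_dataset` list with elements `otu_table` (tibble,
#'   first column `otu_id`, one column per sample), `taxonomy`, `samples`,
#'   `geochem`, `truth` (per-sample true guild cells and true ratios), plus
#'   `verified_candidate_otus` and the `params` used.
#' @export
#' @examples
#' d <- generate_dataset(synthetic_params(n_cores = 2, background_otus = 5,
#'                                        read_depth = 1000))
#' d$truth
generate_dataset <- function(params) {
  if (!inherits(params, "nb_synthetic_params")) {
    params <- do.call(synthetic_params, params)
  }
  p <- params
  nit <- nitrifier_otus()

  cores <- purrr::map(seq_len(p$n_cores), function(ci) {
    truth <- core_truth(p, ci)
    n_dep <- nrow(truth)
    sample_id <- sprintf("%s_d%03d", truth$core_id[1], seq_len(n_dep))

    withr::with_seed(derive_seed(p$seed, ci), {
      # background community: per-OTU surface abundance lognormal, same
      # exponential depth decay as the nitrifiers
      if (p$background_otus > 0) {
        bg_surface <- rlnorm(p$background_otus,
                             meanlog = log(p$background_mean_cells) -
                               p$background_lognorm_sigma^2 / 2,
                             sdlog = p$background_lognorm_sigma)
        bg <- outer(exp(-p$decay_per_cm * truth$depth_cm), bg_surface)
      } else {
        bg <- matrix(0, nrow = n_dep, ncol = 0)
      }

      nit_cells <- as.matrix(truth[, nit$truth_col]) *
        matrix(nit$share, n_dep, nrow(nit), byrow = TRUE)
      cells <- cbind(nit_cells, bg)
      total <- rowSums(cells)
      rel <- cells / total

      counts <- if (p$amplicon_model == "multinomial") {
        t(apply(rel, 1, draw_amplicon_counts, read_depth = p$read_depth))
      } else {
        rel * p$read_depth
      }

      arch_true <- truth$aoa
      bac_true <- total - arch_true
      noise <- function(n) if (p$qpcr_sigma > 0) rlnorm(n, 0, p$qpcr_sigma) else rep(1, n)
      qpcr_arch <- arch_true * noise(n_dep)
      qpcr_bac <- bac_true * noise(n_dep)
    })

    bg_ids <- if (p$background_otus > 0) {
      sprintf("bgOTU_%02d_%03d", ci, seq_len(p$background_otus))
    } else character()
    otu_ids <- c(nit$otu_id, bg_ids)
    colnames(counts) <- otu_ids

    list(
      truth = dplyr::mutate(truth, sample_id = sample_id, .before = 1),
      counts = tibble::as_tibble(counts) |>
        dplyr::mutate(sample_id = sample_id, .before = 1),
      samples = tibble::tibble(
        sample_id = sample_id, core_id = truth$core_id,
        depth_cm = truth$depth_cm,
        qpcr_arch = qpcr_arch, qpcr_bac = qpcr_bac
      ),
      geochem = core_geochem(p, ci),
      bg_ids = bg_ids
    )
  })

  counts_long <- purrr::list_rbind(purrr::map(cores, "counts")) |>
    tidyr::pivot_longer(-"sample_id", names_to = "otu_id", values_to = "n") |>
    dplyr::filter(!is.na(.data$n))
  otu_table <- counts_long |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0) |>
    dplyr::arrange(match(.data$otu_id, unique(counts_long$otu_id)))

  bg_tax <- purrr::list_rbind(purrr::map(cores, function(co) {
    tibble::tibble(otu_id = co$bg_ids, domain = "Bacteria",
                   phylum = "unclassified", class = "unclassified",
                   order = "unclassified", family = "unclassified",
                   genus = "unclassified")
  }))
  taxonomy <- dplyr::bind_rows(
    dplyr::select(nit, -"truth_col", -"share"), bg_tax
  ) |>
    dplyr::mutate(db = "SILVA 138.1")

  truth <- purrr::list_rbind(purrr::map(cores, "truth")) |>
    dplyr::mutate(
      nob_candidate = .data$nob_candidate_aero + .data$nob_candidate_anaero,
      nob_total = .data$nob_nitrospiraceae + .data$nob_nitrospinaceae +
        .data$nob_candidate,
      ratio_true = .data$aoa / .data$nob_total,
      ratio_canonical = .data$aoa /
        (.data$nob_nitrospiraceae + .data$nob_nitrospinaceae)
    )

  structure(
    list(
      otu_table = otu_table,
      taxonomy = taxonomy,
      samples = purrr::list_rbind(purrr::map(cores, "samples")),
      geochem = purrr::list_rbind(purrr::map(cores, "geochem")),
      truth = truth,
      verified_candidate_otus = c("OTU_4", "OTU_235"),
      params = p
    ),
    class = "nb_synthetic_dataset"
  )
}

# Porewater profiles for one core: measured-style O2 (linear to zero at the
# OPD) plus illustrative nitrate/nitrite/ammonium shapes.
core_geochem <- function(p, ci) {
  opd <- p$opd_cm[ci]
  z <- sort(unique(c(0, p$depths_cm)))
  prof <- make_o2_profile(z, opd, p$o2_surface_uM,
                          core_id = sprintf("core%02d", ci))
  prof$no3_uM <- pmax(0, 30 * pmin(1, z / opd) * ifelse(z <= opd, 1,
                                                        exp(-0.05 * (z - opd))))
  prof$no2_uM <- pmax(0, 0.5 * exp(-((z - opd)^2) / (0.1 * opd^2 + 1)))
  prof$nh4_uM <- ifelse(z <= opd, 0.1, 0.1 + 2 * (z - opd) / opd)
  prof
}

#' @export
print.nb_synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<nb_synthetic_dataset> %d cores, %d samples, %d OTUs (r_true = %g, f_candidate = %g)\n",
    x$params$n_cores, nrow(x$samples), nrow(x$otu_table),
    x$params$r_true, x$params$f_candidate
  ))
  invisible(x)
}

#' Write a synthetic dataset as the pipeline's TSV inputs
#'
#' Emits `otu_counts.tsv`, `taxonomy.tsv`, `samples.tsv`, `geochem.tsv`, and
#' `truth.tsv` into `dir`, in the formats the readers in this package consume.
#' Counts are written rounded to integers (relevant only for the
#' expected-count amplicon model).
#'
#' @param dataset An `nb_synthetic_dataset`.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "nb_synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  otu <- dataset$otu_table
  otu[-1] <- lapply(otu[-1], function(x) as.integer(round(x)))
  paths <- c(
    otu_counts = file.path(dir, "otu_counts.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    samples = file.path(dir, "samples.tsv"),
    geochem = file.path(dir, "geochem.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_otu_table(otu, paths[["otu_counts"]])
  write_taxonomy(dataset$taxonomy, paths[["taxonomy"]])
  readr::write_tsv(dataset$samples, paths[["samples"]])
  readr::write_tsv(dataset$geochem, paths[["geochem"]])
  readr::write_tsv(dataset$truth, paths[["truth"]])
  invisible(paths)
}
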