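#' Guild configuration: lineage patterns per nitrifier guild
#'
#' Maps taxonomic names at stated ranks to functional guilds. Defaults follow
#' the marine-sediment convention: AOA are the archaeal ammonia-oxidizer
#' family Nitrosopumilaceae; canonical NOB are the families Nitrospiraceae
#' and Nitrospinaceae (kept as separate labels); anammox bacteria are the
#' order Brocadiales. The candidate NOB lineage is deliberately NOT matched
#' by taxonomy patterns: its database classification is unstable
#' (Schekmanbacteria or Nitrospinota depending on the reference release), so
#' membership is driven by an explicit, independently verified OTU id list
#' passed to [assign_guilds()], optionally backed by a phylum name.
#'
#' @param aoa_family Family name(s) matched to the `AOA` guild.
#' @param nitrospiraceae,nitrospinaceae Family name(s) for the two canonical
#'   NOB labels.
#' @param anammox_order Order name(s) matched to the `anammox` guild.
#' @param candidate_phylum Optional phylum name(s) for putative candidate-NOB
#'   OTUs; even when it matches, an OTU only enters the `NOB_candidate` guild
#'   if listed in `verified_candidate_otus` (see [assign_guilds()]).
#'
#' @return A tibble with columns `guild`, `rank`, `pattern`.
#' @export
guild_config <- function(aoa_family = "Nitrosopumilaceae",
                         nitrospiraceae = "Nitrospiraceae",
                         nitrospinaceae = "Nitrospinaceae",
                         anammox_order = "Brocadiales",
                         candidate_phylum = "Schekmanbacteria") {
  cfg <- dplyr::bind_rows(
    tibble::tibble(guild = "AOA", rank = "family", pattern = aoa_family),
    tibble::tibble(guild = "NOB_Nitrospiraceae", rank = "family",
                   pattern = nitrospiraceae),
    tibble::tibble(guild = "NOB_Nitrospinaceae", rank = "family",
                   pattern = nitrospinaceae),
    tibble::tibble(guild = "anammox", rank = "order", pattern = anammox_order),
    if (length(candidate_phylum) > 0 && !all(is.na(candidate_phylum))) {
      tibble::tibble(guild = "NOB_candidate", rank = "phylum",
                     pattern = candidate_phylum)
    }
  )
  if (any(is.na(cfg$pattern) | cfg$pattern == "")) {
    stop_param("Guild patterns must be non-empty.", "pattern")
  }
  if (!all(cfg$rank %in% TAX_RANKS)) {
    stop_param("Guild pattern ranks must be one of the six lineage ranks.",
               "rank")
  }
  cfg
}

NB_GUILDS <- c("AOA", "NOB_Nitrospiraceae", "NOB_Nitrospinaceae",
               "NOB_candidate", "anammox", "other")
NOB_CANONICAL <- c("NOB_Nitrospiraceae", "NOB_Nitrospinaceae")
NOB_ALL <- c(NOB_CANONICAL, "NOB_candidate")

#' Attribute OTUs to nitrifier guilds
#'
#' Assigns every OTU of a taxonomy table to exactly one guild by
#' case-insensitive exact match of lineage names at the ranks stated in the
#' guild configuration. Candidate-NOB membership is a verification filter:
#' only OTUs listed in `verified_candidate_otus` are labelled
#' `NOB_candidate`; OTUs whose taxonomy matches the candidate phylum but that
#' are not on the verified list fall through to `other` (unverified putative
#' hits). An OTU matching two different guilds is a hard error, never a
#' silent priority. Unmatched OTUs are `other`.
#'
#' @param taxonomy Tibble from [read_taxonomy()] (columns `otu_id` + ranks).
#' @param config Tibble from [guild_config()].
#' @param verified_candidate_otus Character vector of OTU ids independently
#'   verified to belong to the candidate NOB lineage; ids absent from the
#'   taxonomy are skipped with a warning.
#'
#' @return A tibble `otu_id`, `guild`, `provenance` covering every OTU.
#' @export
assign_guilds <- function(taxonomy, config = guild_config(),
                          verified_candidate_otus = character()) {
  stopifnot(all(c("otu_id", TAX_RANKS) %in% names(taxonomy)))
  missing <- setdiff(verified_candidate_otus, taxonomy$otu_id)
  if (length(missing) > 0) {
    warn(sprintf("Verified candidate OTU(s) absent from taxonomy, skipped: %s",
                 paste(missing, collapse = ", ")))
  }
  verified <- intersect(verified_candidate_otus, taxonomy$otu_id)

  pattern_cfg <- dplyr::filter(config, .data$guild != "NOB_candidate")
  hits <- purrr::pmap(pattern_cfg, function(guild, rank, pattern) {
    match <- tolower(taxonomy[[rank]]) == tolower(pattern)
    tibble::tibble(
      otu_id = taxonomy$otu_id[match], guild = guild,
      provenance = sprintf("%s == '%s'", rank, pattern)
    )
  }) |> purrr::list_rbind()

  conflicts <- hits |>
    dplyr::distinct(.data$otu_id, .data$guild) |>
    dplyr::count(.data$otu_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(sprintf("OTU(s) match more than one guild pattern: %s",
                  paste(conflicts$otu_id, collapse = ", ")),
          class = "nitribalance_guild_conflict")
  }
  hits <- dplyr::distinct(hits, .data$otu_id, .keep_all = TRUE)

  cand_conflict <- intersect(verified, hits$otu_id)
  if (length(cand_conflict) > 0) {
    abort(sprintf(
      "Verified candidate OTU(s) also match a taxonomy guild pattern: %s",
      paste(cand_conflict, collapse = ", ")),
      class = "nitribalance_guild_conflict")
  }

  taxonomy |>
    dplyr::transmute(otu_id = .data$otu_id) |>
    dplyr::left_join(hits, by = "otu_id") |>
    dplyr::mutate(
      guild = dplyr::case_when(
        .data$otu_id %in% verified ~ "NOB_candidate",
        !is.na(.data$guild) ~ .data$guild,
        TRUE ~ "other"
      ),
      provenance = dplyr::case_when(
        .data$otu_id %in% verified ~ "verified candidate list",
        !is.na(.data$provenance) ~ .data$provenance,
        TRUE ~ "no pattern matched"
      )
    )
}
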