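# Small in-code fixtures shared across test files.

tiny_params <- function(...) {
  args <- list(n_cores = 2, depths_cm = seq(5, 45, by = 10), opd_cm = 30,
               background_otus = 5, read_depth = 2000, seed = 11)
  do.call(synthetic_params, utils::modifyList(args, list(...)))
}

# Query plus reads sitting exactly on the screening boundaries.
screen_fixture <- function() {
  withr::with_seed(51, {
    query <- random_dna(1000)
    list(
      query = query,
      len200 = substr(query, 1, 200),          # exactly 200 bp, 100% id
      len201 = substr(query, 1, 201),          # 201 bp, 100% id
      id950 = mutate_seq(query, seq(10, 990, by = 20)),   # 50 changes, 95.0%
      id951 = mutate_seq(query, seq(10, 970, by = 20)),   # 49 changes, 95.1%
      junk = strrep("A", 50)                   # short filler, never aligned
    )
  })
}

# Run the analysis stages (guilds -> relative -> absolute -> zones) on a
# generated dataset, returning the pieces tests need.
analyse_dataset <- function(dataset, opd_from = c("truth", "inferred")) {
  opd_from <- match.arg(opd_from)
  gm <- assign_guilds(dataset$taxonomy, guild_config(),
                      dataset$verified_candidate_otus)
  rel <- relative_abundances(dataset$otu_table, gm)
  ab <- absolute_abundances(rel, dataset$samples)
  opd <- if (opd_from == "truth") {
    tibble::tibble(core_id = unique(dataset$samples$core_id),
                   opd_cm = dataset$params$opd_cm)
  } else {
    infer_opd(dataset$geochem)
  }
  zones <- split_redox_zones(dataset$samples, opd)
  list(guild_map = gm, rel = rel, abs = ab, zones = zones)
}

bootstrap_ci_of <- function(x, seed) {
  s <- summarize_ratios(x, theoretical_band(), ci_level = 0.9,
                        n_boot = 300, seed = seed)
  c(s$ci_low, s$ci_high)
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(purrr::imap(seqs, function(s, nm) c(paste0(">", nm), s))),
             path)
  path
}
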