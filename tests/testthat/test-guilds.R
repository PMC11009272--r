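toy_taxonomy <- function() {
  tibble::tribble(
    ~otu_id, ~domain, ~phylum, ~class, ~order, ~family, ~genus,
    "OTU_1", "Archaea", "Crenarchaeota", "c", "o", "Nitrosopumilaceae", "g",
    "OTU_3", "Bacteria", "Nitrospirota", "c", "o", "nitrospiraceae", "g",
    "OTU_5", "Bacteria", "Nitrospinota", "c", "o", "NITROSPINACEAE", "g",
    "OTU_4", "Bacteria", "Schekmanbacteria", "c", "o", "f", "g",
    "OTU_8", "Bacteria", "Schekmanbacteria", "c", "o", "f", "g",
    "OTU_9", "Bacteria", "Planctomycetota", "c", "Brocadiales", "f", "g",
    "OTU_x", "unclassified", "unclassified", "unclassified", "unclassified",
    "unclassified", "unclassified"
  )
}

test_that("guild assignment is total, case-insensitive, and verification-filtered", {
  gm <- assign_guilds(toy_taxonomy(), guild_config(),
                      verified_candidate_otus = "OTU_4")
  g <- setNames(gm$guild, gm$otu_id)
  expect_identical(g[["OTU_1"]], "AOA")
  expect_identical(g[["OTU_3"]], "NOB_Nitrospiraceae")
  expect_identical(g[["OTU_5"]], "NOB_Nitrospinaceae")
  expect_identical(g[["OTU_4"]], "NOB_candidate")
  # putative candidate phylum but NOT verified -> other
  expect_identical(g[["OTU_8"]], "other")
  expect_identical(g[["OTU_9"]], "anammox")
  expect_identical(g[["OTU_x"]], "other")
  expect_setequal(gm$otu_id, toy_taxonomy()$otu_id)  # total function
})

test_that("guild assignment warns on unknown candidate ids and errors on conflicts", {
  expect_warning(
    assign_guilds(toy_taxonomy(), guild_config(),
                  verified_candidate_otus = c("OTU_4", "OTU_404")),
    "OTU_404")
  # one OTU matching two guild patterns is a hard error
  cfg <- guild_config(anammox_order = "o")
  expect_error(assign_guilds(toy_taxonomy(), cfg),
               class = "nitribalance_guild_conflict")
  # a verified candidate that also matches a taxonomy pattern is a conflict
  expect_error(assign_guilds(toy_taxonomy(), guild_config(),
                             verified_candidate_otus = "OTU_1"),
               class = "nitribalance_guild_conflict")
})

test_that("pattern order never changes the assignment", {
  cfg <- guild_config()
  gm1 <- assign_guilds(toy_taxonomy(), cfg, "OTU_4")
  gm2 <- assign_guilds(toy_taxonomy(), cfg[rev(seq_len(nrow(cfg))), ], "OTU_4")
  expect_identical(dplyr::arrange(gm1, otu_id)$guild,
                   dplyr::arrange(gm2, otu_id)$guild)
})

test_that("pairwise identity matches hand examples and is symmetric", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT")$identity_percent, 100)
  expect_equal(pairwise_identity("ACGT", "ACGA")$identity_percent, 75)
  expect_error(pairwise_identity("", "ACGT"),
               class = "nitribalance_parameter_error")
  withr::with_seed(13, {
    for (k in 1:10) {
      a <- random_dna(sample(5:30, 1))
      b <- random_dna(sample(5:30, 1))
      ab <- pairwise_identity(a, b)
      ba <- pairwise_identity(b, a)
      expect_equal(ab$identity_percent, ba$identity_percent)
      expect_equal(ab$alignment_length, ba$alignment_length)
    }
  })
})

test_that("a short amplicon is scored over its overlap with a long gene", {
  gene <- withr::with_seed(7, random_dna(300))
  amplicon <- substr(gene, 101, 200)
  expect_equal(pairwise_identity(amplicon, gene)$identity_percent, 100)
})

test_that("pairwise identity agrees with the exhaustive DP oracle on short sequences", {
  withr::with_seed(17, {
    checked <- 0
    while (checked < 40) {
      a <- random_dna(sample(2:8, 1))
      b <- random_dna(sample(2:8, 1))
      oracle <- nw_overlap_identity_set(a, b)
      if (is.null(oracle)) next
      got <- pairwise_identity(a, b)$identity_percent
      expect_true(any(abs(oracle - got) < 1e-6),
                  label = sprintf("identity %s vs %s: got %.3f, oracle {%s}",
                                  a, b, got, paste(round(oracle, 3), collapse = ", ")))
      checked <- checked + 1
    }
  })
})

test_that("MAG-to-OTU linking picks the best hit with documented tie-breaks", {
  mag <- withr::with_seed(23, random_dna(1000))
  otus <- c(
    OTU_4 = mag,                                        # exact match
    OTU_235 = withr::with_seed(24, mutate_seq(mag, c(200, 400, 600, 800))),
    OTU_9 = withr::with_seed(25, random_dna(1000))
  )
  link <- link_mag_to_otus(mag, otus, min_identity = 95)
  expect_identical(link$otu_id, "OTU_4")
  expect_equal(link$identity_percent, 100)

  # 4 mismatches over 1000 aligned columns -> 99.6%
  link2 <- link_mag_to_otus(otus[["OTU_235"]], otus[c("OTU_4", "OTU_9")])
  expect_equal(link2$identity_percent, 99.6)

  # below the identity floor -> no link
  none <- link_mag_to_otus(mag, otus["OTU_9"], min_identity = 95)
  expect_true(is.na(none$otu_id))

  # exact tie broken lexicographically
  tie <- link_mag_to_otus(mag, c(OTU_b = mag, OTU_a = mag))
  expect_identical(tie$otu_id, "OTU_a")
})
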