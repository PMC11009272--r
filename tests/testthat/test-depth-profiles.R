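toy_otu <- function() {
  tibble::tibble(otu_id = c("OTU_1", "OTU_2", "OTU_3"),
                 s1 = c(5L, 5L, 10L), s2 = c(0L, 10L, 10L))
}
toy_map <- function() {
  tibble::tibble(otu_id = c("OTU_1", "OTU_2", "OTU_3"),
                 guild = c("AOA", "AOA", "NOB_Nitrospinaceae"),
                 provenance = "test")
}

test_that("relative abundances are count fractions summed over guild members", {
  rel <- relative_abundances(toy_otu(), toy_map())
  get <- function(s, g) rel$rel_abund[rel$sample_id == s & rel$guild == g]
  expect_equal(get("s1", "AOA"), 0.5)
  expect_equal(get("s1", "NOB_Nitrospinaceae"), 0.5)
  expect_equal(get("s2", "AOA"), 0.5)
  # per-sample conservation across all guilds
  sums <- rel |> dplyr::summarise(s = sum(rel_abund), .by = sample_id)
  expect_equal(sums$s, rep(1, 2), tolerance = 1e-12)

  zero <- toy_otu()
  zero$s1 <- 0L
  err <- tryCatch(relative_abundances(zero, toy_map()), error = identity)
  expect_s3_class(err, "nitribalance_format_error")
  expect_match(conditionMessage(err), "s1")
})

test_that("absolute abundance is relative times qPCR total and is linear in qPCR", {
  rel <- relative_abundances(toy_otu(), toy_map())
  samples <- tibble::tibble(sample_id = c("s1", "s2"), core_id = "c1",
                            depth_cm = c(1, 10),
                            qpcr_arch = c(4e7, 1e7), qpcr_bac = c(6e7, 1e7))
  ab <- absolute_abundances(rel, samples)
  expect_equal(ab$abs_abund[ab$sample_id == "s1" & ab$guild == "AOA"], 5e7)
  rel25 <- tibble::tibble(sample_id = "s1", guild = "AOA", rel_abund = 0.25)
  expect_equal(absolute_abundances(rel25, samples)$abs_abund, 2.5e7)

  doubled <- dplyr::mutate(samples, qpcr_arch = qpcr_arch * 2,
                           qpcr_bac = qpcr_bac * 2)
  expect_equal(absolute_abundances(rel, doubled)$abs_abund, 2 * ab$abs_abund)

  expect_error(absolute_abundances(rel, samples[1, ]),
               class = "nitribalance_format_error")
})

test_that("OPD inference interpolates linearly and flags unbounded profiles", {
  g <- tibble::tibble(core_id = "c1", depth_cm = c(0, 9, 18, 30),
                      o2_uM = c(10, 5, 0, 0))
  expect_equal(infer_opd(g, threshold_uM = 1)$opd_cm, 9 + (5 - 1) / 5 * 9)
  expect_equal(infer_opd(g, threshold_uM = 0)$opd_cm, 18)

  deep <- tibble::tibble(core_id = "c1", depth_cm = c(0, 10, 20),
                         o2_uM = c(100, 80, 60))
  res <- infer_opd(deep, threshold_uM = 1)
  expect_equal(res$opd_cm, 20)
  expect_true(res$unbounded)

  no_o2 <- tibble::tibble(core_id = "c1", depth_cm = c(0, 10))
  expect_error(infer_opd(no_o2), class = "nitribalance_format_error")
})

test_that("redox zoning is a partition with a closed oxic boundary", {
  samples <- tibble::tibble(sample_id = c("a", "b", "c"), core_id = "c1",
                            depth_cm = c(5, 16.2, 250),
                            qpcr_arch = 1, qpcr_bac = 1)
  z <- split_redox_zones(samples, tibble::tibble(core_id = "c1", opd_cm = 16.2))
  expect_identical(z$zone, c("oxic", "oxic", "anoxic"))
  expect_equal(nrow(z), nrow(samples))   # every sample labelled exactly once
  expect_error(
    split_redox_zones(dplyr::mutate(samples, core_id = "c9"),
                      tibble::tibble(core_id = "c1", opd_cm = 1)),
    class = "nitribalance_format_error")
})

test_that("depth averaging matches hand values and the analytic oracle", {
  expect_equal(depth_averaged_abundance(c(0, 1), c(0, 100)), 0.5)
  expect_equal(depth_averaged_abundance(c(3, 3, 3, 3), c(0, 7, 11, 40)), 3)
  # hand trapezoid: ((1+2)/2 * 10 + (2+4)/2 * 30) / 40 = 105 / 40
  expect_equal(depth_averaged_abundance(c(1, 2, 4), c(0, 10, 40)), 2.625)
  expect_error(depth_averaged_abundance(1, 5),
               class = "nitribalance_parameter_error")

  withr::with_seed(31, {
    for (k in 1:100) {
      n <- sample(3:12, 1)
      z <- sort(runif(n, 0, 300))
      while (any(diff(z) == 0)) z <- sort(runif(n, 0, 300))
      v <- runif(n, 0, 50)
      want <- analytic_piecewise_linear_integral(v, z) / (z[n] - z[1])
      expect_true(abs(depth_averaged_abundance(v, z) - want) < 1e-10)
    }
  })
})

test_that("NOB composition fractions sum to one and recover f_candidate", {
  d <- generate_dataset(tiny_params(qpcr_sigma = 0, background_otus = 0,
                                    f_candidate = 0.65,
                                    amplicon_model = "expected"))
  an <- analyse_dataset(d)
  comp <- nob_composition(an$abs, an$zones)
  sums <- comp$per_sample |>
    dplyr::summarise(s = sum(fraction), .by = sample_id)
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)
  oxic_cand <- comp$per_sample |>
    dplyr::filter(zone == "oxic", guild == "NOB_candidate")
  expect_equal(oxic_cand$fraction, rep(0.65, nrow(oxic_cand)),
               tolerance = 1e-9)
  avg_cand <- comp$depth_averaged |>
    dplyr::filter(guild == "NOB_candidate")
  expect_equal(avg_cand$fraction, rep(0.65, nrow(avg_cand)), tolerance = 1e-9)
})

test_that("noise-free pipeline recovers the true absolute abundances", {
  d <- generate_dataset(tiny_params(qpcr_sigma = 0,
                                    amplicon_model = "expected"))
  an <- analyse_dataset(d)
  aoa <- an$abs |> dplyr::filter(guild == "AOA") |>
    dplyr::arrange(match(sample_id, d$truth$sample_id))
  expect_equal(aoa$abs_abund, d$truth$aoa, tolerance = 1e-9)
})
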