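test_that("theoretical band modes give the established and trait-derived values", {
  lit <- theoretical_band()
  expect_equal(c(lit$low, lit$central, lit$high), c(2.6, 6.9, 15.8))
  comp <- theoretical_band(mode = "computed")
  expect_equal(comp$low, 1.6 / 0.63, tolerance = 1e-12)
  expect_equal(comp$central, 2.3 / 0.30, tolerance = 1e-12)
  expect_equal(comp$high, 3.1 / 0.20, tolerance = 1e-12)
  one <- theoretical_band(trait_set(c(1, 1, 1), c(1, 1, 1)), mode = "computed")
  expect_equal(c(one$low, one$central, one$high), c(1, 1, 1))
  expect_error(trait_set(yield_ratio = c(3, 2, 1)),
               class = "nitribalance_parameter_error")
})

test_that("sample ratios exclude zero-NOB samples and report them", {
  r <- sample_ratios(c(1e7, 2e6, 5e5), c(1e6, 0, 1e5))
  expect_equal(r$ratio, c(10, NA, 5))
  expect_identical(r$excluded, c(FALSE, TRUE, FALSE))
  expect_error(sample_ratios(c(1, 2), c(0, 0)),
               class = "nitribalance_format_error")
  expect_error(sample_ratios(1:3, 1:2), class = "nitribalance_parameter_error")
})

test_that("regression matches the closed-form OLS oracle in both intercept modes", {
  x <- c(1, 2, 4, 8, 9)
  expect_equal(fit_abundance_regression(26 * x, x)$slope, 26)
  expect_equal(fit_abundance_regression(26 * x, x)$r_squared, 1)
  f0 <- fit_abundance_regression(26 * x, x, with_intercept = FALSE)
  expect_equal(f0$slope, 26)
  expect_equal(f0$r_squared, 1)

  withr::with_seed(41, {
    for (k in 1:20) {
      n <- sample(5:40, 1)
      xx <- rlnorm(n, 14, 1)
      yy <- 3 * xx + rnorm(n, 0, mean(xx) * 0.2)
      for (wi in c(TRUE, FALSE)) {
        fit <- fit_abundance_regression(yy, xx, with_intercept = wi)
        want <- ols_closed_form(yy, xx, with_intercept = wi)
        expect_equal(fit$slope, want$slope, tolerance = 1e-9)
        expect_equal(fit$r_squared, want$r_squared, tolerance = 1e-9)
        if (wi) expect_equal(fit$intercept, want$intercept, tolerance = 1e-9)
      }
    }
  })
  expect_error(fit_abundance_regression(c(1, 2, 3), c(2, 2, 2)),
               class = "nitribalance_parameter_error")
})

test_that("regression slope converges to the true ratio as noise vanishes", {
  withr::with_seed(43, {
    x <- rlnorm(50, 14, 0.8)
    for (sigma in c(0.05, 0.005)) {
      y <- 3 * x * rlnorm(50, 0, sigma)
      fit <- fit_abundance_regression(y, x)
      expect_equal(fit$slope, 3, tolerance = 10 * sigma)
    }
  })
})

test_that("ratio summaries count band exceedance and bootstrap deterministically", {
  band <- theoretical_band()
  s <- summarize_ratios(c(1, 2, 3), band, n_boot = 200, seed = 5)
  expect_equal(s$median, 2)
  s2 <- summarize_ratios(rep(7, 10), band, n_boot = 200, seed = 5)
  expect_equal(c(s2$ci_low, s2$ci_high), c(7, 7))  # degenerate bootstrap
  s3 <- summarize_ratios(c(5, 20, 50), band, n_boot = 200, seed = 5)
  expect_equal(s3$n_above_band, 2L)
  expect_equal(s3$n_below_band, 0L)
  # above + in + below partitions the valid samples
  withr::with_seed(44, {
    r <- rlnorm(60, log(10), 1.5)
    s4 <- summarize_ratios(r, band, n_boot = 200, seed = 5)
    n_in <- sum(r >= band$low & r <= band$high)
    expect_equal(s4$n_above_band + n_in + s4$n_below_band, s4$n)
  })
  # seeded determinism
  a <- summarize_ratios(r, band, n_boot = 500, seed = 9)
  b <- summarize_ratios(r, band, n_boot = 500, seed = 9)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
  c2 <- summarize_ratios(r, band, n_boot = 500, seed = 10)
  expect_false(identical(a$ci_low, c2$ci_low))
})

test_that("reattribution inflates medians by exactly the candidate share", {
  d <- generate_dataset(tiny_params(r_true = 8, f_candidate = 0.6,
                                    qpcr_sigma = 0,
                                    amplicon_model = "expected"))
  an <- analyse_dataset(d)
  res <- reattribution_analysis(an$abs, an$zones, n_boot = 200, seed = 3)
  expect_equal(res$with$summary$median, 8, tolerance = 1e-9)
  expect_equal(res$without$summary$median, 20, tolerance = 1e-9)
  expect_equal(res$median_ratio_without_over_with, 1 / (1 - 0.6),
               tolerance = 1e-9)
  expect_equal(res$n_oxic_samples,
               sum(an$zones$zone == "oxic"))
})

test_that("an empty candidate guild leaves both arms identical, with a warning", {
  d <- generate_dataset(tiny_params(qpcr_sigma = 0,
                                    amplicon_model = "expected"))
  an <- analyse_dataset(d)
  ab <- dplyr::mutate(an$abs,
                      guild = ifelse(guild == "NOB_candidate", "other", guild))
  expect_warning(
    res <- reattribution_analysis(ab, an$zones, n_boot = 200, seed = 3),
    "identical")
  expect_equal(res$without$summary$median, res$with$summary$median)
  expect_equal(res$median_ratio_without_over_with, 1)
})

test_that("tidy and glance methods summarise fitted objects", {
  d <- generate_dataset(tiny_params(qpcr_sigma = 0))
  an <- analyse_dataset(d)
  res <- reattribution_analysis(an$abs, an$zones, n_boot = 200, seed = 3)
  td <- tidy(res)
  expect_identical(td$arm, c("without_candidate", "with_candidate"))
  expect_true(all(c("median", "ci_low", "ci_high", "slope") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$median_ratio_without_over_with,
               res$median_ratio_without_over_with)
  tr <- tidy(res$with$regression)
  expect_identical(tr$term, c("(Intercept)", "nob"))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_ratio_arms(res), "ggplot")
})
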