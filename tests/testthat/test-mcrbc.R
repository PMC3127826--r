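test_that("efficiency calibration recovers the amplification factor", {
  perfect <- data.frame(amount = 10^(0:-4), ct = 20 + 3.321928 * (0:4))
  fit <- calibrate_efficiency(perfect)
  expect_equal(fit$efficiency, 2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  slow <- data.frame(amount = 10^(0:-3), ct = 22 + 3.786 * (0:3))
  expect_equal(calibrate_efficiency(slow)$efficiency, 10^(1 / 3.786),
               tolerance = 1e-9)                      # = 1.836...
  expect_equal(round(calibrate_efficiency(slow)$efficiency, 3), 1.837)

  expect_error(calibrate_efficiency(perfect[1:2, ]), "at least 3")
  inverted <- data.frame(amount = 10^(0:-3), ct = 30 - 2 * (0:3))
  expect_error(calibrate_efficiency(inverted), "non-negative")
})

test_that("percent methylation matches the delta-Ct closed form and flags", {
  expect_equal(percent_methylation(25, 25, 2)$percent, 0)
  expect_equal(percent_methylation(26, 25, 2)$percent, 50)
  expect_equal(percent_methylation(29, 25, 1.9)$percent,
               100 * (1 - 1.9^-4))                    # 92.33%
  expect_equal(round(percent_methylation(29, 25, 1.9)$percent, 2), 92.33)

  neg <- percent_methylation(24.5, 25, 2)
  expect_equal(neg$raw, 100 * (1 - 2^0.5))            # -41.42%
  expect_equal(neg$percent, 0)
  expect_identical(neg$flags, "negative_clamped")

  sent <- percent_methylation(NA, 25, 2)
  expect_equal(sent$percent, 100)
  expect_identical(sent$flags, "low_template")
  expect_identical(percent_methylation(NA, NA, 2)$flags, "not_evaluated")
  expect_error(percent_methylation(25, 24, 1), "efficiency")
})

test_that("percent methylation is monotone and bounded (property)", {
  dct <- seq(-2, 12, by = 0.25)
  pm <- percent_methylation(25 + dct, 25, 1.9)$percent
  expect_true(all(diff(pm[dct >= 0]) > 0 | pm[dct >= 0][-1] == 100))
  expect_true(all(pm >= 0 & pm <= 100))
  # increasing in efficiency for fixed positive delta Ct
  es <- seq(1.5, 2, by = 0.1)
  pe <- vapply(es, function(e) percent_methylation(28, 25, e)$percent, 0)
  expect_true(all(diff(pe) > 0))
  # raw (unclamped) values can be negative but never yield percent outside range
  expect_true(all(percent_methylation(25 + dct, 25, 2)$percent <= 100))
})

test_that("replicate aggregation reports digestion-aware mean, SE and QC", {
  same <- aggregate_replicates(c(60, 60, 60))
  expect_equal(same$percent, 60); expect_equal(same$se, 0)

  one <- aggregate_replicates(c(50, 60, 70))
  expect_equal(one$percent, 60)
  expect_equal(one$se, sd(c(50, 60, 70)) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(one$se, 2), 5.77)

  two <- aggregate_replicates(c(50, 60, 70, 80), digestion = c(1, 1, 2, 2))
  expect_equal(two$percent, mean(c(55, 75)))
  expect_equal(two$se, sd(c(55, 75)) / sqrt(2))

  qc <- aggregate_replicates(c(95, 96, 97), mcrbc_ct = c(38, 38.2, 37.9))
  expect_true(is.na(qc$percent))
  expect_match(qc$flags, "low_template")
  noisy <- aggregate_replicates(c(50, 60), mcrbc_ct = c(26, 30))
  expect_match(noisy$flags, "low_template")
  ok <- aggregate_replicates(c(50, 60), mcrbc_ct = c(28, 28.4))
  expect_identical(ok$flags, "")
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})

test_that("group comparison matches a textbook Welch t computation", {
  idem <- compare_groups(c(10, 11, 12), c(10, 11, 12))
  expect_equal(idem$difference, 0)
  expect_false(idem$significant)

  a <- c(10, 12, 11); b <- c(20, 22, 21)
  got <- compare_groups(a, b)
  # independent oracle: Welch statistic from first principles
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_manual <- (mean(a) - mean(b)) / se
  df_manual <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(abs(t_manual), df_manual, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(got$significant)

  const <- compare_groups(c(5, 5), c(7, 7))
  expect_equal(const$p, 0); expect_true(const$significant)
  expect_equal(compare_groups(c(5, 5), c(5, 5))$p, 1)
  expect_error(compare_groups(10, c(1, 2)), "at least 2")
})

test_that("sample-size calculation follows two-sample t power analysis", {
  expect_identical(required_sample_size(1, 1, 0.05, 0.8), 17L)
  # doubling the detectable difference cannot increase n
  ns <- vapply(c(0.5, 1, 2, 4), function(d) required_sample_size(2, d), 0L)
  expect_true(all(diff(ns) <= 0))
  expect_error(required_sample_size(1, 0), "positive")
})

test_that("estimate_methylation pairs treatments within digestions", {
  tab <- as_ct_table(data.frame(
    sample = "s", fragment = "f",
    treatment = rep(c("mock", "mcrbc"), each = 3),
    digestion = 1L, replicate = rep(paste0("r", 1:3), 2),
    ct = c(25, 25, 25, 27, 27, 27)))
  est <- estimate_methylation(tab, efficiency = 2)
  expect_equal(est$percent, 75)  # delta Ct 2 at E=2
  expect_equal(est$n_pcr_replicates, 3L)
})
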