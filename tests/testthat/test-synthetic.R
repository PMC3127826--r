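test_that("gen_reference is seed-deterministic, embeds motifs, hits target GC", {
  r1 <- gen_reference(3000, 0.5,
                      embedded_motifs = list(list(motif = "CACATG", pos = -1300)),
                      seed = 42)
  r2 <- gen_reference(3000, 0.5,
                      embedded_motifs = list(list(motif = "CACATG", pos = -1300)),
                      seed = 42)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(extract_fragment(r1, -1300, -1295), "CACATG")
  r3 <- gen_reference(3000, 0.5, seed = 43)
  expect_false(identical(r1$sequence, r3$sequence))

  big <- gen_reference(10000, 0.5, seed = 1)
  gc <- mean(seq_chars(big$sequence) %in% c("G", "C"))
  expect_gt(gc, 0.45); expect_lt(gc, 0.55)

  expect_error(gen_reference(3000, 0.5, seed = 1,
    embedded_motifs = list(list(motif = "CACATG", pos = -100),
                           list(motif = "CACATG", pos = -103))),
    "overlap")
})

test_that("gen_profile assigns exact per-context rates, blocks and offsets", {
  r <- std_promoter()
  zero <- gen_profile(r, base_rates = c(CG = 0, CHG = 0, CHH = 0))
  expect_true(all(zero$profile$p_red == 0))
  expect_true(all(zero$profile$p_green == 0))

  rates <- c(CG = 0.016, CHG = 0.169, CHH = 0.202)
  pair <- gen_profile(r, base_rates = rates,
                      blocks = list(list(start = -846, end = -651,
                                         override = 0.95)),
                      stripe_delta = 0.093)
  pf <- pair$profile
  inblk <- pf$pos >= -846 & pf$pos <= -651
  expect_true(all(pf$p_red[inblk] == 0.95))
  out <- pf[!inblk & pf$context != "unknown", ]
  # no sampling at this stage: rates hold exactly per context
  expect_equal(as.numeric(tapply(out$p_red, out$context, mean)[c("CG","CHG","CHH")]),
               unname(rates))
  expect_equal(pf$p_green, pmin(1, pf$p_red + 0.093))

  expect_error(gen_profile(r, blocks = list(
    list(start = -900, end = -700, override = 0.5),
    list(start = -800, end = -600, override = 0.9))),
    "conflicting")
})

test_that("context labels in profiles agree with classify_context", {
  r <- std_promoter(seed = 21)
  pf <- stripe_profile(gen_profile(r), "red")
  redo <- vapply(pf$pos, function(p) classify_context(r, p), character(1))
  expect_identical(pf$context, redo)
})

test_that("bisulfite clone generator honours conversion and methylation truth", {
  r <- std_promoter()
  frag <- c(-500, -301)
  p0 <- stripe_profile(gen_profile(r, base_rates = c(CG=0, CHG=0, CHH=0)), "red")
  cs0 <- gen_bisulfite_clones(p0, frag, 5, conversion_efficiency = 1,
                              seq_error_rate = 0, seed = 5)
  ref <- extract_fragment(r, frag[1], frag[2])
  expect_true(all(cs0$clones == convert_in_silico(ref)))

  p1 <- stripe_profile(gen_profile(r, base_rates = c(CG=1, CHG=1, CHH=1),
                                   unknown_rate = 1), "red")
  cs1 <- gen_bisulfite_clones(p1, frag, 5, conversion_efficiency = 1,
                              seq_error_rate = 0, seed = 6)
  expect_true(all(cs1$clones == ref))

  # binomial sampling oracle at p = 0.5
  ph <- stripe_profile(gen_profile(r, base_rates = c(CG=.5, CHG=.5, CHH=.5),
                                   unknown_rate = .5), "red")
  csh <- gen_bisulfite_clones(ph, frag, 1000, conversion_efficiency = 1,
                              seq_error_rate = 0, seed = 7)
  frac <- colMeans(csh$truth)
  se <- sqrt(0.25 / 1000)
  expect_true(all(abs(frac - 0.5) < 3 * se + 1e-12))

  expect_identical(
    gen_bisulfite_clones(p0, frag, 3, seed = 9)$clones,
    gen_bisulfite_clones(p0, frag, 3, seed = 9)$clones)
})

test_that("molecule pools follow the profile and the fraction shortcut", {
  r <- std_promoter()
  frag <- c(-846, -651)
  p0 <- stripe_profile(gen_profile(r, base_rates = c(CG=0, CHG=0, CHH=0)), "red")
  pool0 <- gen_molecule_pool(p0, frag, 50, seed = 1)
  expect_false(any(pool0$states))
  expect_equal(pool_nonamplifiable_fraction(pool0), 0)

  p1 <- stripe_profile(gen_profile(r, base_rates = c(CG=1, CHG=1, CHH=1),
                                   unknown_rate = 1), "red")
  pool1 <- gen_molecule_pool(p1, frag, 50, seed = 1)
  expect_true(all(pool1$states))
  expect_equal(pool_nonamplifiable_fraction(pool1), 1)

  p3 <- stripe_profile(gen_profile(r, base_rates = c(CG=.3, CHG=.3, CHH=.3),
                                   unknown_rate = .3), "red")
  pool3 <- gen_molecule_pool(p3, frag, 10000, seed = 2)
  expect_lt(abs(mean(pool3$states) - 0.3), 0.015)

  poolf <- gen_molecule_pool(p0, frag, 10000, seed = 3,
                             digestible_fraction = 0.4)
  f <- pool_nonamplifiable_fraction(poolf)
  expect_lt(abs(f - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
})

test_that("McrBC digestion model enforces the 40-3000 base pair window", {
  r <- std_promoter()
  frag <- c(-846, -651)
  # two methylated half-sites 20 bases apart: below minimum spacing, survives
  near <- manual_pool(matrix(TRUE, 1, 2), c(1L, 21L), r, frag)
  expect_equal(pool_nonamplifiable_fraction(near), 0)
  # 100 bases apart: cut
  far <- manual_pool(matrix(TRUE, 1, 2), c(1L, 101L), r, frag)
  expect_equal(pool_nonamplifiable_fraction(far), 1)
})

test_that("simulated Ct tables encode the surviving fraction exactly", {
  r <- std_promoter()
  frag <- c(-846, -651)
  # survivors 1/1024 at E = 2 -> delta Ct = 10 cycles
  states <- matrix(FALSE, 1024, 2)
  states[seq_len(1023), ] <- TRUE
  pool <- manual_pool(states, c(1L, 101L), r, frag)
  ct <- simulate_mcrbc_qpcr(pool, efficiency = 2, noise_sd = 0,
                            n_replicates = 1, seed = 1)
  dct <- ct$ct[ct$treatment == "mcrbc"] - ct$ct[ct$treatment == "mock"]
  expect_equal(dct, 10, tolerance = 1e-12)

  # nothing methylated -> delta Ct 0, estimator ~ 0%
  pool0 <- manual_pool(matrix(FALSE, 100, 2), c(1L, 101L), r, frag)
  ct0 <- simulate_mcrbc_qpcr(pool0, efficiency = 2, noise_sd = 0, seed = 1)
  est0 <- estimate_methylation(ct0, efficiency = 2)
  expect_equal(est0$percent, 0)

  # fully digested pool -> no-amplification sentinel
  ctF <- simulate_mcrbc_qpcr(manual_pool(matrix(TRUE, 10, 2), c(1L, 101L),
                                         r, frag),
                             noise_sd = 0, seed = 1)
  expect_true(all(is.na(ctF$ct[ctF$treatment == "mcrbc"])))
})
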