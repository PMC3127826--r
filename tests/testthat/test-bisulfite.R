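test_that("cytosine context classification matches brute force on all 3-mers", {
  ctx_for <- function(d1, d2) {
    r <- suppressWarnings(
      reference_region("t", paste0("AC", d1, d2), atg_index = 1))
    classify_context(r, 2)
  }
  # independent oracle: direct rule on the following dinucleotide
  oracle <- function(d1, d2)
    if (d1 == "G") "CG" else if (d2 == "G") "CHG" else "CHH"
  bases <- c("A", "C", "G", "T")
  got <- character(0)
  for (d1 in bases) for (d2 in bases) {
    lab <- ctx_for(d1, d2)
    expect_identical(lab, oracle(d1, d2))
    got <- c(got, lab)
  }
  expect_equal(unname(table(got)[c("CG", "CHG", "CHH")]),
               c(4L, 3L, 9L), ignore_attr = TRUE)
})

test_that("context edge cases: sequence end and N", {
  r <- suppressWarnings(reference_region("t", "ACTAC", atg_index = 1))
  expect_identical(classify_context(r, 5), "unknown")  # C at final position
  r2 <- suppressWarnings(reference_region("t", "ACNT", atg_index = 1))
  expect_identical(classify_context(r2, 2), "unknown")
  rcg <- suppressWarnings(reference_region("t", "ACG", atg_index = 1))
  expect_identical(classify_context(rcg, 2), "CG")     # CG needs one base
  expect_error(classify_context(r, 1), "not a cytosine")
})

test_that("in-silico conversion flips exactly the unmethylated cytosines", {
  expect_identical(convert_in_silico("ACGC"), "ATGT")
  expect_identical(convert_in_silico("ACGC", methylated_positions = 2), "ACGT")
  expect_identical(convert_in_silico("AGTT"), "AGTT")
  expect_error(convert_in_silico("ACGC", methylated_positions = 1),
               "must all be cytosines")
})

test_that("clone alignment maps converted clones and flags bad ones", {
  ref <- "TAGCATCGGATCAGTACGGT"
  conv <- convert_in_silico(ref)
  al <- align_clone(conv, ref)
  expect_true(al$accepted)
  expect_identical(al$clone_bases, seq_chars(conv))

  # single-base deletion: one reference position gapped, rest unshifted
  del <- paste0(substr(conv, 1, 9), substr(conv, 11, nchar(conv)))
  ald <- align_clone(del, ref)
  expect_true(ald$accepted)
  expect_equal(sum(ald$clone_bases == "-"), 1L)
  kept <- ald$clone_bases != "-"
  expect_identical(paste(ald$clone_bases[kept], collapse = ""), del)

  rc <- align_clone(revcomp(conv), ref)
  expect_false(rc$accepted)
  expect_match(rc$reason, "identity")

  short <- align_clone(substr(conv, 1, 10), ref)
  expect_false(short$accepted)
  expect_match(short$reason, "length")
  expect_error(align_clone("", ref), "empty clone")
})

test_that("methylation calls map clone bases to states", {
  expect_identical(call_methylation("C", c("C", "T", "-", "A", "N")),
                   c("methylated", "unmethylated", "ambiguous",
                     "ambiguous", "ambiguous"))
  expect_error(call_methylation("G", "C"), "must be C")
})

test_that("region summaries count, partition and percentage correctly", {
  r <- toy_region(upstream = "AATCGATTGA", downstream = "ATGAAA")
  # one C at -7 (the C of TCG); clones: one methylated, one converted
  frag <- c(-10, -1)
  ref <- extract_fragment(r, frag[1], frag[2])
  cs <- bisulfite_clone_set(
    c(a = ref, b = convert_in_silico(ref)), r, frag, sample = "g")
  s <- summarize_region(call_clone_set(cs))
  expect_equal(nrow(s$per_position), 1L)
  expect_equal(s$per_position$percent, 50)
  expect_equal(s$region_wide, 50)
  # conservation: calls partition the clone count at every position
  expect_true(all(with(s$per_position,
    n_methylated + n_unmethylated + n_ambiguous) == s$n_clones))
})

test_that("per-context estimates recover generator truth within 3 binomial SEs", {
  r <- std_promoter(seed = 17)
  truth <- c(CG = 0.016, CHG = 0.169, CHH = 0.202)
  pf <- stripe_profile(gen_profile(r, base_rates = truth), "red")
  cs <- gen_bisulfite_clones(pf, c(-1007, -684), 48,
                             conversion_efficiency = 1, seq_error_rate = 0,
                             seed = 18)
  s <- summarize_region(call_clone_set(cs))
  pc <- s$per_context
  for (ctx in names(truth)) {
    row <- pc[pc$context == ctx, ]
    se <- binom_se_pct(truth[[ctx]], row$n_unambiguous)
    expect_lt(abs(row$percent - 100 * truth[[ctx]]), 3 * se + 1e-9)
  }
})

test_that("estimator is unbiased over repeated clone sets (property)", {
  r <- std_promoter(seed = 30)
  truth <- c(CG = 0.1, CHG = 0.2, CHH = 0.3)
  pf <- stripe_profile(gen_profile(r, base_rates = truth), "red")
  errs <- t(vapply(1:60, function(k) {
    cs <- gen_bisulfite_clones(pf, c(-400, -201), 8,
                               conversion_efficiency = 1, seq_error_rate = 0,
                               seed = 1000 + k)
    pc <- summarize_region(call_clone_set(cs))$per_context
    vapply(names(truth), function(ctx)
      pc$percent[pc$context == ctx] - 100 * truth[[ctx]], 0)
  }, numeric(3)))
  mc_se <- apply(errs, 2, sd) / sqrt(nrow(errs))
  expect_true(all(abs(colMeans(errs)) < 3.5 * mc_se))
})

test_that("stripe comparison recovers uniform offsets and handles ties", {
  r <- std_promoter(seed = 19)
  pair0 <- gen_profile(r, stripe_delta = 0)
  mk <- function(pair, side, seed, n = 24)
    summarize_region(call_clone_set(gen_bisulfite_clones(
      stripe_profile(pair, side), c(-1007, -684), n,
      conversion_efficiency = 1, seq_error_rate = 0, seed = seed,
      sample = side)))
  same <- mk(pair0, "red", 1)
  idem <- compare_stripes(same, same)
  expect_equal(idem$difference, 0)
  expect_equal(idem$fraction_green_higher, 0)  # ties never in the numerator

  # extreme case: all-methylated green vs all-unmethylated red
  pg <- gen_profile(r, base_rates = c(CG = 0, CHG = 0, CHH = 0),
                    stripe_delta = 1)
  extreme <- compare_stripes(mk(pg, "green", 2), mk(pg, "red", 3))
  expect_equal(extreme$difference, 100)
  expect_equal(extreme$fraction_green_higher, 100)

  # offset recovery at the 9.3-point scale
  pairo <- gen_profile(r, stripe_delta = 0.093)
  g <- mk(pairo, "green", 4); rr <- mk(pairo, "red", 5)
  cmpst <- compare_stripes(g, rr)
  se <- sqrt(binom_se_pct(g$region_wide / 100, g$n_calls_unambiguous)^2 +
             binom_se_pct(rr$region_wide / 100, rr$n_calls_unambiguous)^2)
  expect_lt(abs(cmpst$difference - 9.3), 3 * se)

  bad <- mk(pair0, "red", 6)
  bad$per_position <- bad$per_position[-1, ]
  expect_error(compare_stripes(same, bad), "different cytosine positions")
})

test_that("degenerate primers pass the bias check and fixed bases fail", {
  # reference whose 5' end realizes the degenerate forward primer with C at
  # each Y position (the situation the degeneracy is designed for)
  head <- "TGGAGTTAAATTAACAAGGC"
  r <- toy_region(upstream = paste0(head, "GATTAGGATTAAGGATTTTA"),
                  downstream = "ATGAAA")
  frag <- c(-40, -1)
  ok <- check_primer_bias("TGGAGTTAAATTAAYAAGGY", r, frag, "forward")
  expect_false(ok$biased)
  bad <- check_primer_bias(head, r, frag, "forward")  # fixed C over ref C
  expect_true(bad$biased)
  expect_equal(length(bad$positions), 2L)
  expect_error(check_primer_bias("GGGGGGGGGG", r, frag, "forward"),
               "not locatable")
})

test_that("reverse primers are checked in top-strand sense", {
  # fragment 3' end ...GGGCTAGGA; reverse primer = revcomp with R over the
  # top-strand C (reads G or A on its own strand)
  r <- toy_region(upstream = "ATTAGATTAGGGGCTAGGA", downstream = "ATGAAA")
  frag <- c(-19, -1)
  ok <- check_primer_bias("TCCTARCCCC", r, frag, "reverse")
  # top-strand sense GGGGYTAGGA: Y over the single reference C
  expect_false(ok$biased)
  biased <- check_primer_bias("TCCTAGCCCC", r, frag, "reverse")
  expect_true(biased$biased)
})

test_that("motif methylation contrasts motif interior against flanks", {
  r <- gen_reference(600, 0.4, atg_index = 451,
                     embedded_motifs = list(list(motif = "CACATG", pos = -200)),
                     seed = 55)
  pair <- gen_profile(r, base_rates = c(CG = .8, CHG = .8, CHH = .8),
                      unknown_rate = .8,
                      blocks = list(list(start = -200, end = -195,
                                         override = 0)))
  cs <- gen_bisulfite_clones(stripe_profile(pair, "red"), c(-260, -141), 200,
                             conversion_efficiency = 1, seq_error_rate = 0,
                             seed = 56)
  s <- summarize_region(call_clone_set(cs))
  mm <- motif_methylation(s, data.frame(start = -200, end = -195), flank = 10)
  expect_identical(mm$status, "ok")
  expect_equal(mm$inside_percent, 0)
  expect_gt(mm$flank_percent, 70); expect_lt(mm$flank_percent, 90)

  skipped <- motif_methylation(s, data.frame(start = -150, end = -130))
  expect_match(skipped$status, "skipped")

  # motif window containing no cytosines (the TG of the E-box)
  noc <- motif_methylation(s, data.frame(start = -196, end = -195))
  expect_match(noc$status, "no scorable cytosines")
})
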