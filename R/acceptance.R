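# Parameter-recovery reproduction experiments.
#
# Wet-lab measurements cannot be recomputed, so the package validates its
# estimators by simulation at the study's own operating points: per-context
# methylation levels (CHH 20.2%, CHG 16.9%, CG 1.6%), green-minus-red stripe
# offsets (9.3 points in -1007..-684, 5.2 in -534..-184), and the 95%
# McrBC-digestible fraction of the -846..-651 fragment.  Each experiment
# simulates data under those truths, runs the corresponding estimator, and
# reports estimate, truth and the binomial/replicate standard error.
# Conversion failure and sequencing error are switched off here: the
# tolerance of these experiments is the binomial sampling SE, which presumes
# an unbiased draw (the small biases those artefacts introduce are exercised
# separately in the unit tests).

acc_reference <- function(seed) {
  gen_reference(1200, gc_fraction = 0.38, atg_index = 1101L, seed = seed)
}

ACC_BS_FRAGMENTS <- list(c(-1007, -684), c(-534, -184))
ACC_CONTEXT_TRUTH <- c(CG = 0.016, CHG = 0.169, CHH = 0.202)
ACC_STRIPE_OFFSET <- c(`-1007..-684` = 0.093, `-534..-184` = 0.052)
ACC_MCRBC_FRAGMENT <- c(-846, -651)
ACC_MCRBC_TRUTH <- 0.95

#' Per-context methylation recovery experiment
#'
#' Simulates 48 bisulfite clones over each of the two analyzed promoter
#' amplicons with every cytosine's methylation probability set to its
#' context's overall truth, pools both amplicons, and summarizes per
#' context.
#'
#' @param seed integer seed driving every random draw
#' @param n_clones clones per amplicon
#' @return data.frame: context, truth_percent, estimate_percent, se
#'   (binomial, percent scale), n (unambiguous calls)
#' @export
recovery_experiment_contexts <- function(seed, n_clones = 48) {
  region <- acc_reference(seed)
  profile <- stripe_profile(
    gen_profile(region, base_rates = ACC_CONTEXT_TRUTH), "red")
  sets <- lapply(seq_along(ACC_BS_FRAGMENTS), function(i)
    call_clone_set(gen_bisulfite_clones(
      profile, ACC_BS_FRAGMENTS[[i]], n_clones,
      conversion_efficiency = 1, seq_error_rate = 0,
      seed = seed + i)))
  pc <- summarize_region(sets)$per_context
  pc <- pc[pc$context %in% names(ACC_CONTEXT_TRUTH), ]
  truth <- ACC_CONTEXT_TRUTH[pc$context]
  data.frame(context = pc$context,
             truth_percent = 100 * unname(truth),
             estimate_percent = pc$percent,
             se = 100 * sqrt(truth * (1 - truth) / pc$n_unambiguous),
             n = pc$n_unambiguous, row.names = NULL)
}

#' Stripe-offset recovery experiment
#'
#' Simulates 24 red-stripe clones from the baseline per-context profile and
#' 24 green-stripe clones from baseline plus the region's reported uniform
#' offset, for each amplicon, and recovers the region-wide green-minus-red
#' difference with \code{\link{compare_stripes}}.
#'
#' @param seed integer seed
#' @param n_clones clones per stripe
#' @return data.frame: fragment, truth_diff (percent points),
#'   estimate_diff, se (combined binomial SE), n (calls per side)
#' @export
recovery_experiment_stripes <- function(seed, n_clones = 24) {
  region <- acc_reference(seed)
  rows <- lapply(seq_along(ACC_BS_FRAGMENTS), function(i) {
    frag <- ACC_BS_FRAGMENTS[[i]]
    label <- sprintf("%+d..%+d", frag[1], frag[2])
    offset <- ACC_STRIPE_OFFSET[[sprintf("%d..%d", frag[1], frag[2])]]
    pair <- gen_profile(region, base_rates = ACC_CONTEXT_TRUTH,
                        stripe_delta = offset)
    summ <- lapply(c(green = "green", red = "red"), function(side)
      summarize_region(call_clone_set(gen_bisulfite_clones(
        stripe_profile(pair, side), frag, n_clones,
        conversion_efficiency = 1, seq_error_rate = 0,
        seed = seed + 10L * i + (side == "green"), sample = side))))
    cmpst <- compare_stripes(summ$green, summ$red)
    se <- sqrt(sum(vapply(summ, function(s)
      (100 * sqrt((s$region_wide / 100) * (1 - s$region_wide / 100) /
                    s$n_calls_unambiguous))^2, 0)))
    data.frame(fragment = label, truth_diff = 100 * offset,
               estimate_diff = cmpst$difference, se = se,
               n = summ$green$n_calls_unambiguous)
  })
  do.call(rbind, rows)
}

#' McrBC estimator recovery experiment
#'
#' Simulates a molecule pool for the -846..-651 amplicon whose
#' McrBC-digestible fraction is 95% (the level reported for the stably
#' pigmented cultivars at this fragment), generates triplicate McrBC and
#' mock Cts over two independent digestions at efficiency 1.9 with 0.15
#' cycles of noise, and estimates percent methylation.
#'
#' @param seed integer seed
#' @param n_molecules pool size
#' @return one-row data.frame: truth_percent, estimate_percent, se
#'   (replicate SE and pool binomial SE combined), n
#' @export
recovery_experiment_mcrbc <- function(seed, n_molecules = 10000) {
  region <- acc_reference(seed)
  profile <- stripe_profile(
    gen_profile(region, base_rates = ACC_CONTEXT_TRUTH), "red")
  pool <- gen_molecule_pool(profile, ACC_MCRBC_FRAGMENT, n_molecules,
                            seed = seed + 50L,
                            digestible_fraction = ACC_MCRBC_TRUTH)
  ct <- simulate_mcrbc_qpcr(pool, efficiency = 1.9,
                            ct_at_full_template = 25, noise_sd = 0.15,
                            n_replicates = 3, n_digestions = 2,
                            seed = seed + 51L, sample = "stable_red")
  est <- estimate_methylation(ct, efficiency = 1.9)
  se_pool <- 100 * sqrt(ACC_MCRBC_TRUTH * (1 - ACC_MCRBC_TRUTH) / n_molecules)
  se_rep <- if (is.finite(est$se)) est$se else 0
  data.frame(truth_percent = 100 * ACC_MCRBC_TRUTH,
             estimate_percent = est$percent,
             se = sqrt(se_pool^2 + se_rep^2),
             n = n_molecules)
}
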