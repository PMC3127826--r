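# McrBC / real-time PCR percent-methylation estimation.
#
# McrBC cuts DNA carrying methylcytosine preceded by a purine when two such
# half-sites lie 40-3000 bp apart; comparing Ct values of McrBC-digested vs
# mock-digested template therefore estimates the fraction of template copies
# that carried a cuttable methylation configuration:
#
#   %M = 100 * (1 - E^-(Ct_McrBC - Ct_mock))
#
# with E the per-cycle amplification efficiency.  Negative raw values (McrBC
# Ct below mock Ct, i.e. measurement noise) are clamped to 0 and flagged.

#' Calibrate qPCR amplification efficiency from a dilution series
#'
#' Least-squares fit of Ct against log10(relative template amount); the
#' per-cycle amplification factor is \code{E = 10^(-1/slope)}.  A perfect
#' doubling assay has slope -3.32 cycles per 10-fold dilution (E = 2);
#' real assays in this system calibrated between 1.84 and 1.95.
#'
#' @param dilution_series data.frame (or list) with columns/elements
#'   \code{amount} (relative template amount, > 0) and \code{ct}
#' @return object of class \code{EfficiencyFit} with elements
#'   \code{efficiency}, \code{slope}, \code{r_squared}
#' @export
calibrate_efficiency <- function(dilution_series) {
  d <- as.data.frame(dilution_series)
  stopifnot(all(c("amount", "ct") %in% names(d)))
  if (any(d$amount <= 0)) stop("dilution amounts must be positive")
  if (length(unique(d$amount)) < 3L)
    stop("need at least 3 distinct dilution levels")
  fit <- stats::lm(ct ~ log10(amount), data = d)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("non-negative standard-curve slope; is the dilution series inverted?")
  # suppress lm's "essentially perfect fit" note: exact series are legal here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(efficiency = 10^(-1 / slope), slope = slope,
                 r_squared = r2),
            class = "EfficiencyFit")
}

#' @export
print.EfficiencyFit <- function(x, ...) {
  cat(sprintf("EfficiencyFit: E = %.3f (slope %.3f cycles/log10, R^2 %.4f)\n",
              x$efficiency, x$slope, x$r_squared))
  invisible(x)
}

effic_value <- function(e) {
  v <- if (inherits(e, "EfficiencyFit")) e$efficiency else e
  if (!is.numeric(v) || v <= 1 || v > 2)
    stop("efficiency must lie in (1, 2]")
  v
}

#' Percent methylation from a McrBC/mock Ct pair
#'
#' The surviving template fraction after digestion is
#' \code{E^-(ct_mcrbc - ct_mock)}; percent methylation is 100 times one minus
#' that fraction.  An \code{NA} McrBC Ct with a finite mock Ct is read as the
#' no-amplification sentinel (complete digestion): percent 100 with a
#' \code{low_template} flag.  Raw negatives are clamped to 0 and flagged
#' \code{negative_clamped}; a missing mock Ct yields \code{not_evaluated}.
#'
#' @param ct_mcrbc,ct_mock crossing thresholds (cycles); vectors recycle
#' @param efficiency amplification factor in (1,2] or an
#'   \code{EfficiencyFit}
#' @return data.frame with columns \code{percent} (in [0,100] or NA),
#'   \code{raw} (unclamped), \code{flags} (comma-joined subset of
#'   negative_clamped, low_template, not_evaluated)
#' @export
percent_methylation <- function(ct_mcrbc, ct_mock, efficiency = 2) {
  E <- effic_value(efficiency)
  n <- max(length(ct_mcrbc), length(ct_mock))
  ct_mcrbc <- rep_len(as.numeric(ct_mcrbc), n)
  ct_mock <- rep_len(as.numeric(ct_mock), n)
  raw <- 100 * (1 - E^(-(ct_mcrbc - ct_mock)))
  percent <- pmin(100, pmax(0, raw))
  flags <- character(n)
  neg <- !is.na(raw) & raw < 0
  flags[neg] <- "negative_clamped"
  sentinel <- is.na(ct_mcrbc) & !is.na(ct_mock)
  percent[sentinel] <- 100
  flags[sentinel] <- "low_template"
  dead <- is.na(ct_mock)
  percent[dead] <- NA_real_
  flags[dead] <- "not_evaluated"
  data.frame(percent = percent, raw = raw, flags = flags)
}

#' Aggregate replicate percent-methylation estimates
#'
#' Replicate structure follows the assay design: PCR replicates (typically
#' triplicate) nested in independent enzyme digestions (typically 2-3).  The
#' point estimate is the mean of digestion-level means; the SE is computed
#' across digestion means when more than one digestion is present, else
#' across PCR replicates.  Low-template QC: the estimate is withheld
#' (\code{percent = NA}, flag \code{low_template}) when the McrBC-side mean
#' Ct exceeds \code{ct_cutoff} or the McrBC replicate SD exceeds
#' \code{sd_cutoff} -- the regime in which a nearly fully digested template
#' makes quantification unreliable.
#'
#' @param percents replicate-level percent estimates
#' @param digestion optional grouping vector (same length); default treats
#'   all replicates as one digestion
#' @param mcrbc_ct optional raw McrBC-side Ct values backing the replicates,
#'   used for the QC rules
#' @param ct_cutoff,sd_cutoff QC thresholds (cycles)
#' @param sample,fragment labels carried into the result
#' @return one-row data.frame of class \code{MethylationEstimate}: columns
#'   sample, fragment, percent, se, flags, n_digestions, n_pcr_replicates
#' @export
aggregate_replicates <- function(percents, digestion = NULL,
                                 mcrbc_ct = NULL,
                                 ct_cutoff = 35, sd_cutoff = 1.5,
                                 sample = NA_character_,
                                 fragment = NA_character_) {
  percents <- as.numeric(percents)
  if (!length(percents)) stop("no replicate estimates to aggregate")
  digestion <- digestion %||% rep(1L, length(percents))
  stopifnot(length(digestion) == length(percents))

  flags <- character(0)
  keep <- !is.na(percents)
  if (!any(keep)) {
    flags <- "not_evaluated"
    est <- NA_real_; se <- NA_real_
  } else {
    dmeans <- tapply(percents[keep], digestion[keep], mean)
    est <- mean(dmeans)
    se <- if (length(dmeans) > 1L)
      stats::sd(dmeans) / sqrt(length(dmeans))
    else if (sum(keep) > 1L)
      stats::sd(percents[keep]) / sqrt(sum(keep))
    else NA_real_
  }
  if (!is.null(mcrbc_ct)) {
    cts <- mcrbc_ct[is.finite(mcrbc_ct)]
    high_ct <- (length(cts) && mean(cts) > ct_cutoff) ||
      length(cts) < length(mcrbc_ct)           # no-amplification sentinel(s)
    noisy <- length(cts) > 1L && stats::sd(cts) > sd_cutoff
    if (high_ct || noisy) {
      flags <- union(flags, "low_template")
      est <- NA_real_
      se <- NA_real_
    }
  }
  out <- data.frame(sample = sample, fragment = fragment,
                    percent = est, se = se,
                    flags = paste(flags, collapse = ","),
                    n_digestions = length(unique(digestion)),
                    n_pcr_replicates = length(percents))
  class(out) <- c("MethylationEstimate", "data.frame")
  out
}

#' Per-sample, per-fragment methylation estimates from a Ct table
#'
#' Pairs McrBC and mock Cts within each (sample, fragment, digestion) cell --
#' by replicate label when the labels match one-to-one, otherwise against the
#' digestion's mock mean -- converts each pair with
#' \code{\link{percent_methylation}} and aggregates with
#' \code{\link{aggregate_replicates}}.
#'
#' @param ct_table a \code{CtTable} (see \code{\link{read_ct_table}})
#' @param efficiency scalar efficiency, an \code{EfficiencyFit}, or a named
#'   vector/list keyed by fragment for per-amplicon calibration
#' @param ct_cutoff,sd_cutoff QC thresholds passed through
#' @return data.frame with one row per sample x fragment
#' @export
estimate_methylation <- function(ct_table, efficiency = 2,
                                 ct_cutoff = 35, sd_cutoff = 1.5) {
  df <- as.data.frame(ct_table)
  stopifnot(all(CT_COLUMNS %in% names(df)))
  if (is.null(df$digestion)) df$digestion <- 1L
  eff_for <- function(frag) {
    if (is.list(efficiency) ||
        (is.numeric(efficiency) && !is.null(names(efficiency)))) {
      e <- efficiency[[frag]]
      if (is.null(e)) stop("no efficiency supplied for fragment ", frag)
      e
    } else efficiency
  }
  cells <- unique(df[c("sample", "fragment")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- df[df$sample == cells$sample[i] & df$fragment == cells$fragment[i], ]
    E <- eff_for(cells$fragment[i])
    reps <- lapply(split(sub, sub$digestion), function(dg) {
      mc <- dg[dg$treatment == "mcrbc", ]
      mk <- dg[dg$treatment == "mock", ]
      if (!nrow(mc) || !nrow(mk)) return(NULL)
      paired <- nrow(mc) == nrow(mk) &&
        setequal(mc$replicate, mk$replicate)
      mock_ct <- if (paired) mk$ct[match(mc$replicate, mk$replicate)]
                 else rep(mean(mk$ct, na.rm = TRUE), nrow(mc))
      pm <- percent_methylation(mc$ct, mock_ct, E)
      data.frame(digestion = dg$digestion[dg$treatment == "mcrbc"],
                 percent = pm$percent, mcrbc_ct = mc$ct)
    })
    reps <- do.call(rbind, reps)
    if (is.null(reps))
      return(data.frame(sample = cells$sample[i],
                        fragment = cells$fragment[i],
                        percent = NA_real_, se = NA_real_,
                        flags = "not_evaluated",
                        n_digestions = 0L, n_pcr_replicates = 0L))
    aggregate_replicates(reps$percent, reps$digestion, reps$mcrbc_ct,
                         ct_cutoff = ct_cutoff, sd_cutoff = sd_cutoff,
                         sample = cells$sample[i],
                         fragment = cells$fragment[i])
  })
  do.call(rbind, res)
}

#' Compare two groups of methylation estimates
#'
#' Two-sided two-sample t-test (Welch by default; set \code{pooled = TRUE}
#' for the classical equal-variance test).  Groups in which every value is
#' identical short-circuit the t machinery: equal constants are "no
#' difference" (p = 1), distinct constants a sure difference (p = 0).
#'
#' @param group_a,group_b numeric vectors (>= 2 values each)
#' @param alpha significance level (the source analyses used p <= 0.05)
#' @param pooled use the pooled-variance t-test instead of Welch
#' @return data.frame: difference (mean_a - mean_b), t, df, p, significant
#' @export
compare_groups <- function(group_a, group_b, alpha = 0.05, pooled = FALSE) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  diff <- mean(a) - mean(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (diff == 0) 1 else 0
    return(data.frame(difference = diff, t = NA_real_, df = NA_real_,
                      p = p, significant = p <= alpha))
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  data.frame(difference = diff, t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             significant = tt$p.value <= alpha)
}

#' Required sample size for a two-group comparison
#'
#' Smallest per-group n for a two-sample t-test to detect
#' \code{detectable_difference} given the observed SD, at the requested
#' alpha and power.
#' @param observed_sd within-group SD (> 0)
#' @param detectable_difference smallest difference worth detecting (> 0)
#' @param alpha two-sided significance level
#' @param power target power
#' @return integer n per group
#' @export
required_sample_size <- function(observed_sd, detectable_difference,
                                 alpha = 0.05, power = 0.8) {
  stopifnot(observed_sd > 0, alpha > 0, alpha < 1, power > alpha, power < 1)
  if (detectable_difference <= 0)
    stop("detectable difference must be positive")
  pt <- stats::power.t.test(delta = detectable_difference, sd = observed_sd,
                            sig.level = alpha, power = power,
                            type = "two.sample")
  as.integer(ceiling(pt$n))
}
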