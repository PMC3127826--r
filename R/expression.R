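# Efficiency-corrected relative transcript quantification (Pfaffl form),
# normalized to a reference gene (actin in the source system).

#' Efficiency-corrected relative expression ratio
#'
#' Ratio of target transcript in sample a relative to sample b, normalized
#' to a reference gene:
#'
#'   ratio = E_target^(dCt_target) / E_ref^(dCt_ref),  dCt = mean(b) - mean(a)
#'
#' With both efficiencies equal to E this reduces to the familiar
#' E^-(ddCt).  The SE comes from first-order propagation of the replicate
#' Ct variances through the log ratio.
#'
#' @param target_cts_a,target_cts_b target-gene replicate Cts in samples a, b
#' @param ref_cts_a,ref_cts_b reference-gene replicate Cts
#' @param e_target,e_ref per-gene amplification efficiencies in (1,2]
#'   (scalars or \code{EfficiencyFit} objects; calibrated values in this
#'   system ranged 1.839-1.945)
#' @return data.frame: ratio, se, log_ratio, se_log
#' @export
relative_expression <- function(target_cts_a, target_cts_b,
                                ref_cts_a, ref_cts_b,
                                e_target = 2, e_ref = 2) {
  Et <- effic_value(e_target); Er <- effic_value(e_ref)
  for (v in list(target_cts_a, target_cts_b, ref_cts_a, ref_cts_b))
    if (!length(v) || anyNA(v)) stop("all replicate Cts must be present")
  d_target <- mean(target_cts_b) - mean(target_cts_a)
  d_ref <- mean(ref_cts_b) - mean(ref_cts_a)
  log_ratio <- d_target * log(Et) - d_ref * log(Er)
  var_mean <- function(x)
    if (length(x) > 1L) stats::var(x) / length(x) else 0
  se_log <- sqrt(log(Et)^2 * (var_mean(target_cts_a) + var_mean(target_cts_b)) +
                 log(Er)^2 * (var_mean(ref_cts_a) + var_mean(ref_cts_b)))
  ratio <- exp(log_ratio)
  data.frame(ratio = ratio, se = ratio * se_log,
             log_ratio = log_ratio, se_log = se_log)
}

#' Test whether expression ratios exceed one
#'
#' One-sided one-sample t-test of log(ratio) against zero across biological
#' replicate ratios.  Ratios are multiplicative, so testing on the log scale
#' treats x-fold up and down symmetrically.
#'
#' @param ratios biological-replicate expression ratios (>= 2, all > 0)
#' @param alpha significance level
#' @return data.frame: mean_ratio (geometric), t, df, p, significant
#' @export
ratio_greater_than_one_test <- function(ratios, alpha = 0.05) {
  r <- as.numeric(ratios)
  if (length(r) < 2L) stop("need at least 2 replicate ratios")
  if (any(r <= 0)) stop("ratios must be positive")
  lr <- log(r)
  if (stats::sd(lr) == 0) {
    p <- if (mean(lr) > 0) 0 else 1
    return(data.frame(mean_ratio = exp(mean(lr)), t = NA_real_,
                      df = NA_real_, p = p, significant = p <= alpha))
  }
  tt <- stats::t.test(lr, mu = 0, alternative = "greater")
  data.frame(mean_ratio = exp(mean(lr)), t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             significant = tt$p.value <= alpha)
}

#' Relative expression for every gene in a Ct table
#'
#' Expects a Ct-style TSV/data.frame with columns \code{gene},
#' \code{sample}, \code{replicate}, \code{ct}; computes, per non-reference
#' gene, the efficiency-corrected ratio of \code{sample_a} vs
#' \code{sample_b} normalized to \code{ref_gene}.
#'
#' @param df data.frame with gene/sample/replicate/ct columns
#' @param sample_a,sample_b the two samples to compare (a relative to b)
#' @param ref_gene reference (normalizer) gene name
#' @param efficiencies optional named vector of per-gene efficiencies;
#'   genes absent from it use \code{default_efficiency}
#' @param default_efficiency fallback efficiency
#' @return data.frame, one row per target gene: gene, ratio, se
#' @export
expression_table <- function(df, sample_a, sample_b, ref_gene = "actin",
                             efficiencies = NULL, default_efficiency = 2) {
  stopifnot(all(c("gene", "sample", "replicate", "ct") %in% names(df)))
  cts <- function(g, s) df$ct[df$gene == g & df$sample == s]
  if (!length(cts(ref_gene, sample_a)) || !length(cts(ref_gene, sample_b)))
    stop("missing reference-gene Cts for ", ref_gene)
  eff <- function(g) {
    e <- efficiencies[[g]] %||% default_efficiency
    effic_value(e)
  }
  genes <- setdiff(unique(df$gene), ref_gene)
  out <- lapply(genes, function(g) {
    r <- relative_expression(cts(g, sample_a), cts(g, sample_b),
                             cts(ref_gene, sample_a), cts(ref_gene, sample_b),
                             eff(g), eff(ref_gene))
    cbind(data.frame(gene = g), r)
  })
  do.call(rbind, out)
}
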