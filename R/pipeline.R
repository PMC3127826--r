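# End-to-end pipeline: simulate (or load) data -> McrBC estimates ->
# bisulfite summaries -> expression ratios -> feature scan -> report.
# Driven by a single YAML (or list) config; deterministic given config+seed.

#' Read and validate a pipeline configuration
#'
#' @param config a YAML file path or an already-parsed list.  Recognized
#'   blocks: \code{reference} (either \code{fasta}+\code{atg_index} or
#'   simulation parameters), \code{profile}, \code{bisulfite},
#'   \code{mcrbc}, \code{expression} (optional), \code{features},
#'   top-level \code{seed} and \code{outdir}.
#' @return validated config list
#' @export
read_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  if (is.null(cfg$seed)) stop("config must set a seed")
  if (is.null(cfg$reference))
    stop("config must contain a reference block")
  ref <- cfg$reference
  if (is.null(ref$fasta) && is.null(ref$length))
    stop("reference block needs either a fasta path or simulation parameters (length, ...)")
  if (!is.null(ref$fasta) && !file.exists(ref$fasta))
    stop("reference fasta not found: ", ref$fasta)
  if (is.null(cfg$bisulfite) && is.null(cfg$mcrbc) && is.null(cfg$features))
    stop("config enables no analysis stage")
  if (!is.null(cfg$bisulfite) && is.null(cfg$bisulfite$clones_green) &&
      is.null(cfg$bisulfite$n_clones))
    stop("bisulfite block needs clone FASTAs or simulation parameters (n_clones)")
  cfg
}

stage_seed <- function(seed, k) (as.integer(seed) + 1000L * k) %% .Machine$integer.max

config_digest <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}

frag_label <- function(fr) sprintf("%+d..%+d", fr[1], fr[2])

#' Run the full analysis pipeline
#'
#' Executes every configured stage, writing TSV/FASTA outputs with a
#' provenance header (config hash, seed, package version) plus a
#' human-readable \code{report.txt}.  With a fixed config and seed the
#' result files are byte-identical across runs.
#'
#' @param config YAML path or config list (see
#'   \code{\link{read_pipeline_config}})
#' @param outdir output directory (overrides the config's \code{outdir})
#' @param verbose log per-stage progress to stderr
#' @return (invisibly) a list with the in-memory results of each stage and
#'   the paths written
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = FALSE) {
  cfg <- read_pipeline_config(config)
  outdir <- outdir %||% cfg$outdir %||% "stripemeth_results"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  prov <- c(sprintf("stripemeth %s",
                    as.character(utils::packageVersion("stripemeth"))),
            sprintf("config md5 %s", config_digest(cfg)),
            sprintf("seed %d", seed))
  paths <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  emit <- function(file, df) {
    p <- file.path(outdir, file)
    write_results(p, df, header_lines = prov)
    paths <<- c(paths, p)
    p
  }
  report <- c("stripemeth pipeline report", paste("#", prov), "")
  results <- list()

  # --- reference -----------------------------------------------------------
  t0 <- Sys.time()
  ref_cfg <- cfg$reference
  region <- if (!is.null(ref_cfg$fasta)) {
    seqs <- read_fasta(ref_cfg$fasta)
    if (is.null(ref_cfg$atg_index)) stop("reference fasta needs atg_index")
    reference_region(names(seqs)[1L] %||% "reference", seqs[[1L]],
                     ref_cfg$atg_index)
  } else {
    motifs <- lapply(ref_cfg$motifs %||% list(), function(m)
      list(motif = m$motif, pos = m$pos))
    gen_reference(ref_cfg$length, ref_cfg$gc_fraction %||% 0.38,
                  embedded_motifs = motifs,
                  atg_index = ref_cfg$atg_index,
                  seed = stage_seed(seed, 1L))
  }
  results$region <- region
  write_fasta(file.path(outdir, "reference.fasta"),
              stats::setNames(region$sequence, region$name))
  paths <- c(paths, file.path(outdir, "reference.fasta"))
  say("reference ready (%d bp) [%.2fs]", nchar(region$sequence),
      as.numeric(Sys.time() - t0, units = "secs"))

  # --- methylation profile -------------------------------------------------
  pr_cfg <- cfg$profile %||% list()
  base_rates <- unlist(pr_cfg$base_rates %||%
                         list(CG = 0.016, CHG = 0.169, CHH = 0.202))
  blocks <- pr_cfg$blocks %||% list()
  pair <- gen_profile(region, base_rates = base_rates, blocks = blocks,
                      stripe_delta = pr_cfg$stripe_delta %||% 0)
  results$profile <- pair
  emit("profile.tsv", pair$profile)

  # --- bisulfite stage -----------------------------------------------------
  if (!is.null(cfg$bisulfite)) {
    bs <- cfg$bisulfite
    frags <- bs$fragments %||% list(c(-1007, -684), c(-534, -184))
    sets <- list(green = list(), red = list())
    k <- 10L
    for (fr in frags) {
      fr <- unlist(fr)
      for (side in c("green", "red")) {
        k <- k + 1L
        cs <- if (!is.null(bs[[paste0("clones_", side)]])) {
          clones <- read_fasta(bs[[paste0("clones_", side)]])
          bisulfite_clone_set(clones, region, fr, sample = side)
        } else {
          gen_bisulfite_clones(
            stripe_profile(pair, side), fr,
            n_clones = bs$n_clones %||% 24,
            conversion_efficiency = bs$conversion_efficiency %||% 0.995,
            seq_error_rate = bs$seq_error_rate %||% 0.001,
            seed = stage_seed(seed, k), sample = side)
        }
        write_fasta(file.path(outdir,
                              sprintf("clones_%s_%s.fasta", side,
                                      gsub("[+.]", "", frag_label(fr)))),
                    cs$clones)
        sets[[side]] <- c(sets[[side]], list(call_clone_set(cs)))
      }
    }
    sum_green <- summarize_region(sets$green)
    sum_red <- summarize_region(sets$red)
    results$bisulfite <- list(green = sum_green, red = sum_red)
    emit("bisulfite_per_position.tsv",
         rbind(cbind(sample = "green", sum_green$per_position),
               cbind(sample = "red", sum_red$per_position)))
    emit("bisulfite_per_context.tsv",
         rbind(cbind(sample = "green", sum_green$per_context),
               cbind(sample = "red", sum_red$per_context)))
    emit("bisulfite_per_clone.tsv",
         rbind(sum_green$per_clone, sum_red$per_clone))
    cmpst <- compare_stripes(sum_green, sum_red)
    results$stripe_comparison <- cmpst
    emit("stripe_comparison.tsv",
         data.frame(region_wide_green = sum_green$region_wide,
                    region_wide_red = sum_red$region_wide,
                    difference = cmpst$difference,
                    mean_position_difference = cmpst$mean_position_difference,
                    fraction_green_higher = cmpst$fraction_green_higher,
                    n_positions = cmpst$n_positions_compared))
    report <- c(report, "== Bisulfite clone analysis ==",
                sprintf("green region-wide %.1f%%, red %.1f%%, difference %.1f points",
                        sum_green$region_wide, sum_red$region_wide,
                        cmpst$difference),
                sprintf("%.0f%% of comparable cytosines higher in green (n=%d)",
                        cmpst$fraction_green_higher,
                        cmpst$n_positions_compared), "")
    say("bisulfite stage done")
  }

  # --- McrBC stage ---------------------------------------------------------
  if (!is.null(cfg$mcrbc)) {
    mc <- cfg$mcrbc
    frags <- mc$fragments %||% list(c(-846, -651))
    ct_all <- list(); est_all <- list()
    k <- 40L
    for (fr in frags) {
      fr <- unlist(fr)
      for (side in c("green", "red")) {
        k <- k + 1L
        ctb <- if (!is.null(mc$ct_table)) {
          tab <- read_ct_table(mc$ct_table)
          tab[tab$fragment == frag_label(fr) & tab$sample == side, ]
        } else {
          pool <- gen_molecule_pool(stripe_profile(pair, side), fr,
                                    n_molecules = mc$n_molecules %||% 5000,
                                    seed = stage_seed(seed, k))
          simulate_mcrbc_qpcr(pool,
                              efficiency = mc$efficiency %||% 2,
                              ct_at_full_template = mc$ct_at_full_template %||% 25,
                              noise_sd = mc$noise_sd %||% 0.15,
                              n_replicates = mc$n_replicates %||% 3,
                              n_digestions = mc$n_digestions %||% 2,
                              seed = stage_seed(seed, k + 400L),
                              sample = side, fragment_label = frag_label(fr))
        }
        ct_all <- c(ct_all, list(as.data.frame(ctb)))
      }
    }
    ct_df <- do.call(rbind, ct_all)
    emit("mcrbc_ct.tsv", ct_df)
    est <- estimate_methylation(as_ct_table(ct_df),
                                efficiency = mc$efficiency %||% 2)
    results$mcrbc <- est
    emit("mcrbc_estimates.tsv", est)
    report <- c(report, "== McrBC/qPCR methylation estimates ==",
                utils::capture.output(print(est, row.names = FALSE)), "")
    say("mcrbc stage done")
  }

  # --- expression stage ----------------------------------------------------
  if (!is.null(cfg$expression)) {
    ex <- cfg$expression
    df <- if (!is.null(ex$ct_table)) {
      utils::read.delim(ex$ct_table)
    } else {
      sim_expression_cts(ex, seed = stage_seed(seed, 90L))
    }
    tab <- expression_table(df, sample_a = ex$compare[[1]] %||% "red",
                            sample_b = ex$compare[[2]] %||% "green",
                            ref_gene = ex$ref_gene %||% "actin",
                            efficiencies = ex$efficiencies,
                            default_efficiency = ex$default_efficiency %||% 2)
    results$expression <- tab
    emit("expression_ratios.tsv", tab)
    report <- c(report, "== Relative expression (vs reference gene) ==",
                utils::capture.output(print(tab, row.names = FALSE)), "")
    say("expression stage done")
  }

  # --- sequence features ---------------------------------------------------
  if (!is.null(cfg$features)) {
    fe <- cfg$features
    win <- unlist(fe$window %||% c(-(region$atg_index - 1L),
                                   nchar(region$sequence) - region$atg_index + 1L))
    hits <- scan_motif(region, fe$motif %||% "CACATG",
                       both_strands = fe$both_strands %||% TRUE,
                       start = win[1], end = win[2])
    results$motif_hits <- hits
    emit("features_motifs.tsv", hits)
    hs <- count_mcrbc_halfsites(region, both_strands = TRUE,
                                start = win[1], end = win[2])
    emit("features_halfsites.tsv", hs)
    results$halfsites <- hs
    report <- c(report, "== Sequence features ==",
                sprintf("motif %s: %d occurrence(s) in %s..%s",
                        fe$motif %||% "CACATG", nrow(hits),
                        win[1], win[2]),
                sprintf("McrBC half-sites (both strands): %d", nrow(hs)), "")
    say("features stage done")
  }

  writeLines(report, file.path(outdir, "report.txt"))
  paths <- c(paths, file.path(outdir, "report.txt"))
  results$paths <- paths
  invisible(results)
}

# Tiny expression simulator for demo configs: per-gene true ratios between
# two samples, Gaussian Ct noise, reference gene flat.
sim_expression_cts <- function(ex, seed = NULL) {
  genes <- ex$genes %||% list(MYB10 = 4.0)
  ref_gene <- ex$ref_gene %||% "actin"
  samples <- unlist(ex$compare %||% c("red", "green"))
  nrep <- ex$n_replicates %||% 3
  noise <- ex$noise_sd %||% 0.1
  base_ct <- ex$base_ct %||% 24
  with_seed(seed, {
    rows <- list()
    for (g in c(ref_gene, names(genes))) {
      for (s in samples) {
        # sample a (first) has `ratio`-fold more target than sample b
        shift <- if (g == ref_gene || s == samples[2L]) 0
                 else -log2(genes[[g]])
        rows <- c(rows, list(data.frame(
          gene = g, sample = s, replicate = paste0("r", seq_len(nrep)),
          ct = base_ct + shift + stats::rnorm(nrep, 0, noise))))
      }
    }
    do.call(rbind, rows)
  })
}
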