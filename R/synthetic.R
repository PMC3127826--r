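# Synthetic-data generators.
#
# The downstream estimators were developed against fruit-peel DNA that cannot
# ship with the package, so every assayable object -- reference promoter,
# per-cytosine methylation mosaic, bisulfite clone sets, McrBC-digested
# molecule pools and qPCR Ct readings -- has a generator here with the
# statistical structure the analysis assumes.  All generators are
# deterministic given `seed` and leave the caller's RNG state untouched.

#' Generate a synthetic promoter reference
#'
#' Draws an i.i.d. base sequence at a target GC fraction, anchors a
#' translation-start ATG near the 3' end (so most of the region is promoter,
#' i.e. negative ATG-relative coordinates), and embeds literal motifs at
#' requested ATG-relative positions.
#'
#' @param length total sequence length (bp)
#' @param gc_fraction target GC content in (0,1); realized GC is within a few
#'   points for length >= 1000
#' @param embedded_motifs list of \code{list(motif=, pos=)} with \code{pos}
#'   the ATG-relative start; placements must not overlap
#' @param atg_index 1-based position of the A of ATG; default leaves 150 bp
#'   downstream of (and including) the start codon
#' @param seed RNG seed (deterministic output for a fixed seed)
#' @param name region label
#' @return a \code{\link{reference_region}}
#' @export
gen_reference <- function(length, gc_fraction = 0.5, embedded_motifs = list(),
                          atg_index = NULL, seed = NULL,
                          name = "synthetic_promoter") {
  stopifnot(length >= 10, gc_fraction > 0, gc_fraction < 1)
  atg_index <- as.integer(atg_index %||% max(1L, length - 149L))
  stopifnot(atg_index >= 1L, atg_index <= length)
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  ch <- with_seed(seed,
    sample(names(probs), length, replace = TRUE, prob = probs))
  if (atg_index + 2L <= length)
    ch[atg_index + 0:2] <- c("A", "T", "G")

  if (length(embedded_motifs)) {
    iv <- lapply(embedded_motifs, function(m) {
      stopifnot(!is.null(m$motif), !is.null(m$pos))
      motif <- assert_dna(m$motif, allow_n = FALSE, what = "motif")
      start <- m$pos
      positions <- atg_positions(start,
        if (start < 0 && start + nchar(motif) - 1L >= 0)
          start + nchar(motif) else start + nchar(motif) - 1L)
      positions <- positions[seq_len(nchar(motif))]
      list(motif = motif, atg_pos = positions)
    })
    # overlap / range check in raw index space
    tmp_region <- structure(list(name = name,
                                 sequence = paste(ch, collapse = ""),
                                 atg_index = atg_index),
                            class = "ReferenceRegion")
    all_idx <- lapply(iv, function(m) atg_to_index(m$atg_pos, tmp_region))
    flat <- unlist(all_idx)
    if (anyDuplicated(flat)) stop("embedded motif placements overlap")
    for (k in seq_along(iv))
      ch[all_idx[[k]]] <- seq_chars(iv[[k]]$motif)
  }
  suppressWarnings(
    reference_region(name, paste(ch, collapse = ""), atg_index))
}

#' Per-cytosine methylation profile
#'
#' A data.frame with one row per forward-strand cytosine: \code{pos}
#' (ATG-relative), \code{context} (CG/CHG/CHH/unknown) and \code{p}
#' (methylation probability).  Carries its \code{ReferenceRegion} as an
#' attribute.
#' @param region a ReferenceRegion
#' @param p numeric vector of probabilities, one per forward-strand C (in
#'   sequence order), or a single value recycled
#' @export
methylation_profile <- function(region, p) {
  stopifnot(inherits(region, "ReferenceRegion"))
  ch <- seq_chars(region$sequence)
  idx <- which(ch == "C")
  pos <- index_to_atg(idx, region)
  ctx <- vapply(pos, function(g) classify_context(region, g), character(1))
  if (length(p) == 1L) p <- rep(p, length(idx))
  stopifnot(length(p) == length(idx), all(p >= 0 & p <= 1))
  out <- data.frame(pos = pos, context = ctx, p = p)
  attr(out, "region") <- region
  class(out) <- c("MethylationProfile", "data.frame")
  out
}

#' Generate paired green/red stripe methylation profiles
#'
#' The red-stripe profile assigns every forward-strand cytosine its
#' context's base rate; regional blocks then override (or scale) the rate;
#' the green-stripe profile adds a uniform offset, clamped to [0,1].  Default
#' base rates are the overall per-context levels observed in the apple
#' MYB10 promoter study system (CHH 20.2%, CHG 16.9%, CG 1.6%).
#'
#' @param region a ReferenceRegion
#' @param base_rates named vector of per-context probabilities
#' @param blocks list of \code{list(start=, end=, override=)} or
#'   \code{list(start=, end=, multiplier=)} in ATG-relative coordinates;
#'   overlapping blocks with conflicting overrides are rejected
#' @param stripe_delta green-minus-red probability offset (scalar)
#' @param unknown_rate probability for cytosines of indeterminable context
#' @return object of class \code{StripePair}: list with elements
#'   \code{profile} (columns pos, context, p_red, p_green), \code{region},
#'   \code{delta}
#' @export
gen_profile <- function(region,
                        base_rates = c(CG = 0.016, CHG = 0.169, CHH = 0.202),
                        blocks = list(), stripe_delta = 0,
                        unknown_rate = 0) {
  stopifnot(all(base_rates >= 0 & base_rates <= 1),
            all(c("CG", "CHG", "CHH") %in% names(base_rates)))
  base <- methylation_profile(region, 0)
  rate_of <- c(base_rates, unknown = unknown_rate)
  p_red <- unname(rate_of[base$context])

  if (length(blocks)) {
    assigned <- rep(NA_real_, nrow(base))
    for (b in blocks) {
      stopifnot(!is.null(b$start), !is.null(b$end))
      idx_hit <- which(base$pos >= b$start & base$pos <= b$end)
      val <- if (!is.null(b$override)) rep(b$override, length(idx_hit))
             else if (!is.null(b$multiplier))
               clamp01(p_red[idx_hit] * b$multiplier)
             else stop("block needs either override or multiplier")
      clash <- idx_hit[!is.na(assigned[idx_hit])]
      if (length(clash) &&
          any(assigned[clash] != val[match(clash, idx_hit)]))
        stop("overlapping blocks with conflicting overrides")
      assigned[idx_hit] <- val
    }
    p_red <- ifelse(is.na(assigned), p_red, assigned)
  }
  stopifnot(all(p_red >= 0 & p_red <= 1))
  out <- list(
    profile = data.frame(pos = base$pos, context = base$context,
                         p_red = p_red,
                         p_green = clamp01(p_red + stripe_delta)),
    region = region, delta = stripe_delta)
  class(out) <- "StripePair"
  out
}

#' Extract one stripe's profile from a StripePair
#' @param pair a StripePair
#' @param side "red" or "green"
#' @return a \code{MethylationProfile}
#' @export
stripe_profile <- function(pair, side = c("red", "green")) {
  stopifnot(inherits(pair, "StripePair"))
  side <- match.arg(side)
  p <- if (side == "red") pair$profile$p_red else pair$profile$p_green
  out <- data.frame(pos = pair$profile$pos, context = pair$profile$context,
                    p = p)
  attr(out, "region") <- pair$region
  class(out) <- c("MethylationProfile", "data.frame")
  out
}

#' Serialize / read a StripePair profile as TSV
#' @param pair a StripePair
#' @param path output TSV (columns pos, context, p_red, p_green)
#' @export
write_profile <- function(path, pair) {
  write_results(path, pair$profile)
}

profile_lookup <- function(profile, positions) {
  p <- profile$p[match(positions, profile$pos)]
  ifelse(is.na(p), 0, p)  # cytosines absent from the profile are unmethylated
}

#' Simulate bisulfite-converted Sanger clones
#'
#' Each clone is an independent draw: every cytosine in the fragment is
#' methylated with its profile probability; methylated cytosines read as C;
#' unmethylated cytosines convert to T with probability
#' \code{conversion_efficiency} (else they read C, mimicking incomplete
#' conversion); finally every base suffers an independent substitution error
#' at \code{seq_error_rate} (uniform over the three other bases).
#'
#' @param profile a \code{MethylationProfile} (one stripe)
#' @param fragment an \code{AmpliconFragment} or c(start, end)
#' @param n_clones number of clones to draw (the study used 12-24, up to 48
#'   per region)
#' @param conversion_efficiency probability an unmethylated C reads T
#' @param seq_error_rate per-base substitution error
#' @param seed RNG seed
#' @param sample sample label (e.g. "green", "red")
#' @return object of class \code{BisulfiteCloneSet} with elements
#'   \code{clones} (named character vector), \code{c_positions}
#'   (ATG-relative forward-strand C positions), \code{truth} (n_clones x nC
#'   logical matrix of simulated methylation states), \code{region},
#'   \code{fragment}, \code{sample}
#' @export
gen_bisulfite_clones <- function(profile, fragment, n_clones,
                                 conversion_efficiency = 0.995,
                                 seq_error_rate = 0.001,
                                 seed = NULL, sample = "sample") {
  stopifnot(inherits(profile, "MethylationProfile"), n_clones >= 1,
            conversion_efficiency >= 0, conversion_efficiency <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1)
  region <- attr(profile, "region")
  frag <- as_fragment(fragment)
  refseq <- extract_fragment(region, frag$start, frag$end)
  ref_ch <- seq_chars(refseq)
  pos_all <- atg_positions(frag$start, frag$end)
  c_idx <- which(ref_ch == "C")
  flags <- character(0)
  if (!length(c_idx)) {
    warning("fragment contains no cytosines; clone set is vacuous")
    flags <- "no_cytosines"
  }
  c_pos <- pos_all[c_idx]
  p <- profile_lookup(profile, c_pos)

  out <- with_seed(seed, {
    truth <- matrix(
      stats::rbinom(n_clones * length(c_idx), 1L, rep(p, each = n_clones)) == 1L,
      nrow = n_clones, ncol = length(c_idx))
    clones <- character(n_clones)
    L <- length(ref_ch)
    for (k in seq_len(n_clones)) {
      ch <- ref_ch
      if (length(c_idx)) {
        converted <- stats::runif(length(c_idx)) < conversion_efficiency
        ch[c_idx] <- ifelse(truth[k, ], "C", ifelse(converted, "T", "C"))
      }
      if (seq_error_rate > 0) {
        err <- which(stats::runif(L) < seq_error_rate)
        for (i in err)
          ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
      }
      clones[k] <- paste(ch, collapse = "")
    }
    list(truth = truth, clones = clones)
  })
  names(out$clones) <- sprintf("%s|clone%02d", sample, seq_len(n_clones))
  structure(
    list(sample = sample, fragment = frag, region = region,
         clones = out$clones, c_positions = c_pos, truth = out$truth,
         call_matrix = NULL, flags = flags),
    class = "BisulfiteCloneSet")
}

#' @export
print.BisulfiteCloneSet <- function(x, ...) {
  cat(sprintf(
    "BisulfiteCloneSet '%s': %d clone(s) on %+d..%+d, %d cytosine position(s)%s\n",
    x$sample, length(x$clones), x$fragment$start, x$fragment$end,
    length(x$c_positions),
    if (is.null(x$call_matrix)) " (not yet called)" else " (called)"))
  invisible(x)
}

# --- McrBC molecule pools ------------------------------------------------

# Half-sites are purine-C dinucleotides on the forward strand; `start` is the
# purine's position (separations are measured between half-site starts).
fragment_halfsites <- function(region, frag) {
  refseq <- extract_fragment(region, frag$start, frag$end)
  hs <- halfsite_positions(refseq)          # 1-based offsets within fragment
  pos_all <- atg_positions(frag$start, frag$end)
  list(local = hs, atg = pos_all[hs], c_atg = pos_all[pmin(hs + 1L, length(pos_all))])
}

#' Simulate a pool of genomic DNA molecules for McrBC digestion
#'
#' Each molecule carries an independent methylation state at every McrBC
#' half-site (purine-C) in the fragment, drawn from the profile probability
#' of the half-site's cytosine.  Alternatively, \code{digestible_fraction}
#' constructs a pool in which exactly that expected fraction of molecules
#' carries an eligible methylated pair (two half-sites 40-3000 bp apart) and
#' the rest carry none -- handy for calibrating the estimator against a known
#' truth.
#'
#' @param profile a MethylationProfile
#' @param fragment AmpliconFragment or c(start, end)
#' @param n_molecules pool size
#' @param seed RNG seed
#' @param digestible_fraction optional probability in [0,1]; overrides the
#'   profile-driven draw as described above
#' @return object of class \code{MoleculePool}
#' @export
gen_molecule_pool <- function(profile, fragment, n_molecules, seed = NULL,
                              digestible_fraction = NULL) {
  stopifnot(inherits(profile, "MethylationProfile"), n_molecules >= 1)
  region <- attr(profile, "region")
  frag <- as_fragment(fragment)
  hs <- fragment_halfsites(region, frag)
  H <- length(hs$local)
  if (H < 2L)
    warning("fragment has <2 McrBC half-sites; digestion impossible")
  states <- if (is.null(digestible_fraction)) {
    p <- profile_lookup(profile, hs$c_atg)
    with_seed(seed,
      matrix(stats::rbinom(n_molecules * H, 1L, rep(p, each = n_molecules)) == 1L,
             nrow = n_molecules, ncol = H))
  } else {
    stopifnot(digestible_fraction >= 0, digestible_fraction <= 1, H >= 1L)
    sep <- outer(hs$local, hs$local, function(a, b) abs(a - b))
    pair <- which(sep >= 40 & sep <= 3000, arr.ind = TRUE)
    if (!nrow(pair))
      stop("no half-site pair 40-3000 bp apart; cannot build a digestible pool")
    i <- pair[1L, 1L]; j <- pair[1L, 2L]
    m <- matrix(FALSE, nrow = n_molecules, ncol = H)
    dig <- with_seed(seed,
                     stats::runif(n_molecules) < digestible_fraction)
    m[dig, c(i, j)] <- TRUE
    m
  }
  structure(
    list(n_molecules = n_molecules, states = states,
         halfsite_local = hs$local, halfsite_atg = hs$atg,
         fragment = frag, region = region),
    class = "MoleculePool")
}

#' Fraction of pool molecules destroyed by McrBC
#'
#' A molecule is non-amplifiable when it carries at least two methylated
#' half-sites whose starts lie 40-3000 bp apart: the enzyme then cuts between
#' them (midpoint model) which, for pools built over the amplicon itself,
#' always destroys the template.
#' @param pool a MoleculePool
#' @param min_sep,max_sep eligible half-site separation window (bp)
#' @return fraction in [0,1]
#' @export
pool_nonamplifiable_fraction <- function(pool, min_sep = 40, max_sep = 3000) {
  stopifnot(inherits(pool, "MoleculePool"))
  loc <- pool$halfsite_local
  cut <- apply(pool$states, 1L, function(st) {
    v <- loc[st]
    if (length(v) < 2L) return(FALSE)
    has_pair_in_window(v, min_sep, max_sep)
  })
  mean(cut)
}

has_pair_in_window <- function(sorted_pos, min_sep, max_sep) {
  v <- sort(sorted_pos)
  for (i in seq_len(length(v) - 1L)) {
    d <- v[(i + 1L):length(v)] - v[i]
    if (any(d >= min_sep & d <= max_sep)) return(TRUE)
  }
  FALSE
}

#' Simulate McrBC + mock qPCR crossing thresholds for a molecule pool
#'
#' The mock digestion reads the full template (Ct = \code{ct_at_full_template}
#' plus noise); the McrBC digestion reads only the surviving fraction f, at
#' Ct = \code{ct_at_full_template} - log_E(f) plus noise.  A fully digested
#' pool (f = 0) yields the no-amplification sentinel \code{NA} in the ct
#' column.
#'
#' @param pool a MoleculePool
#' @param efficiency per-cycle amplification factor in (1,2]
#' @param ct_at_full_template mock-template crossing threshold (cycles)
#' @param noise_sd Gaussian Ct noise SD (cycles)
#' @param n_replicates PCR replicates per digestion (the study ran
#'   triplicates)
#' @param n_digestions independent enzyme digestions (the study used 2-3)
#' @param seed RNG seed
#' @param sample,fragment_label labels for the emitted CtTable
#' @return a \code{CtTable} data.frame with a \code{digestion} column
#' @export
simulate_mcrbc_qpcr <- function(pool, efficiency = 2,
                                ct_at_full_template = 25,
                                noise_sd = 0.15, n_replicates = 3,
                                n_digestions = 1, seed = NULL,
                                sample = "sample", fragment_label = NULL) {
  stopifnot(inherits(pool, "MoleculePool"),
            efficiency > 1, efficiency <= 2, n_replicates >= 1,
            n_digestions >= 1, noise_sd >= 0)
  frag <- pool$fragment
  fragment_label <- fragment_label %||%
    sprintf("%+d..%+d", frag$start, frag$end)
  surviving <- 1 - pool_nonamplifiable_fraction(pool)
  ct_mcrbc_true <- if (surviving > 0)
    ct_at_full_template - log(surviving) / log(efficiency) else NA_real_

  n <- n_digestions * n_replicates
  noise <- with_seed(seed, matrix(stats::rnorm(2 * n, 0, noise_sd), ncol = 2))
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      digestion = seq_len(n_digestions))
  df <- rbind(
    data.frame(sample = sample, fragment = fragment_label,
               treatment = "mock", digestion = grid$digestion,
               replicate = paste0("r", grid$replicate),
               ct = ct_at_full_template + noise[, 1L]),
    data.frame(sample = sample, fragment = fragment_label,
               treatment = "mcrbc", digestion = grid$digestion,
               replicate = paste0("r", grid$replicate),
               ct = if (is.na(ct_mcrbc_true)) NA_real_
                    else ct_mcrbc_true + noise[, 2L]))
  as_ct_table(df[order(df$digestion, df$treatment, df$replicate), ])
}
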