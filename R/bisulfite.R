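# Amplicon bisulfite Sanger-clone analysis.
#
# Bisulfite treatment converts unmethylated cytosine to uracil (read T after
# PCR) while 5-methylcytosine stays C.  Cloned amplicons are aligned back to
# the unconverted reference; each reference cytosine column then yields a
# methylated (C), unmethylated (T) or ambiguous (gap/other) call per clone.
# Calls are summarized per position, per cytosine context (CG/CHG/CHH; H =
# A, C or T -- plant genomes methylate all three), per clone, and
# region-wide.  The forward (bisulfite top) strand only is analyzed:
# amplicons are strand-specific after bisulfite PCR.

#' Classify the sequence context of a cytosine
#'
#' \code{CG} if the next base is G; \code{CHG} if the next base is H (A, C
#' or T) and the base after that is G; \code{CHH} if both following bases
#' are H; \code{unknown} when the context cannot be determined (sequence end
#' or an N).  A CG call needs only one downstream base.
#'
#' @param region a \code{ReferenceRegion}
#' @param pos ATG-relative position of a cytosine
#' @return one of "CG", "CHG", "CHH", "unknown"
#' @export
classify_context <- function(region, pos) {
  i <- atg_to_index(pos, region)
  n <- nchar(region$sequence)
  if (substr(region$sequence, i, i) != "C")
    stop("base at position ", pos, " is not a cytosine")
  b1 <- if (i + 1L <= n) substr(region$sequence, i + 1L, i + 1L) else ""
  b2 <- if (i + 2L <= n) substr(region$sequence, i + 2L, i + 2L) else ""
  if (b1 == "G") return("CG")
  if (b1 == "" || b1 == "N" || b2 == "" || b2 == "N") return("unknown")
  H <- c("A", "C", "T")
  if (b1 %in% H && b2 == "G") return("CHG")
  if (b1 %in% H && b2 %in% H) return("CHH")
  "unknown"
}

#' In-silico bisulfite conversion
#'
#' Every cytosine not listed in \code{methylated_positions} becomes T;
#' methylated cytosines and non-C bases are untouched.
#'
#' @param sequence DNA string
#' @param methylated_positions 1-based positions within \code{sequence}
#'   (must all be C)
#' @return converted DNA string
#' @export
convert_in_silico <- function(sequence, methylated_positions = integer(0)) {
  ch <- seq_chars(sequence)
  if (length(methylated_positions)) {
    mp <- as.integer(methylated_positions)
    stopifnot(all(mp >= 1L), all(mp <= length(ch)))
    if (any(ch[mp] != "C"))
      stop("methylated_positions must all be cytosines")
  }
  conv <- ch == "C"
  conv[methylated_positions] <- FALSE
  ch[conv] <- "T"
  paste(ch, collapse = "")
}

bisulfite_substitution_matrix <- function(match = 2, mismatch = -2) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m[, "N"] <- 0; m["N", ] <- 0
  # rows = clone (pattern), cols = reference (subject): a clone T over a
  # reference C is expected conversion, scored as a full match so that
  # conversion state cannot distort the alignment
  m["T", "C"] <- match
  m
}

#' Align a bisulfite clone to its unconverted reference fragment
#'
#' Global (Needleman-Wunsch, affine-gap) alignment in which reference-C vs
#' clone-T (expected conversion) and reference-C vs clone-C (methylation)
#' both score as matches; other mismatches are penalized.  Clones whose
#' length deviates too far from the reference, or whose identity on non-C
#' reference positions falls below \code{identity_floor}, are rejected with
#' a reason (a reverse-complement clone fails the floor; the caller may
#' retry after reverse-complementing).
#'
#' @param clone clone sequence (character)
#' @param reference unconverted reference fragment (character)
#' @param identity_floor minimum identity on non-C reference positions
#' @param length_tolerance allowed relative length deviation
#' @param match,mismatch,gap_opening,gap_extension alignment scores
#'   (penalties positive)
#' @return list: \code{accepted} (logical), \code{reason} (if rejected),
#'   \code{clone_bases} (per reference position: clone base or "-"),
#'   \code{identity} (non-C-position identity)
#' @export
align_clone <- function(clone, reference, identity_floor = 0.8,
                        length_tolerance = 0.2,
                        match = 2, mismatch = -2,
                        gap_opening = 5, gap_extension = 1) {
  if (!nzchar(clone)) stop("empty clone sequence")
  clone <- assert_dna(clone, what = "clone")
  reference <- assert_dna(reference, what = "reference")
  Lr <- nchar(reference); Lc <- nchar(clone)
  if (abs(Lc - Lr) > length_tolerance * Lr)
    return(list(accepted = FALSE,
                reason = sprintf("length %d outside %.0f%% of reference %d",
                                 Lc, 100 * length_tolerance, Lr),
                clone_bases = NULL, identity = NA_real_))
  al <- Biostrings::pairwiseAlignment(
    pattern = clone, subject = reference,
    substitutionMatrix = bisulfite_substitution_matrix(match, mismatch),
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global")
  pat <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  sub <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  ref_cols <- sub != "-"
  clone_bases <- pat[ref_cols]           # one entry per reference position
  ref_ch <- sub[ref_cols]
  non_c <- ref_ch != "C" & ref_ch != "N"
  scorable <- non_c & clone_bases != "-" & clone_bases != "N"
  identity <- if (any(scorable))
    mean(clone_bases[scorable] == ref_ch[scorable]) else 0
  if (identity < identity_floor)
    return(list(accepted = FALSE,
                reason = sprintf("identity %.2f below floor %.2f (reverse complement?)",
                                 identity, identity_floor),
                clone_bases = clone_bases, identity = identity))
  list(accepted = TRUE, reason = NA_character_,
       clone_bases = clone_bases, identity = identity)
}

#' Call methylation status at a reference cytosine
#'
#' Clone C means the cytosine resisted conversion (methylated); clone T
#' means it converted (unmethylated); a gap, N or any other base is
#' ambiguous and excluded from denominators downstream.
#'
#' @param ref_base reference base (must be "C"); vectors recycle
#' @param clone_base aligned clone base or "-"
#' @return character vector over {"methylated","unmethylated","ambiguous"}
#' @export
call_methylation <- function(ref_base, clone_base) {
  n <- max(length(ref_base), length(clone_base))
  ref_base <- rep_len(toupper(ref_base), n)
  clone_base <- rep_len(toupper(clone_base), n)
  if (any(ref_base != "C")) stop("reference base must be C")
  ifelse(clone_base == "C", "methylated",
         ifelse(clone_base == "T", "unmethylated", "ambiguous"))
}

#' Build a clone set from sequences
#'
#' @param clones named character vector of clone sequences (FASTA headers
#'   conventionally \code{sample|clone_id})
#' @param region the unconverted \code{ReferenceRegion}
#' @param fragment AmpliconFragment or c(start, end)
#' @param sample sample label
#' @return an uncalled \code{BisulfiteCloneSet}
#' @export
bisulfite_clone_set <- function(clones, region, fragment, sample = "sample") {
  frag <- as_fragment(fragment)
  refseq <- extract_fragment(region, frag$start, frag$end)
  ref_ch <- seq_chars(refseq)
  pos_all <- atg_positions(frag$start, frag$end)
  c_pos <- pos_all[ref_ch == "C"]
  if (is.null(names(clones)))
    names(clones) <- sprintf("%s|clone%02d", sample, seq_along(clones))
  structure(
    list(sample = sample, fragment = frag, region = region,
         clones = clones, c_positions = c_pos, truth = NULL,
         call_matrix = NULL, flags = character(0)),
    class = "BisulfiteCloneSet")
}

#' Align all clones of a set and fill its call matrix
#'
#' @param clone_set a \code{BisulfiteCloneSet}
#' @param ... passed to \code{\link{align_clone}}
#' @return the clone set with \code{call_matrix} (accepted clones x
#'   reference-C positions), \code{alignment} diagnostics and any
#'   \code{rejected} clones recorded
#' @export
call_clone_set <- function(clone_set, ...) {
  stopifnot(inherits(clone_set, "BisulfiteCloneSet"))
  frag <- clone_set$fragment
  refseq <- extract_fragment(clone_set$region, frag$start, frag$end)
  ref_ch <- seq_chars(refseq)
  c_idx <- which(ref_ch == "C")
  res <- lapply(clone_set$clones, align_clone, reference = refseq, ...)
  accepted <- vapply(res, `[[`, logical(1), "accepted")
  calls <- matrix(
    unlist(lapply(res[accepted], function(r)
      call_methylation(rep("C", length(c_idx)), r$clone_bases[c_idx]))),
    nrow = sum(accepted), ncol = length(c_idx), byrow = TRUE)
  dimnames(calls) <- list(names(clone_set$clones)[accepted],
                          clone_set$c_positions)
  clone_set$call_matrix <- calls
  clone_set$alignment <- data.frame(
    clone = names(clone_set$clones),
    accepted = accepted,
    identity = vapply(res, `[[`, numeric(1), "identity"),
    reason = vapply(res, `[[`, character(1), "reason"))
  clone_set$rejected <- names(clone_set$clones)[!accepted]
  clone_set
}

context_of_positions <- function(region, positions) {
  vapply(positions, function(p) classify_context(region, p), character(1))
}

#' Summarize methylation calls for a region
#'
#' Percentages use unambiguous calls only (ambiguous calls reduce the
#' denominator; they are never counted as unmethylated).  Contexts come from
#' the unconverted reference.  Accepts a single called
#' \code{BisulfiteCloneSet} or a list of sets (e.g. the two amplicons of one
#' sample), whose calls are pooled for the per-context and region-wide
#' figures.
#'
#' @param clone_set a called \code{BisulfiteCloneSet} or list thereof
#' @return object of class \code{RegionMethylationSummary}: list with
#'   \code{per_position}, \code{per_context}, \code{per_clone} data.frames,
#'   \code{region_wide} percent, plus bookkeeping fields
#' @export
summarize_region <- function(clone_set) {
  sets <- if (inherits(clone_set, "BisulfiteCloneSet")) list(clone_set)
          else clone_set
  stopifnot(length(sets) >= 1,
            all(vapply(sets, inherits, logical(1), "BisulfiteCloneSet")))
  sets <- lapply(sets, function(s)
    if (is.null(s$call_matrix)) call_clone_set(s) else s)

  per_pos <- do.call(rbind, lapply(sets, function(s) {
    cm <- s$call_matrix
    if (!ncol(cm)) return(NULL)
    ctx <- context_of_positions(s$region, s$c_positions)
    data.frame(
      fragment = sprintf("%+d..%+d", s$fragment$start, s$fragment$end),
      pos = s$c_positions, context = ctx,
      n_methylated = colSums(cm == "methylated"),
      n_unmethylated = colSums(cm == "unmethylated"),
      n_ambiguous = colSums(cm == "ambiguous"),
      row.names = NULL)
  }))
  if (is.null(per_pos)) stop("no cytosine calls to summarize")
  unamb <- per_pos$n_methylated + per_pos$n_unmethylated
  per_pos$percent <- ifelse(unamb > 0,
                            100 * per_pos$n_methylated / unamb, NA_real_)

  per_ctx <- do.call(rbind, lapply(split(per_pos, per_pos$context),
    function(d) data.frame(context = d$context[1L],
                           n_methylated = sum(d$n_methylated),
                           n_unambiguous = sum(d$n_methylated +
                                                 d$n_unmethylated))))
  per_ctx$percent <- ifelse(per_ctx$n_unambiguous > 0,
                            100 * per_ctx$n_methylated / per_ctx$n_unambiguous,
                            NA_real_)
  rownames(per_ctx) <- NULL

  per_clone <- do.call(rbind, lapply(sets, function(s) {
    cm <- s$call_matrix
    if (!nrow(cm)) return(NULL)
    nm <- rowSums(cm == "methylated")
    nu <- rowSums(cm == "methylated" | cm == "unmethylated")
    data.frame(clone = rownames(cm), n_methylated = nm, n_unambiguous = nu,
               percent = ifelse(nu > 0, 100 * nm / nu, NA_real_),
               row.names = NULL)
  }))

  total_m <- sum(per_pos$n_methylated)
  total_u <- sum(per_pos$n_methylated + per_pos$n_unmethylated)
  structure(
    list(sample = sets[[1L]]$sample,
         fragments = vapply(sets, function(s)
           sprintf("%+d..%+d", s$fragment$start, s$fragment$end),
           character(1)),
         per_position = per_pos, per_context = per_ctx,
         per_clone = per_clone,
         region_wide = if (total_u > 0) 100 * total_m / total_u else NA_real_,
         n_calls_unambiguous = total_u,
         n_clones = sum(vapply(sets, function(s) nrow(s$call_matrix), 0L))),
    class = "RegionMethylationSummary")
}

#' @export
print.RegionMethylationSummary <- function(x, ...) {
  cat(sprintf("RegionMethylationSummary '%s' (%s): region-wide %.1f%% over %d calls\n",
              x$sample, paste(x$fragments, collapse = ", "),
              x$region_wide, x$n_calls_unambiguous))
  print(x$per_context)
  invisible(x)
}

#' Compare green- vs red-stripe methylation summaries
#'
#' Region-wide difference (green minus red), the mean of per-position
#' differences, and the fraction of cytosine positions where green exceeds
#' red.  Only positions with unambiguous calls in both summaries enter the
#' per-position statistics; ties count in the denominator but never the
#' numerator.
#'
#' @param green,red \code{RegionMethylationSummary} objects over the same
#'   fragment(s)
#' @return list with \code{difference} (region-wide),
#'   \code{mean_position_difference}, \code{fraction_green_higher} (percent),
#'   \code{n_positions_compared}, and the per-position table
#' @export
compare_stripes <- function(green, red) {
  stopifnot(inherits(green, "RegionMethylationSummary"),
            inherits(red, "RegionMethylationSummary"))
  g <- green$per_position; r <- red$per_position
  key_g <- paste(g$fragment, g$pos); key_r <- paste(r$fragment, r$pos)
  if (!identical(sort(key_g), sort(key_r)))
    stop("summaries cover different cytosine positions")
  r <- r[match(key_g, key_r), ]
  both <- !is.na(g$percent) & !is.na(r$percent)
  d <- g$percent[both] - r$percent[both]
  list(difference = green$region_wide - red$region_wide,
       mean_position_difference = mean(d),
       fraction_green_higher = 100 * mean(d > 0),
       n_positions_compared = sum(both),
       per_position = data.frame(fragment = g$fragment[both],
                                 pos = g$pos[both],
                                 green = g$percent[both],
                                 red = r$percent[both],
                                 difference = d))
}

# --- primer-bias and motif reporting -------------------------------------

# Allowed post-bisulfite reads of an unconverted reference base, top strand.
bisulfite_reads <- function(ref_base) {
  switch(ref_base,
         C = c("C", "T"),
         N = DNA_BASES,
         ref_base)
}

primer_compatible_at <- function(primer_ch, ref_ch) {
  all(vapply(seq_along(primer_ch), function(i) {
    length(intersect(iupac_expand(primer_ch[i]),
                     bisulfite_reads(ref_ch[i]))) > 0
  }, logical(1)))
}

#' Check a bisulfite-PCR primer for amplification bias
#'
#' Bisulfite conversion makes unmethylated cytosines read T while methylated
#' ones stay C, so a primer whose footprint covers a reference cytosine must
#' tolerate both reads (a degenerate code such as Y or N) or it will
#' preferentially amplify one methylation state.  Forward primers are
#' checked as given against the fragment 5' end; reverse primers are
#' reverse-complemented into top-strand sense and checked against the 3'
#' end.  If the primer is not compatible at its canonical end the whole
#' fragment is scanned before giving up.
#'
#' @param primer IUPAC DNA string (reverse primers in their own 5'->3'
#'   orientation)
#' @param region a \code{ReferenceRegion}
#' @param fragment AmpliconFragment or c(start, end)
#' @param orientation "forward" or "reverse"
#' @return list: \code{biased} (logical), \code{positions} (ATG-relative
#'   positions of non-degenerate cytosine coverage, empty if unbiased),
#'   \code{offset} (ATG-relative start of the primer footprint)
#' @export
check_primer_bias <- function(primer, region, fragment,
                              orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  frag <- as_fragment(fragment)
  refseq <- extract_fragment(region, frag$start, frag$end)
  ref_ch <- seq_chars(refseq)
  pos_all <- atg_positions(frag$start, frag$end)
  pch <- seq_chars(if (orientation == "forward") primer else revcomp(primer))
  L <- length(pch); n <- length(ref_ch)
  if (L > n) stop("primer longer than fragment")

  canonical <- if (orientation == "forward") 1L else n - L + 1L
  offsets <- unique(c(canonical, seq_len(n - L + 1L)))
  at <- NA_integer_
  for (o in offsets) {
    if (primer_compatible_at(pch, ref_ch[o:(o + L - 1L)])) { at <- o; break }
  }
  if (is.na(at))
    stop("primer not locatable on fragment (no bisulfite-compatible offset)")

  idx <- at:(at + L - 1L)
  over_c <- which(ref_ch[idx] == "C")
  bad <- over_c[!vapply(over_c, function(i)
    all(c("C", "T") %in% iupac_expand(pch[i])), logical(1))]
  list(biased = length(bad) > 0,
       positions = pos_all[idx][bad],
       offset = pos_all[at])
}

#' Methylation in and around motif occurrences
#'
#' For each motif occurrence, reports the percent methylation of scorable
#' cytosines inside the motif and within flanking windows, from a
#' \code{RegionMethylationSummary}.  Occurrences extending outside the
#' summarized fragment(s) are skipped with a note.
#'
#' @param summary a \code{RegionMethylationSummary}
#' @param motifs data.frame with columns \code{start}, \code{end}
#'   (ATG-relative), e.g. from \code{\link{scan_motif}}
#' @param flank flanking window size (bases on each side)
#' @return data.frame: start, end, status, inside_percent, inside_n,
#'   flank_percent, flank_n
#' @export
motif_methylation <- function(summary, motifs, flank = 10) {
  stopifnot(inherits(summary, "RegionMethylationSummary"))
  pp <- summary$per_position
  covered <- range(pp$pos)
  pct_over <- function(sel) {
    d <- pp[sel & !is.na(pp$percent), ]
    n <- sum(d$n_methylated + d$n_unmethylated)
    list(percent = if (n > 0) 100 * sum(d$n_methylated) / n else NA_real_,
         n = nrow(d))
  }
  rows <- lapply(seq_len(nrow(motifs)), function(k) {
    s <- motifs$start[k]; e <- motifs$end[k]
    if (s < covered[1L] || e > covered[2L])
      return(data.frame(start = s, end = e, status = "skipped: outside fragment",
                        inside_percent = NA_real_, inside_n = 0L,
                        flank_percent = NA_real_, flank_n = 0L))
    inside <- pct_over(pp$pos >= s & pp$pos <= e)
    fl <- pct_over((pp$pos >= s - flank & pp$pos < s) |
                     (pp$pos > e & pp$pos <= e + flank))
    status <- if (inside$n == 0) "no scorable cytosines" else "ok"
    data.frame(start = s, end = e, status = status,
               inside_percent = inside$percent, inside_n = inside$n,
               flank_percent = fl$percent, flank_n = fl$n)
  })
  do.call(rbind, rows)
}
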