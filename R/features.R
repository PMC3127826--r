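# Promoter sequence features: E-box scanning, McrBC recognition-site
# counting, pairwise identity.

region_or_seq <- function(x, start = NULL, end = NULL) {
  if (inherits(x, "ReferenceRegion")) {
    if (!is.null(start)) {
      list(seq = extract_fragment(x, start, end),
           pos = atg_positions(start, end))
    } else {
      list(seq = x$sequence, pos = index_to_atg(seq_len(nchar(x$sequence)), x))
    }
  } else {
    x <- assert_dna(x)
    list(seq = x, pos = seq_len(nchar(x)))
  }
}

#' Scan for a motif (IUPAC-aware, both strands)
#'
#' Finds every exact IUPAC-expanded occurrence of \code{motif}.  Reverse
#' strand hits are located by matching the motif's reverse complement on the
#' forward strand and are reported by their forward-strand start.  E-box
#' scanning (CACATG) defaults to both strands, as the element is
#' non-palindromic.
#'
#' @param x a \code{ReferenceRegion} or plain DNA string
#' @param motif IUPAC DNA string
#' @param both_strands also scan the reverse strand
#' @param start,end optional ATG-relative window when \code{x} is a region
#' @return data.frame: start, end (ATG-relative for regions, 1-based
#'   otherwise), strand ("+"/"-")
#' @export
scan_motif <- function(x, motif, both_strands = TRUE,
                       start = NULL, end = NULL) {
  if (!nzchar(motif)) stop("empty motif")
  tgt <- region_or_seq(x, start, end)
  find <- function(m) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(m),
                                     Biostrings::DNAString(tgt$seq),
                                     fixed = FALSE)
    IRanges::start(hits)
  }
  fwd <- find(motif)
  out <- data.frame(start = tgt$pos[fwd],
                    end = tgt$pos[fwd + nchar(motif) - 1L],
                    strand = rep("+", length(fwd)))
  if (both_strands) {
    rc <- revcomp(motif)
    rev_hits <- find(rc)
    # a palindromic motif would re-report the same window; keep strands
    # distinguished, as callers may want either convention
    out <- rbind(out,
                 data.frame(start = tgt$pos[rev_hits],
                            end = tgt$pos[rev_hits + nchar(motif) - 1L],
                            strand = rep("-", length(rev_hits))))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# 1-based offsets (of the purine) of forward-strand Pu-C half-sites.
halfsite_positions <- function(sequence) {
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 2L) return(integer(0))
  which(ch[-n] %in% c("A", "G") & ch[-1L] == "C")
}

#' Count McrBC recognition half-sites
#'
#' A half-site is a purine followed by a (methylatable) cytosine: dinucleotide
#' (A|G)C on the forward strand.  With \code{both_strands}, bottom-strand
#' half-sites -- reading GT or GC on the top strand -- are also reported,
#' labelled by strand; N never matches.  Useful for verifying that fragments
#' compared for methylation do not differ merely in their number of
#' potential recognition sites.
#'
#' @param x a \code{ReferenceRegion} or DNA string
#' @param both_strands include bottom-strand half-sites
#' @param start,end optional ATG-relative window for regions
#' @return data.frame: position (of the half-site start, i.e. the purine on
#'   its own strand; for "-" the position of the top-strand dinucleotide
#'   start), strand
#' @export
count_mcrbc_halfsites <- function(x, both_strands = FALSE,
                                  start = NULL, end = NULL) {
  tgt <- region_or_seq(x, start, end)
  ch <- seq_chars(tgt$seq)
  n <- length(ch)
  fwd <- halfsite_positions(tgt$seq)
  out <- data.frame(position = tgt$pos[fwd], strand = rep("+", length(fwd)))
  if (both_strands && n >= 2L) {
    # bottom-strand PuC = top-strand G followed by (T|C) read 5'->3' on top
    rev <- which(ch[-n] == "G" & ch[-1L] %in% c("T", "C"))
    out <- rbind(out, data.frame(position = tgt$pos[rev],
                                 strand = rep("-", length(rev))))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate McrBC-eligible half-site pairs
#'
#' The enzyme requires two methylated half-sites 40-3000 bases apart;
#' separation is measured between half-site start coordinates.
#'
#' @param positions sorted numeric half-site start positions
#' @param min_sep,max_sep inclusive separation window (bases)
#' @return data.frame: first, second, separation
#' @export
enumerate_mcrbc_pairs <- function(positions, min_sep = 40, max_sep = 3000) {
  positions <- sort(as.numeric(positions))
  n <- length(positions)
  if (n < 2L)
    return(data.frame(first = numeric(0), second = numeric(0),
                      separation = numeric(0)))
  idx <- utils::combn(n, 2L)
  sep <- positions[idx[2L, ]] - positions[idx[1L, ]]
  keep <- sep >= min_sep & sep <= max_sep
  data.frame(first = positions[idx[1L, keep]],
             second = positions[idx[2L, keep]],
             separation = sep[keep])
}

#' Percent identity between two sequences
#'
#' \code{global} mode runs a Needleman-Wunsch alignment (match 1, mismatch
#' -1, gap open -2, gap extend -1) and reports matching columns over all
#' alignment columns, gaps included -- the common convention for reporting
#' "% identity" of element hits.  \code{ungapped} mode compares equal-length
#' sequences position by position.
#'
#' @param seq_a,seq_b DNA strings
#' @param mode "global" or "ungapped"
#' @return percent identity in [0,100]
#' @export
pairwise_identity <- function(seq_a, seq_b, mode = c("global", "ungapped")) {
  mode <- match.arg(mode)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  seq_a <- assert_dna(seq_a); seq_b <- assert_dna(seq_b)
  if (mode == "ungapped") {
    if (nchar(seq_a) != nchar(seq_b))
      stop("ungapped mode requires equal-length sequences")
    a <- seq_chars(seq_a); b <- seq_chars(seq_b)
    return(100 * mean(a == b))
  }
  sm <- matrix(-1, 5, 5, dimnames = list(c(DNA_BASES, "N"),
                                         c(DNA_BASES, "N")))
  diag(sm) <- 1
  sm[, "N"] <- 0; sm["N", ] <- 0
  al <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b, substitutionMatrix = sm,
    gapOpening = 1, gapExtension = 1, type = "global")
  a <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  b <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  100 * mean(a == b & a != "-")
}
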