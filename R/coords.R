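#' Reference region with translation-start-anchored coordinates
#'
#' Promoter and coding-region positions are conventionally reported relative
#' to the A of the translation-start ATG, with no position zero: \code{+1} is
#' the A itself and \code{-1} the base immediately 5' of it.  A
#' \code{ReferenceRegion} couples a plain DNA sequence with that anchor so
#' every downstream module (fragment extraction, motif scanning, methylation
#' profiles) can speak ATG-relative coordinates.
#'
#' @param name region label (e.g. an accession or cultivar tag)
#' @param sequence DNA string over A,C,G,T,N (case-insensitive)
#' @param atg_index 1-based index in \code{sequence} of the A of the start
#'   codon.  May point past an upstream-only region's end, in which case no
#'   ATG check is possible.
#' @param annotations optional data.frame with columns \code{label},
#'   \code{start}, \code{end} in ATG-relative coordinates
#' @return an object of class \code{ReferenceRegion}
#' @examples
#' r <- reference_region("toy", "AAACCATGGGT", atg_index = 6)
#' extract_fragment(r, 1, 3)   # "ATG"
#' @export
reference_region <- function(name, sequence, atg_index,
                             annotations = NULL) {
  sequence <- assert_dna(sequence, allow_n = TRUE, what = "reference sequence")
  n <- nchar(sequence)
  stopifnot(length(atg_index) == 1L, atg_index >= 1L, atg_index <= n)
  atg_index <- as.integer(atg_index)
  if (atg_index + 2L <= n) {
    codon <- substr(sequence, atg_index, atg_index + 2L)
    if (codon != "ATG")
      warning("sequence at atg_index is '", codon,
              "', not ATG; coordinates anchored there regardless")
  }
  if (!is.null(annotations))
    stopifnot(all(c("label", "start", "end") %in% names(annotations)))
  structure(
    list(name = name, sequence = sequence, atg_index = atg_index,
         annotations = annotations),
    class = "ReferenceRegion")
}

#' @export
print.ReferenceRegion <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(sprintf("ReferenceRegion '%s': %d bp, spans %d..%+d (ATG-relative)\n",
              x$name, n, -(x$atg_index - 1L), n - x$atg_index + 1L))
  if (!is.null(x$annotations))
    cat(sprintf("  %d annotation(s)\n", nrow(x$annotations)))
  invisible(x)
}

#' Convert ATG-relative positions to sequence indices
#'
#' ATG-relative coordinates skip zero: \code{...,-2,-1,+1,+2,...}.  The
#' mapping is a bijection between valid signed positions and 1-based string
#' indices; \code{index_to_atg} is its inverse.
#'
#' @param pos integer vector of ATG-relative positions (non-zero)
#' @param region a \code{ReferenceRegion}
#' @return integer vector of 1-based indices into \code{region$sequence}
#' @export
atg_to_index <- function(pos, region) {
  stopifnot(inherits(region, "ReferenceRegion"))
  pos <- as.integer(pos)
  if (any(pos == 0L))
    stop("ATG-relative coordinates have no position 0")
  idx <- ifelse(pos > 0L, region$atg_index + pos - 1L, region$atg_index + pos)
  n <- nchar(region$sequence)
  if (any(idx < 1L | idx > n))
    stop("ATG-relative position out of range for region '", region$name,
         "' (valid ", -(region$atg_index - 1L), "..",
         n - region$atg_index + 1L, ")")
  idx
}

#' @rdname atg_to_index
#' @param idx integer vector of 1-based sequence indices
#' @export
index_to_atg <- function(idx, region) {
  stopifnot(inherits(region, "ReferenceRegion"))
  idx <- as.integer(idx)
  n <- nchar(region$sequence)
  if (any(idx < 1L | idx > n)) stop("index out of range")
  ifelse(idx >= region$atg_index,
         idx - region$atg_index + 1L,
         idx - region$atg_index)
}

#' Inclusive length of an ATG-relative span
#'
#' Counts the signed positions in \code{start..end} excluding the
#' non-existent zero, e.g. -51..+105 has length 156.
#' @param start,end ATG-relative endpoints, \code{start < end} allowed to
#'   straddle the origin
#' @return integer length
#' @export
atg_span_length <- function(start, end) {
  stopifnot(start != 0L, end != 0L, start <= end)
  as.integer(abs(end - start) + (sign(start) == sign(end)))
}

#' Extract a fragment by ATG-relative coordinates
#'
#' @inheritParams atg_to_index
#' @param start,end inclusive ATG-relative endpoints (\code{start <= end}
#'   under the signed ordering)
#' @return character DNA string of length \code{atg_span_length(start, end)}
#' @export
extract_fragment <- function(region, start, end) {
  stopifnot(start != 0L, end != 0L, start <= end)
  i <- atg_to_index(start, region)
  j <- atg_to_index(end, region)
  substr(region$sequence, i, j)
}

#' ATG-relative positions covered by a span
#'
#' @inheritParams atg_span_length
#' @return integer vector of the signed positions in order (zero omitted)
#' @export
atg_positions <- function(start, end) {
  stopifnot(start != 0L, end != 0L, start <= end)
  p <- seq.int(start, end)
  p[p != 0L]
}

#' Amplicon fragment with primer pair
#'
#' Endpoints are treated as inclusive amplicon boundaries in ATG-relative
#' coordinates (negative = upstream of the start codon).
#'
#' @param start,end ATG-relative boundaries, \code{start < end}
#' @param forward_primer,reverse_primer IUPAC DNA strings (reverse primer in
#'   its own 5'->3' orientation)
#' @return object of class \code{AmpliconFragment}
#' @export
amplicon_fragment <- function(start, end, forward_primer = NULL,
                              reverse_primer = NULL) {
  stopifnot(start != 0L, end != 0L, start < end)
  flen <- atg_span_length(start, end)
  if (!is.null(forward_primer) && !is.null(reverse_primer)) {
    stopifnot(nzchar(forward_primer), nzchar(reverse_primer))
    if (flen <= nchar(forward_primer) + nchar(reverse_primer))
      stop("fragment shorter than combined primer lengths")
  }
  structure(list(start = as.integer(start), end = as.integer(end),
                 forward_primer = forward_primer,
                 reverse_primer = reverse_primer),
            class = "AmpliconFragment")
}

#' @export
print.AmpliconFragment <- function(x, ...) {
  cat(sprintf("AmpliconFragment %+d..%+d (%d bp)\n", x$start, x$end,
              atg_span_length(x$start, x$end)))
  invisible(x)
}

as_fragment <- function(x) {
  if (inherits(x, "AmpliconFragment")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(amplicon_fragment(x[1], x[2]))
  stop("expected an AmpliconFragment or a length-2 start/end vector")
}
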