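# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", V = "B", D = "H", H = "D", "-" = "-")

#' Reverse-complement a DNA string (IUPAC aware)
#' @param x character scalar over IUPAC DNA codes
#' @return character scalar
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1L]])
  bad <- !ch %in% names(COMPLEMENT)
  if (any(bad)) stop("non-IUPAC character in sequence: ", ch[bad][1L])
  paste(COMPLEMENT[ch], collapse = "")
}

# Expansion of IUPAC one-letter codes to the set of plain bases they admit.
iupac_expand <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  code <- toupper(code)
  if (!code %in% names(map)) stop("not an IUPAC code: ", code)
  strsplit(map[[code]], "", fixed = TRUE)[[1L]]
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1L]]

assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  ch <- seq_chars(x)
  ok <- c(DNA_BASES, if (allow_n) "N")
  if (!all(ch %in% ok))
    stop(what, " contains characters outside {", paste(ok, collapse = ","), "}")
  invisible(paste(ch, collapse = ""))
}
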