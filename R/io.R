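# Tabular and FASTA input/output.
#
# Ct tables are plain TSV with header `sample fragment treatment replicate ct`
# (an optional `digestion` column is accepted and preserved).  Treatment
# tokens are normalized case-insensitively to "mcrbc"/"mock".  FASTA goes
# through Biostrings.

CT_COLUMNS <- c("sample", "fragment", "treatment", "replicate", "ct")

normalize_treatment <- function(x) {
  tok <- tolower(trimws(x))
  ok <- tok %in% c("mcrbc", "mock")
  if (!all(ok))
    stop("unknown treatment token(s): ",
         paste(unique(x[!ok]), collapse = ", "),
         " (expected mcrbc or mock)")
  tok
}

#' Read a qPCR crossing-threshold table
#'
#' @param path TSV file with header columns \code{sample}, \code{fragment},
#'   \code{treatment} (\code{mcrbc}/\code{mock}, case-insensitive),
#'   \code{replicate}, \code{ct} (decimal cycles; empty or NA allowed and
#'   flagged via \code{is.na}).  An optional \code{digestion} column keeps
#'   independent enzyme digestions apart.
#' @return data.frame of class \code{CtTable}
#' @export
read_ct_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           strip.white = TRUE, na.strings = c("NA", ""))
  missing_cols <- setdiff(CT_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("Ct table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  ct_num <- suppressWarnings(as.numeric(raw$ct))
  bad <- which(!is.na(raw$ct) & is.na(ct_num))
  if (length(bad))
    stop("Ct table ", path, ": non-numeric ct at data line(s) ",
         paste(bad + 1L, collapse = ", "))
  raw$ct <- ct_num
  raw$treatment <- normalize_treatment(raw$treatment)
  bad_tr <- which(!raw$treatment %in% c("mcrbc", "mock"))
  if (length(bad_tr))
    stop("Ct table ", path, ": unknown treatment at data line(s) ",
         paste(bad_tr + 1L, collapse = ", "))
  as_ct_table(raw)
}

#' Construct/validate a CtTable from a data.frame
#' @param df data.frame with the CtTable columns
#' @export
as_ct_table <- function(df) {
  stopifnot(all(CT_COLUMNS %in% names(df)))
  df$treatment <- normalize_treatment(df$treatment)
  keycols <- intersect(c("sample", "fragment", "treatment", "digestion",
                         "replicate"), names(df))
  key <- do.call(paste, c(df[keycols], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (", paste(keycols, collapse = ","), ") key(s): ",
         paste(utils::head(unique(gsub("\r", "/", key[duplicated(key)])), 3),
               collapse = "; "))
  df$ct <- as.numeric(df$ct)
  class(df) <- c("CtTable", "data.frame")
  df
}

#' Write a results table as TSV
#'
#' @param path output file
#' @param records data.frame
#' @param header_lines optional provenance comment lines (written with a
#'   leading \code{#})
#' @export
write_results <- function(path, records, header_lines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
write_ct_table <- function(path, records, header_lines = NULL) {
  stopifnot(all(CT_COLUMNS %in% names(records)))
  write_results(path, records, header_lines)
}

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings returning named character vectors, the
#' representation used throughout this package.
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector
#' @export
write_fasta <- function(path, seqs) {
  stopifnot(is.character(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
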