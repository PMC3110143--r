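#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases and maps T to U. Residues outside `{A,C,G,U}` are an input
#' error: the scanner's feature definitions are only meaningful on fully
#' determined RNA residues.
#'
#' @param x character vector of sequences (DNA or RNA, any case).
#' @return character vector over `{A,C,G,U}`.
#' @export
normalize_rna <- function(x) {
  out <- chartr("Tt", "Uu", toupper(x))
  out <- toupper(out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad))
    stop("sequence contains residues outside {A,C,G,T,U}: record(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  out
}

#' Reverse complement of an RNA sequence
#' @param x character vector over `{A,C,G,U}`.
#' @return character vector, reverse complements.
#' @export
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a (possibly gzipped) multi-record FASTA file
#'
#' Sequences are normalized to RNA; the original residue string is kept for
#' output echo.
#'
#' @param path FASTA file (plain or gzip).
#' @return data.frame with columns `id`, `sequence` (normalized RNA),
#'   `original` (as read), `offset` (0, position of fragment in parent).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  orig <- as.character(ss)
  data.frame(id = ids, sequence = normalize_rna(orig), original = orig,
             offset = 0L, row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#' @param seqs named character vector or data.frame with `id`, `sequence`.
#' @param path output file.
#' @param desc optional character vector of description-line suffixes.
#' @export
write_fasta <- function(seqs, path, desc = NULL) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    sq <- seqs$sequence
  } else {
    ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
    sq <- unname(seqs)
  }
  hdr <- if (is.null(desc)) ids else paste(ids, desc)
  x <- Biostrings::BStringSet(sq)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
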