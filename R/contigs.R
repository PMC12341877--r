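#' Contig sets and N-run bookkeeping
#'
#' Contigs are carried as a named character vector of IUPAC sequences; the
#' helpers here locate runs of N (the usual substrate for localising chimera
#' splits) and read/write FASTA through Biostrings.
#'
#' @param path FASTA file of contigs.
#' @return named character vector of sequences.
#' @export
read_contigs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_contigs
#' @param contigs named character vector of sequences.
#' @param width line width for FASTA wrapping.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Locate runs of consecutive N in a sequence
#'
#' @param seq a single sequence string.
#' @return integer matrix with columns `start`, `end`: 0-based half-open
#'   intervals of maximal N-runs, sorted by start; zero rows if none.
#' @export
contig_n_runs <- function(seq) {
  m <- gregexpr("N+", seq)[[1L]]
  if (m[1L] == -1L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  cbind(start = start, end = start + len)
}

#' Reverse-complement a sequence string (IUPAC, preserves N)
#' @param seq a single sequence string.
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
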