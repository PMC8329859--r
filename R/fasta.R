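#' Read and write FASTA files
#'
#' Thin wrappers around the Biostrings readers/writer; sequences travel as
#' named character vectors at the package interfaces.
#'
#' @param path file path.
#' @param x named character vector of sequences.
#' @param alphabet \code{"dna"} or \code{"protein"}.
#' @return `readFasta()` returns a named character vector; `writeFasta()`
#'   writes 60-column wrapped FASTA and returns `path` invisibly.
#' @name fastaIO
NULL

#' @rdname fastaIO
#' @export
readFasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- switch(alphabet,
                dna = Biostrings::readDNAStringSet(path),
                protein = Biostrings::readAAStringSet(path))
  out <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(out) <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  out
}

#' @rdname fastaIO
#' @export
writeFasta <- function(x, path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(x), !is.null(names(x)))
  set <- switch(alphabet,
                dna = Biostrings::DNAStringSet(x),
                protein = Biostrings::AAStringSet(x))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
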