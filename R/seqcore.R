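IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
STRICT_DNA <- c("A", "C", "G", "T")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Validate and normalize a raw sequence
#'
#' Strips FASTA header lines, whitespace and digits, upper-cases, and checks
#' the result against the requested alphabet.
#'
#' @param raw input text; may contain FASTA headers, whitespace and digits.
#' @param alphabet \code{"strict-dna"} (A/C/G/T only, required for templates
#'   that are annealed to or translated), \code{"iupac-dna"} (degenerate codes
#'   allowed, used for overhangs), or \code{"protein"} (20 one-letter codes).
#' @return The cleaned sequence as an upper-case character scalar.
#' @examples
#' validateSequence("atg gct\n", "strict-dna")
#' validateSequence(">x\nMKV", "protein")
#' @export
validateSequence <- function(raw,
                             alphabet = c("strict-dna", "iupac-dna", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(raw), length(raw) == 1L)
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  lines <- lines[!startsWith(trimws(lines), ">")]
  seq <- paste(lines, collapse = "")
  seq <- toupper(gsub("[[:space:][:digit:]]", "", seq))
  allowed <- switch(alphabet,
                    "strict-dna" = STRICT_DNA,
                    "iupac-dna" = IUPAC_DNA,
                    "protein" = AA20)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad))
    stop(sprintf("invalid character '%s' at position %d for alphabet %s",
                 chars[bad[1]], bad[1], alphabet), call. = FALSE)
  seq
}

#' Translate a coding sequence
#'
#' Translates a strict-DNA coding sequence with the standard genetic code (or
#' any NCBI code id accepted by [Biostrings::getGeneticCode()]). A single
#' trailing stop codon is tolerated: it sets the stop flag and is excluded
#' from the protein. Internal stop codons are errors.
#'
#' @param cdsSeq coding sequence; length must be divisible by 3.
#' @param table genetic-code id; \code{"standard"} (the default) or an id
#'   understood by [Biostrings::getGeneticCode()].
#' @return A list with elements \code{protein} (character scalar) and
#'   \code{stop} (logical: TRUE when a trailing stop codon was present).
#' @examples
#' translateCds("ATGGCTTGA")  # list(protein = "MA", stop = TRUE)
#' @export
translateCds <- function(cdsSeq, table = "standard") {
  cdsSeq <- validateSequence(cdsSeq, "strict-dna")
  if (nchar(cdsSeq) %% 3L != 0L)
    stop("coding sequence length must be divisible by 3 (got ",
         nchar(cdsSeq), ")", call. = FALSE)
  code <- if (identical(table, "standard")) Biostrings::GENETIC_CODE
          else Biostrings::getGeneticCode(table)
  n <- nchar(cdsSeq) %/% 3L
  codons <- substring(cdsSeq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(code[codons])
  stops <- which(aa == "*")
  hasStop <- FALSE
  if (length(stops)) {
    if (any(stops < n))
      stop("internal stop codon at codon ", stops[1], call. = FALSE)
    hasStop <- TRUE
    aa <- aa[-n]
  }
  if (!length(aa))
    stop("coding sequence contains only a stop codon", call. = FALSE)
  list(protein = paste(aa, collapse = ""), stop = hasStop)
}

#' Reverse complement
#'
#' IUPAC-aware reverse complement (R<->Y, K<->M, B<->V, D<->H, N<->N, ...).
#'
#' @param x DNA sequence (IUPAC codes allowed).
#' @return The reverse complement as a character scalar, case preserved as
#'   upper case.
#' @examples
#' revComp("ATCG")  # "CGAT"
#' @export
revComp <- function(x) {
  x <- validateSequence(x, "iupac-dna")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Map protein residues to codon spans
#'
#' Residue i of a protein corresponds to bases 3i-2..3i of its coding
#' sequence (1-based inclusive, relative to the first base of the CDS).
#'
#' @param residueIndex vector of 1-based residue indices.
#' @return A data.frame with columns \code{residue}, \code{dnaStart},
#'   \code{dnaEnd}.
#' @examples
#' residueToCodonSpan(c(1, 48, 58))
#' @export
residueToCodonSpan <- function(residueIndex) {
  residueIndex <- as.integer(residueIndex)
  if (any(residueIndex < 1L))
    stop("residue indices are 1-based and must be >= 1", call. = FALSE)
  data.frame(residue = residueIndex,
             dnaStart = 3L * residueIndex - 2L,
             dnaEnd = 3L * residueIndex)
}

orfScanStrand <- function(seq, strand, minCodons, startCodons, sourceId) {
  L <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, by = 3L, length.out = (L - frame) %/% 3L)
    if (!length(starts)) next
    codons <- substring(seq, starts, starts + 2L)
    open <- NA_integer_
    for (k in seq_along(codons)) {
      if (codons[k] %in% STOP_CODONS) {
        if (!is.na(open) && k - open >= minCodons) {
          s <- starts[open]; e <- starts[k] - 1L
          if (strand == "+") {
            src <- c(s, e)
          } else {
            src <- c(L - e + 1L, L - s + 1L)
          }
          out[[length(out) + 1L]] <- OrfCandidate(
            sourceId = sourceId, strand = strand,
            startBase = src[1], endBase = src[2],
            cds = substr(seq, s, e))
        }
        open <- NA_integer_
      } else if (is.na(open) && codons[k] %in% startCodons) {
        open <- k
      }
    }
  }
  out
}

#' Find open reading frames
#'
#' Scans a nucleotide sequence (optionally both strands) for maximal open
#' reading frames: each reported ORF runs from the first start codon after the
#' previous in-frame stop to the next in-frame stop codon. Intended for
#' multicistronic genes and small genomic records; input is capped at 1 Mb by
#' default.
#'
#' @param genomic the nucleotide sequence (strict DNA).
#' @param minCodons minimum translation length (amino acids) to report;
#'   default 50.
#' @param startCodons allowed start codons; defaults to the common bacterial
#'   set ATG/GTG/TTG.
#' @param bothStrands scan the reverse strand too (default TRUE).
#' @param maxBases input size limit in bases (default 1e6).
#' @param sourceId identifier recorded on each candidate.
#' @return A list of [OrfCandidate-class], sorted by forward-strand start
#'   coordinate (ties broken by strand then end).
#' @export
findOrfs <- function(genomic, minCodons = 50L,
                     startCodons = c("ATG", "GTG", "TTG"),
                     bothStrands = TRUE, maxBases = 1e6,
                     sourceId = "seq") {
  if (nchar(genomic) > maxBases)
    stop(sprintf("input of %d bases exceeds the %d-base limit",
                 nchar(genomic), as.integer(maxBases)), call. = FALSE)
  genomic <- validateSequence(genomic, "strict-dna")
  orfs <- orfScanStrand(genomic, "+", minCodons, startCodons, sourceId)
  if (bothStrands)
    orfs <- c(orfs,
              orfScanStrand(revComp(genomic), "-", minCodons, startCodons,
                            sourceId))
  if (!length(orfs)) return(list())
  ord <- order(vapply(orfs, function(o) o@startBase, integer(1)),
               vapply(orfs, function(o) o@strand, character(1)),
               vapply(orfs, function(o) o@endBase, integer(1)))
  orfs[ord]
}
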