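#' Match an ORF translation against a protein isoform
#'
#' Comparison happens at the protein level only: the translation of the
#' candidate is compared residue-by-residue with the isoform. Identical
#' sequences are a perfect match; equal-length sequences differing by at most
#' three single amino-acid substitutions are an imperfect match, with every
#' difference listed; anything else (including any length difference) does
#' not match. Raw DNA is never compared, so silent polymorphisms are
#' invisible by design.
#'
#' @param orf an [OrfCandidate-class].
#' @param isoform the isoform protein sequence (character scalar).
#' @param isoformId identifier recorded in the result.
#' @param maxSubstitutions largest substitution count still reported as an
#'   imperfect match (default 3).
#' @return A [MatchResult-class].
#' @export
matchOrfToIsoform <- function(orf, isoform, isoformId = "isoform",
                              maxSubstitutions = 3L) {
  stopifnot(is(orf, "OrfCandidate"), nzchar(isoform))
  isoform <- validateSequence(isoform, "protein")
  trans <- orf@translation
  noDiff <- data.frame(residue = integer(), isoformAa = character(),
                       orfAa = character())
  if (nchar(trans) != nchar(isoform)) {
    status <- "none"; diffs <- noDiff
  } else {
    a <- strsplit(isoform, "", fixed = TRUE)[[1]]
    b <- strsplit(trans, "", fixed = TRUE)[[1]]
    pos <- which(a != b)
    if (!length(pos)) {
      status <- "perfect"; diffs <- noDiff
    } else if (length(pos) <= maxSubstitutions) {
      status <- "imperfect"
      diffs <- data.frame(residue = pos, isoformAa = a[pos], orfAa = b[pos])
    } else {
      status <- "none"; diffs <- noDiff
    }
  }
  new("MatchResult", isoformId = isoformId, orf = orf, status = status,
      differences = diffs)
}

#' Collate coding-sequence matches per isoform
#'
#' Every isoform is compared with every candidate. Perfect matches are always
#' reported (sorted by source id); imperfect matches are reported only when
#' an isoform has no perfect match (sorted by difference count, then source
#' id). Isoforms without any match get an empty report with the no-match flag
#' set.
#'
#' @param isoforms named character vector of isoform protein sequences.
#' @param candidates list of [OrfCandidate-class].
#' @return A list of [IsoformReport-class], one per isoform, in input order.
#' @export
buildIsoformReports <- function(isoforms, candidates) {
  stopifnot(length(isoforms) >= 1L)
  if (is.null(names(isoforms)))
    names(isoforms) <- sprintf("isoform-%d", seq_along(isoforms))
  lapply(names(isoforms), function(id) {
    results <- lapply(candidates, matchOrfToIsoform, isoform = isoforms[[id]],
                      isoformId = id)
    status <- vapply(results, matchStatus, character(1))
    srcIds <- vapply(results, function(m) m@orf@sourceId, character(1))
    if (any(status == "perfect")) {
      keep <- which(status == "perfect")
      keep <- keep[order(srcIds[keep])]
    } else if (any(status == "imperfect")) {
      keep <- which(status == "imperfect")
      nd <- vapply(results[keep], function(m) nrow(m@differences), integer(1))
      keep <- keep[order(nd, srcIds[keep])]
    } else {
      keep <- integer()
    }
    new("IsoformReport", isoformId = id, matches = results[keep],
        crossRefs = unique(srcIds[keep]), noMatch = length(keep) == 0L)
  })
}

#' Extract coding-sequence candidates from a nucleotide record
#'
#' Reads a local GenBank flat file or a FASTA file. When the record carries
#' CDS features they are used directly (exons joined in feature order, the
#' complement strand honored, a trailing stop codon stripped); a plain FASTA
#' sequence falls back to an ORF scan via [findOrfs()].
#'
#' @param path path to the record file.
#' @param ... passed to [findOrfs()] for the FASTA fallback (e.g.
#'   \code{minCodons}).
#' @return A list of [OrfCandidate-class].
#' @export
parseCdsCandidates <- function(path, ...) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, ">")) {
    seqs <- readFasta(path, "dna")
    out <- list()
    for (i in seq_along(seqs))
      out <- c(out, findOrfs(seqs[[i]], sourceId = names(seqs)[i], ...))
    return(out)
  }
  if (!startsWith(first, "LOCUS"))
    stop("unrecognized record format (expected FASTA or GenBank): ", path,
         call. = FALSE)
  rec <- tryCatch(readGenBank(path),
                  error = function(e) stop("malformed record '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  f <- rec@features
  cdsRows <- which(f$key == "CDS")
  if (!length(cdsRows)) {
    return(findOrfs(rec@sequence, sourceId = rec@name, ...))
  }
  lapply(cdsRows, function(i) {
    p <- parseLocation(f$location[i])
    exons <- p$exons
    seg <- paste(substring(rec@sequence, exons$start, exons$end),
                 collapse = "")
    if (p$strand == "-") seg <- revComp(seg)
    if (nchar(seg) %% 3L != 0L)
      stop("malformed record '", rec@name, "': CDS length not divisible by 3",
           call. = FALSE)
    tr <- translateCds(seg)
    if (tr$stop) seg <- substr(seg, 1L, nchar(seg) - 3L)
    OrfCandidate(sourceId = rec@name, strand = p$strand,
                 startBase = min(exons$start), endBase = max(exons$end),
                 cds = seg, translation = tr$protein)
  })
}
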