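#' Enumerate all start/stop construct combinations
#'
#' Builds one construct per ordered boundary pair (s, t) with s <= t, sorted
#' by (s, t); pairs with s > t are silently excluded, so a residue marked as
#' both start and stop yields the single-residue construct. Each construct
#' carries the codons and residues of the chosen span and a full
#' physicochemical property set; when a [VectorSpec-class] is supplied the
#' tagged and protease-cleaved fusion forms are added via [fuseAndCleave()].
#'
#' @param starts,stops integer vectors of boundary residues (1-based).
#' @param protein the protein sequence of the chosen isoform.
#' @param cdsSeq its coding sequence (a trailing stop codon is allowed).
#' @param vector optional [VectorSpec-class].
#' @return A list of [Construct-class].
#' @export
enumerateConstructs <- function(starts, stops, protein, cdsSeq,
                                vector = NULL) {
  if (!length(starts) || !length(stops))
    stop("at least one start and one stop boundary are required",
         call. = FALSE)
  protein <- validateSequence(protein, "protein")
  cdsSeq <- validateSequence(cdsSeq, "strict-dna")
  nRes <- nchar(protein)
  if (proteinLengthOfCds(cdsSeq) != nRes)
    stop("coding sequence does not encode the given protein length",
         call. = FALSE)
  starts <- sort(unique(as.integer(starts)))
  stops <- sort(unique(as.integer(stops)))
  if (any(c(starts, stops) < 1L) || any(c(starts, stops) > nRes))
    stop("boundaries must lie within 1..", nRes, call. = FALSE)
  pairs <- expand.grid(stop = stops, start = starts)[, c("start", "stop")]
  pairs <- pairs[pairs$start <= pairs$stop, , drop = FALSE]
  pairs <- pairs[order(pairs$start, pairs$stop), , drop = FALSE]
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- pairs$start[i]; t <- pairs$stop[i]
    con <- new("Construct", start = s, stop = t,
               dna = substr(cdsSeq, 3L * s - 2L, 3L * t),
               protein = substr(protein, s, t),
               properties = propertySet(substr(protein, s, t)))
    if (!is.null(vector)) con <- fuseAndCleave(con, vector)
    con
  })
  out
}

#' Fuse a construct with a vector tag and model protease cleavage
#'
#' The tagged form is tagProtein + insert (+ the optional C-terminal tag).
#' When the vector defines a protease site, the cleaved form keeps the last
#' \code{cleavageOffset} residues of the tag on the insert; a vector without
#' a protease site simply has no cleaved form (not an error). Both fusion
#' forms get full property sets.
#'
#' @param construct a [Construct-class].
#' @param vector a [VectorSpec-class].
#' @return The construct with tagged/cleaved sequences and properties filled
#'   in.
#' @export
fuseAndCleave <- function(construct, vector) {
  stopifnot(is(construct, "Construct"), is(vector, "VectorSpec"))
  cterm <- vector@cTermTag
  tagged <- paste0(vector@tagProtein, construct@protein, cterm)
  construct@taggedProtein <- tagged
  construct@taggedProperties <- propertySet(tagged)
  if (!is.na(vector@cleavageOffset)) {
    tag <- vector@tagProtein
    kept <- if (vector@cleavageOffset > 0L)
      substr(tag, nchar(tag) - vector@cleavageOffset + 1L, nchar(tag)) else ""
    cleaved <- paste0(kept, construct@protein, cterm)
    construct@cleavedProtein <- cleaved
    construct@cleavedProperties <- propertySet(cleaved)
  } else {
    construct@cleavedProtein <- character(0)
    construct@cleavedProperties <- NULL
  }
  construct
}

propertyCols <- function(ps, prefix) {
  if (is.null(ps)) {
    cols <- as.list(rep(NA_real_, 4L))
  } else {
    cols <- list(ps@mw, ps@pi, ps@eps280Reduced, ps@eps280Cystine)
  }
  names(cols) <- paste0(prefix, c("mw", "pi", "eps280_reduced",
                                  "eps280_cystine"))
  cols
}

#' Serialize constructs as a bookkeeping table
#'
#' One row per construct: boundaries, protein length, DNA and protein
#' sequences, and MW / pI / extinction coefficients. When any construct
#' carries tagged or cleaved fusion forms, matching column groups are added.
#'
#' @param constructs list of [Construct-class].
#' @return A data.frame ready for [utils::write.csv()]; re-reading the CSV
#'   reproduces the sequences byte-identically.
#' @export
constructTable <- function(constructs) {
  stopifnot(length(constructs) > 0L)
  hasTag <- any(vapply(constructs, function(x)
    length(x@taggedProtein) > 0L, logical(1)))
  hasCleaved <- any(vapply(constructs, function(x)
    length(x@cleavedProtein) > 0L, logical(1)))
  rows <- lapply(constructs, function(x) {
    row <- c(list(start = x@start, stop = x@stop,
                  length = nchar(x@protein), dna = x@dna,
                  protein = x@protein),
             propertyCols(x@properties, ""))
    if (hasTag)
      row <- c(row,
               list(tagged_protein = if (length(x@taggedProtein))
                 x@taggedProtein else NA_character_),
               propertyCols(x@taggedProperties, "tagged_"))
    if (hasCleaved)
      row <- c(row,
               list(cleaved_protein = if (length(x@cleavedProtein))
                 x@cleavedProtein else NA_character_),
               propertyCols(x@cleavedProperties, "cleaved_"))
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Export construct DNA ("Save Construct DNA")
#'
#' Writes the amplified DNA of every construct in spreadsheet-compatible CSV
#' (columns: construct, start, stop, dna).
#'
#' @param constructs list of [Construct-class].
#' @param path output CSV path.
#' @param prefix construct-name prefix.
#' @return `path`, invisibly.
#' @export
saveConstructDna <- function(constructs, path, prefix = "construct") {
  tab <- data.frame(
    construct = vapply(constructs, function(x)
      sprintf("%s_%d-%d", prefix, x@start, x@stop), character(1)),
    start = vapply(constructs, function(x) x@start, integer(1)),
    stop = vapply(constructs, function(x) x@stop, integer(1)),
    dna = vapply(constructs, constructDna, character(1)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
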