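#' Accessors for package classes
#'
#' Small accessor generics for the sequence-design classes; use these rather
#' than reaching into slots.
#'
#' @param x an object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cds", function(x) standardGeneric("cds"))
#' @rdname accessors
#' @export
setMethod("cds", "OrfCandidate", function(x) x@cds)

#' @rdname accessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))
#' @rdname accessors
#' @export
setMethod("translation", "OrfCandidate", function(x) x@translation)

#' @rdname accessors
#' @export
setGeneric("orfStrand", function(x) standardGeneric("orfStrand"))
#' @rdname accessors
#' @export
setMethod("orfStrand", "OrfCandidate", function(x) x@strand)

#' @rdname accessors
#' @export
setGeneric("orfSpan", function(x) standardGeneric("orfSpan"))
#' @rdname accessors
#' @export
setMethod("orfSpan", "OrfCandidate",
          function(x) c(start = x@startBase, end = x@endBase))

#' @rdname accessors
#' @export
setGeneric("matchStatus", function(x) standardGeneric("matchStatus"))
#' @rdname accessors
#' @export
setMethod("matchStatus", "MatchResult", function(x) x@status)

#' @rdname accessors
#' @export
setGeneric("matchDifferences", function(x) standardGeneric("matchDifferences"))
#' @rdname accessors
#' @export
setMethod("matchDifferences", "MatchResult", function(x) x@differences)

#' @rdname accessors
#' @export
setGeneric("isoformMatches", function(x) standardGeneric("isoformMatches"))
#' @rdname accessors
#' @export
setMethod("isoformMatches", "IsoformReport", function(x) x@matches)

#' @rdname accessors
#' @export
setGeneric("primerName", function(x) standardGeneric("primerName"))
#' @rdname accessors
#' @export
setMethod("primerName", "Primer", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("primerDirection", function(x) standardGeneric("primerDirection"))
#' @rdname accessors
#' @export
setMethod("primerDirection", "Primer", function(x) x@direction)

#' @rdname accessors
#' @export
setGeneric("annealingRegion", function(x) standardGeneric("annealingRegion"))
#' @rdname accessors
#' @export
setMethod("annealingRegion", "Primer", function(x) x@annealing)

#' @rdname accessors
#' @export
setGeneric("primerOverhang", function(x) standardGeneric("primerOverhang"))
#' @rdname accessors
#' @export
setMethod("primerOverhang", "Primer", function(x) x@overhang)

#' @rdname accessors
#' @export
setGeneric("tmAnnealing", function(x) standardGeneric("tmAnnealing"))
#' @rdname accessors
#' @export
setMethod("tmAnnealing", "Primer", function(x) x@tmAnnealing)

#' @rdname accessors
#' @export
setGeneric("primerNotices", function(x) standardGeneric("primerNotices"))
#' @rdname accessors
#' @export
setMethod("primerNotices", "Primer", function(x) x@notices)

#' Full primer sequence
#'
#' Serializes a primer as overhang (lower case) followed by annealing region
#' (upper case), 5' to 3'.
#'
#' @param x a [Primer-class].
#' @return A character scalar.
#' @export
setGeneric("primerSequence", function(x) standardGeneric("primerSequence"))
#' @rdname primerSequence
#' @export
setMethod("primerSequence", "Primer", function(x)
  paste0(tolower(x@overhang@sequence), toupper(x@annealing)))

#' @rdname accessors
#' @export
setGeneric("constructProtein", function(x) standardGeneric("constructProtein"))
#' @rdname accessors
#' @export
setMethod("constructProtein", "Construct", function(x) x@protein)

#' @rdname accessors
#' @export
setGeneric("constructDna", function(x) standardGeneric("constructDna"))
#' @rdname accessors
#' @export
setMethod("constructDna", "Construct", function(x) x@dna)

#' @rdname accessors
#' @export
setGeneric("constructBoundaries", function(x) standardGeneric("constructBoundaries"))
#' @rdname accessors
#' @export
setMethod("constructBoundaries", "Construct",
          function(x) c(start = x@start, stop = x@stop))

#' Property accessors
#'
#' @param x a [Construct-class] or [PropertySet-class].
#' @param form which form of the construct: bare, tagged or cleaved.
#' @return For `properties()`, a [PropertySet-class] (or NULL when the form is
#'   absent); the scalar accessors return numbers.
#' @name properties
NULL

#' @rdname properties
#' @export
setGeneric("properties", function(x, form = "bare") standardGeneric("properties"))
#' @rdname properties
#' @export
setMethod("properties", "Construct", function(x, form = "bare") {
  switch(match.arg(form, c("bare", "tagged", "cleaved")),
         bare = x@properties,
         tagged = x@taggedProperties,
         cleaved = x@cleavedProperties)
})

#' @rdname properties
#' @export
setGeneric("mw", function(x) standardGeneric("mw"))
#' @rdname properties
#' @export
setMethod("mw", "PropertySet", function(x) x@mw)

#' @rdname properties
#' @export
setGeneric("pI", function(x) standardGeneric("pI"))
#' @rdname properties
#' @export
setMethod("pI", "PropertySet", function(x) x@pi)

#' @rdname properties
#' @export
setGeneric("eps280", function(x) standardGeneric("eps280"))
#' @rdname properties
#' @export
setMethod("eps280", "PropertySet",
          function(x) c(reduced = x@eps280Reduced, cystine = x@eps280Cystine))

#' @rdname accessors
#' @export
setGeneric("plasmidSequence", function(x) standardGeneric("plasmidSequence"))
#' @rdname accessors
#' @export
setMethod("plasmidSequence", "PlasmidRecord", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("plasmidFeatures", function(x) standardGeneric("plasmidFeatures"))
#' @rdname accessors
#' @export
setMethod("plasmidFeatures", "PlasmidRecord", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("trackSymbols", function(x) standardGeneric("trackSymbols"))
#' @rdname accessors
#' @export
setMethod("trackSymbols", "AnnotationTrack", function(x) x@symbols)

#' @rdname accessors
#' @export
setGeneric("trackLegend", function(x) standardGeneric("trackLegend"))
#' @rdname accessors
#' @export
setMethod("trackLegend", "AnnotationTrack", function(x) x@legend)

#' @rdname accessors
#' @export
setGeneric("vectorName", function(x) standardGeneric("vectorName"))
#' @rdname accessors
#' @export
setMethod("vectorName", "VectorSpec", function(x) x@name)

setMethod("show", "OrfCandidate", function(object) {
  cat(sprintf("OrfCandidate on %s (%s) %d..%d: %d codons\n",
              object@sourceId, object@strand, object@startBase,
              object@endBase, nchar(object@translation)))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult %s ~ %s: %s", object@isoformId,
              object@orf@sourceId, object@status))
  if (nrow(object@differences)) {
    d <- object@differences
    cat(" [", paste(sprintf("%s%d%s", d$isoformAa, d$residue, d$orfAa),
                    collapse = ", "), "]", sep = "")
  }
  cat("\n")
})

setMethod("show", "IsoformReport", function(object) {
  cat(sprintf("IsoformReport for %s: %d match(es)%s\n", object@isoformId,
              length(object@matches),
              if (object@noMatch) " (no matching coding sequence)" else ""))
  for (m in object@matches) show(m)
})

setMethod("show", "Primer", function(object) {
  cat(sprintf("Primer %s (%s, residue %d): %s  Tm=%.1fC\n",
              object@name, object@direction, object@boundaryResidue,
              primerSequence(object), object@tmAnnealing))
  if (length(object@notices))
    cat("  notices:", paste(object@notices, collapse = ", "), "\n")
})

setMethod("show", "Construct", function(object) {
  p <- object@properties
  cat(sprintf("Construct %d-%d (%d aa): MW %.2f Da, pI %.2f, eps280 %d/%d\n",
              object@start, object@stop, nchar(object@protein),
              p@mw, p@pi, as.integer(p@eps280Reduced),
              as.integer(p@eps280Cystine)))
  if (length(object@taggedProtein))
    cat(sprintf("  tagged: %d aa; cleaved: %s\n", nchar(object@taggedProtein),
                if (length(object@cleavedProtein))
                  sprintf("%d aa", nchar(object@cleavedProtein)) else "absent"))
})

setMethod("show", "VectorSpec", function(object) {
  cat(sprintf("VectorSpec %s: backbone %d bp, placeholder %d..%d, tag %d aa%s\n",
              object@name, nchar(object@backbone), object@placeholderStart,
              object@placeholderEnd, nchar(object@tagProtein),
              if (is.na(object@cleavageOffset)) " (no protease site)" else ""))
})

setMethod("show", "PlasmidRecord", function(object) {
  cat(sprintf("PlasmidRecord %s: %d bp %s, %d feature(s)\n", object@name,
              nchar(object@sequence),
              if (object@circular) "circular" else "linear",
              nrow(object@features)))
})

setMethod("show", "AnnotationTrack", function(object) {
  s <- object@symbols
  cat(sprintf("AnnotationTrack %s (%d residues): %s%s\n", object@name,
              nchar(s), substr(s, 1, 50), if (nchar(s) > 50) "..." else ""))
})
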