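#' @import methods
NULL

#' Open reading frame candidate
#'
#' An ORF located on a source nucleotide sequence. Coordinates are 1-based
#' inclusive on the forward strand of the source; for minus-strand candidates
#' the coding sequence is the reverse complement of the spanned region. The
#' stored \code{cds} excludes the stop codon, so its translation has exactly
#' \code{nchar(cds)/3} residues.
#'
#' @slot sourceId identifier of the source record.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot startBase,endBase 1-based inclusive span on the source.
#' @slot cds coding sequence (strict DNA, no stop codon).
#' @slot translation protein sequence encoded by \code{cds}.
#' @exportClass OrfCandidate
setClass("OrfCandidate",
  representation(
    sourceId = "character",
    strand = "character",
    startBase = "integer",
    endBase = "integer",
    cds = "character",
    translation = "character"
  )
)

setValidity("OrfCandidate", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (nchar(object@cds) == 0L)
    msg <- c(msg, "cds must be non-empty")
  if (nchar(object@cds) %% 3L != 0L)
    msg <- c(msg, "cds length must be divisible by 3")
  if (nchar(object@translation) * 3L != nchar(object@cds))
    msg <- c(msg, "translation length must equal cds length / 3")
  if (object@startBase < 1L || object@endBase < object@startBase)
    msg <- c(msg, "coordinates must satisfy 1 <= startBase <= endBase")
  if (length(msg)) msg else TRUE
})

#' Construct an OrfCandidate
#'
#' @param sourceId source record identifier.
#' @param strand \code{"+"} or \code{"-"}.
#' @param startBase,endBase 1-based inclusive coordinates on the source.
#' @param cds coding sequence without the stop codon.
#' @param translation protein translation of \code{cds}; computed when omitted.
#' @return An [OrfCandidate-class] object.
#' @export
OrfCandidate <- function(sourceId, strand, startBase, endBase, cds,
                         translation = NULL) {
  if (is.null(translation))
    translation <- translateCds(cds)$protein
  new("OrfCandidate", sourceId = as.character(sourceId), strand = strand,
      startBase = as.integer(startBase), endBase = as.integer(endBase),
      cds = cds, translation = translation)
}

#' Result of matching an ORF translation against a protein isoform
#'
#' Matching is performed at the protein level only and tolerates up to three
#' single amino-acid substitutions; unequal lengths never match.
#'
#' @slot isoformId isoform identifier.
#' @slot orf the [OrfCandidate-class] that was compared.
#' @slot status \code{"perfect"}, \code{"imperfect"} or \code{"none"}.
#' @slot differences data.frame with columns \code{residue}, \code{isoformAa},
#'   \code{orfAa}; empty unless status is \code{"imperfect"}.
#' @exportClass MatchResult
setClass("MatchResult",
  representation(
    isoformId = "character",
    orf = "OrfCandidate",
    status = "character",
    differences = "data.frame"
  )
)

setValidity("MatchResult", function(object) {
  msg <- character()
  n <- nrow(object@differences)
  if (!object@status %in% c("perfect", "imperfect", "none"))
    msg <- c(msg, "status must be perfect, imperfect or none")
  if (object@status == "perfect" && n != 0L)
    msg <- c(msg, "perfect matches must list no differences")
  if (object@status == "imperfect" && (n < 1L || n > 3L))
    msg <- c(msg, "imperfect matches must list 1-3 differences")
  if (length(msg)) msg else TRUE
})

#' Per-isoform collation of coding-sequence matches
#'
#' @slot isoformId isoform identifier.
#' @slot matches list of [MatchResult-class], perfect matches first. Imperfect
#'   matches are listed only when no perfect match exists for the isoform.
#' @slot crossRefs source record ids of the listed matches.
#' @slot noMatch TRUE when no candidate matched the isoform at all.
#' @exportClass IsoformReport
setClass("IsoformReport",
  representation(
    isoformId = "character",
    matches = "list",
    crossRefs = "character",
    noMatch = "logical"
  )
)

#' A primer overhang
#'
#' A 5' extension that does not anneal to the template. Degenerate IUPAC codes
#' are permitted here (and only here); \code{frameOffset} records the reading
#' frame of the insert's first codon relative to the overhang 3' end (0 means
#' the insert starts a codon immediately after the overhang).
#'
#' @slot sequence overhang bases (IUPAC DNA, may be empty).
#' @slot origin \code{"vector"}, \code{"restriction"} or \code{"custom"}.
#' @slot frameOffset integer 0-2.
#' @exportClass Overhang
setClass("Overhang",
  representation(
    sequence = "character",
    origin = "character",
    frameOffset = "integer"
  )
)

setValidity("Overhang", function(object) {
  msg <- character()
  if (!object@origin %in% c("vector", "restriction", "custom"))
    msg <- c(msg, "origin must be vector, restriction or custom")
  if (object@frameOffset < 0L || object@frameOffset > 2L)
    msg <- c(msg, "frameOffset must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Construct an Overhang
#'
#' @param sequence overhang bases (IUPAC DNA codes allowed; case-insensitive).
#'   May be empty.
#' @param origin one of \code{"vector"}, \code{"restriction"}, \code{"custom"}.
#' @param frameOffset reading-frame offset (0-2) of the insert's first codon
#'   relative to the overhang 3' end.
#' @return An [Overhang-class] object.
#' @export
Overhang <- function(sequence = "", origin = "custom", frameOffset = 0L) {
  if (nzchar(sequence))
    sequence <- validateSequence(sequence, "iupac-dna")
  new("Overhang", sequence = sequence, origin = origin,
      frameOffset = as.integer(frameOffset))
}

#' A PCR primer
#'
#' @slot name primer name (\code{prefix_Fw_position} / \code{prefix_Rv_position}).
#' @slot direction \code{"Fw"} or \code{"Rv"}.
#' @slot boundaryResidue the 1-based protein residue the primer was designed for.
#' @slot annealing template-annealing region (strict DNA, 5'->3').
#' @slot overhang the attached [Overhang-class] (may be empty).
#' @slot tmAnnealing melting temperature (degrees C) of the annealing region;
#'   overhangs never contribute.
#' @slot notices zero or more of \code{"start-codon-in-overhang"},
#'   \code{"stop-codon-in-overhang"}, \code{"tm-unreachable"}.
#' @exportClass Primer
setClass("Primer",
  representation(
    name = "character",
    direction = "character",
    boundaryResidue = "integer",
    annealing = "character",
    overhang = "Overhang",
    tmAnnealing = "numeric",
    notices = "character"
  )
)

setValidity("Primer", function(object) {
  msg <- character()
  if (!object@direction %in% c("Fw", "Rv"))
    msg <- c(msg, "direction must be 'Fw' or 'Rv'")
  if (!grepl("^[ACGT]+$", object@annealing))
    msg <- c(msg, "annealing region must be strict DNA (A/C/G/T)")
  bad <- setdiff(object@notices,
                 c("start-codon-in-overhang", "stop-codon-in-overhang",
                   "tm-unreachable"))
  if (length(bad))
    msg <- c(msg, paste("unknown notice:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Physicochemical property set
#'
#' Molecular weight (average masses), isoelectric point (Bjellqvist pKa set)
#' and molar extinction coefficients at 280 nm under reducing conditions and
#' assuming all cysteine pairs form cystines.
#'
#' @slot mw molecular weight, Da.
#' @slot pi isoelectric point, pH units.
#' @slot eps280Reduced,eps280Cystine extinction coefficients, M^-1 cm^-1.
#' @exportClass PropertySet
setClass("PropertySet",
  representation(
    mw = "numeric",
    pi = "numeric",
    eps280Reduced = "numeric",
    eps280Cystine = "numeric"
  )
)

setValidity("PropertySet", function(object) {
  msg <- character()
  if (object@mw <= 0) msg <- c(msg, "mw must be positive")
  if (object@pi <= 0 || object@pi >= 14)
    msg <- c(msg, "pi must lie in (0, 14)")
  if (object@eps280Reduced < 0 || object@eps280Cystine < 0)
    msg <- c(msg, "extinction coefficients must be >= 0")
  if (length(msg)) msg else TRUE
})

setClassUnion("PropertySetOrNULL", c("PropertySet", "NULL"))

#' An expression construct
#'
#' A truncation of the protein of interest defined by a start/stop residue
#' pair (both included), with its amplified DNA, protein sequence, and
#' physicochemical properties for the bare and, when a vector is set, the
#' tagged and protease-cleaved forms.
#'
#' @slot start,stop 1-based residue boundaries, start <= stop.
#' @slot dna codons start..stop of the coding sequence.
#' @slot protein residues start..stop of the protein.
#' @slot properties [PropertySet-class] of the bare protein.
#' @slot taggedProtein,cleavedProtein fusion sequences (length-0 character
#'   when absent).
#' @slot taggedProperties,cleavedProperties property sets of the fusion forms
#'   (NULL when absent).
#' @exportClass Construct
setClass("Construct",
  representation(
    start = "integer",
    stop = "integer",
    dna = "character",
    protein = "character",
    properties = "PropertySet",
    taggedProtein = "character",
    cleavedProtein = "character",
    taggedProperties = "PropertySetOrNULL",
    cleavedProperties = "PropertySetOrNULL"
  ),
  prototype(taggedProtein = character(0), cleavedProtein = character(0),
            taggedProperties = NULL, cleavedProperties = NULL)
)

setValidity("Construct", function(object) {
  msg <- character()
  if (object@start > object@stop)
    msg <- c(msg, "start must be <= stop")
  if (nchar(object@protein) != object@stop - object@start + 1L)
    msg <- c(msg, "protein length must equal stop - start + 1")
  if (nchar(object@dna) != 3L * nchar(object@protein))
    msg <- c(msg, "dna length must equal 3 x protein length")
  if (length(msg)) msg else TRUE
})

#' A cloning vector definition
#'
#' @slot name vector name (unique within a config file).
#' @slot overhangFw,overhangRv forward/reverse primer overhangs.
#' @slot tagProtein N-terminal tag residues fused to the insert.
#' @slot cleavageOffset residues of the tag retained on the insert after
#'   protease cleavage; NA when the vector has no protease site.
#' @slot cTermTag optional C-terminal tag ("" when absent).
#' @slot backbone full vector sequence carrying an insertion placeholder.
#' @slot placeholderStart,placeholderEnd 1-based span of the placeholder.
#' @slot features data.frame (name, start, end, type) of backbone annotations.
#' @exportClass VectorSpec
setClass("VectorSpec",
  representation(
    name = "character",
    overhangFw = "Overhang",
    overhangRv = "Overhang",
    tagProtein = "character",
    cleavageOffset = "integer",
    cTermTag = "character",
    backbone = "character",
    placeholderStart = "integer",
    placeholderEnd = "integer",
    features = "data.frame"
  )
)

setValidity("VectorSpec", function(object) {
  msg <- character()
  L <- nchar(object@backbone)
  if (object@placeholderStart < 1L || object@placeholderEnd > L ||
      object@placeholderStart > object@placeholderEnd)
    msg <- c(msg, "placeholder span must lie within the backbone")
  if (!is.na(object@cleavageOffset) &&
      object@cleavageOffset > nchar(object@tagProtein))
    msg <- c(msg, "cleavageOffset cannot exceed the tag length")
  if (length(msg)) msg else TRUE
})

#' An annotated plasmid record
#'
#' A circular plasmid sequence plus its feature table, ready to be written as
#' a GenBank flat file.
#'
#' @slot name record name (LOCUS).
#' @slot sequence plasmid sequence (strict DNA).
#' @slot circular topology flag.
#' @slot features data.frame with columns \code{key}, \code{start}, \code{end},
#'   \code{strand} and a list column \code{qualifiers} of named character
#'   vectors.
#' @exportClass PlasmidRecord
setClass("PlasmidRecord",
  representation(
    name = "character",
    sequence = "character",
    circular = "logical",
    features = "data.frame"
  )
)

setValidity("PlasmidRecord", function(object) {
  msg <- character()
  L <- nchar(object@sequence)
  f <- object@features
  if (nrow(f)) {
    if (any(f$start < 1L) || any(f$end > L) || any(f$start > f$end))
      msg <- c(msg, "every feature span must lie within the sequence")
  }
  if (length(msg)) msg else TRUE
})

#' A per-residue annotation track
#'
#' One single-character symbol per query residue (blank = no annotation),
#' displayed vertically aligned under the query sequence.
#'
#' @slot name track name.
#' @slot symbols string of per-residue symbols, same length as the query.
#' @slot legend named character vector mapping symbol to meaning.
#' @slot metadata free-form list (e.g. construct-boundary hover data).
#' @exportClass AnnotationTrack
setClass("AnnotationTrack",
  representation(
    name = "character",
    symbols = "character",
    legend = "character",
    metadata = "list"
  ),
  prototype(metadata = list())
)

#' Construct an AnnotationTrack
#'
#' @param name track name.
#' @param symbols per-residue symbol string.
#' @param legend named character vector (names are symbols).
#' @param metadata optional list of extra data.
#' @return An [AnnotationTrack-class] object.
#' @export
AnnotationTrack <- function(name, symbols, legend = character(), metadata = list()) {
  new("AnnotationTrack", name = name, symbols = symbols,
      legend = legend, metadata = metadata)
}
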