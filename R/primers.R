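growToTargetTm <- function(segmentAt, maxAvail, opts) {
  # segmentAt(L) returns the candidate annealing region of length L
  notices <- character()
  if (!is.null(opts$fixedLength)) {
    L <- as.integer(opts$fixedLength)
    if (L > maxAvail)
      stop("annealing region of ", L, " bases would run past the CDS boundary",
           call. = FALSE)
    seq <- segmentAt(L)
    return(list(annealing = seq,
                tm = meltingTemperature(seq, opts$tmMethod, opts$na,
                                        opts$primerConc),
                notices = notices))
  }
  minLen <- as.integer(opts$minLen)
  maxLen <- min(as.integer(opts$maxLen), maxAvail)
  if (minLen > maxAvail)
    stop("annealing region of ", minLen,
         " bases would run past the CDS boundary", call. = FALSE)
  L <- minLen
  repeat {
    seq <- segmentAt(L)
    tm <- meltingTemperature(seq, opts$tmMethod, opts$na, opts$primerConc)
    if (tm >= opts$targetTm || L >= maxLen) break
    L <- L + 1L
  }
  if (tm < opts$targetTm) notices <- "tm-unreachable"
  list(annealing = seq, tm = tm, notices = notices)
}

primerOpts <- function(targetTm = 65, fixedLength = NULL, minLen = 15L,
                       maxLen = 60L, tmMethod = "nearest-neighbor",
                       na = 0.05, primerConc = 5e-7) {
  list(targetTm = targetTm, fixedLength = fixedLength, minLen = minLen,
       maxLen = maxLen, tmMethod = tmMethod, na = na, primerConc = primerConc)
}

#' Design boundary primers
#'
#' Turns a protein-residue boundary into a PCR primer on the coding sequence.
#' A start residue yields a forward primer whose annealing region begins
#' exactly at the residue's first codon base (base 3s-2); a stop residue
#' yields a reverse primer whose annealing region is the reverse complement
#' of the CDS segment ending at base 3t. The clicked residue is therefore
#' always included in the amplified construct. In Tm mode (the default,
#' target 65 C) the annealing region grows one base at a time from
#' \code{minLen} until the target is met; if \code{maxLen} (or the CDS end)
#' is reached first the primer carries a \code{tm-unreachable} notice. With
#' \code{fixedLength} set, exactly that length is used.
#'
#' @param cdsSeq coding sequence of the chosen isoform (strict DNA, no
#'   internal stop; a trailing stop codon is allowed and ignored for
#'   coordinates beyond the last residue).
#' @param startResidue,stopResidue 1-based boundary residue.
#' @param targetTm target melting temperature, degrees C (default 65).
#' @param fixedLength fixed annealing length; overrides Tm mode.
#' @param minLen,maxLen annealing-length bounds in Tm mode (defaults 15/60).
#' @param tmMethod,na,primerConc passed to [meltingTemperature()].
#' @param prefix primer-name prefix; the primer is named
#'   \code{prefix_Fw_position} or \code{prefix_Rv_position}.
#' @return A [Primer-class] with an empty overhang.
#' @seealso [attachOverhang()], [primerTable()]
#' @export
designForwardPrimer <- function(cdsSeq, startResidue, targetTm = 65,
                                fixedLength = NULL, minLen = 15L,
                                maxLen = 60L, tmMethod = "nearest-neighbor",
                                na = 0.05, primerConc = 5e-7,
                                prefix = "construct") {
  cdsSeq <- validateSequence(cdsSeq, "strict-dna")
  nRes <- proteinLengthOfCds(cdsSeq)
  startResidue <- as.integer(startResidue)
  if (startResidue < 1L || startResidue > nRes)
    stop("start residue ", startResidue, " outside protein (1..", nRes, ")",
         call. = FALSE)
  b0 <- 3L * startResidue - 2L
  res <- growToTargetTm(function(L) substr(cdsSeq, b0, b0 + L - 1L),
                        maxAvail = nchar(cdsSeq) - b0 + 1L,
                        primerOpts(targetTm, fixedLength, minLen, maxLen,
                                   tmMethod, na, primerConc))
  new("Primer", name = sprintf("%s_Fw_%d", prefix, startResidue),
      direction = "Fw", boundaryResidue = startResidue,
      annealing = res$annealing, overhang = Overhang(""),
      tmAnnealing = res$tm, notices = res$notices)
}

#' @rdname designForwardPrimer
#' @export
designReversePrimer <- function(cdsSeq, stopResidue, targetTm = 65,
                                fixedLength = NULL, minLen = 15L,
                                maxLen = 60L, tmMethod = "nearest-neighbor",
                                na = 0.05, primerConc = 5e-7,
                                prefix = "construct") {
  cdsSeq <- validateSequence(cdsSeq, "strict-dna")
  nRes <- proteinLengthOfCds(cdsSeq)
  stopResidue <- as.integer(stopResidue)
  if (stopResidue < 1L || stopResidue > nRes)
    stop("stop residue ", stopResidue, " outside protein (1..", nRes, ")",
         call. = FALSE)
  e0 <- 3L * stopResidue
  res <- growToTargetTm(function(L) revComp(substr(cdsSeq, e0 - L + 1L, e0)),
                        maxAvail = e0,
                        primerOpts(targetTm, fixedLength, minLen, maxLen,
                                   tmMethod, na, primerConc))
  new("Primer", name = sprintf("%s_Rv_%d", prefix, stopResidue),
      direction = "Rv", boundaryResidue = stopResidue,
      annealing = res$annealing, overhang = Overhang(""),
      tmAnnealing = res$tm, notices = res$notices)
}

# residues encoded by a CDS, ignoring a trailing stop codon if present
proteinLengthOfCds <- function(cdsSeq) {
  n <- nchar(cdsSeq) %/% 3L
  if (nchar(cdsSeq) %% 3L != 0L)
    stop("coding sequence length must be divisible by 3", call. = FALSE)
  last <- substr(cdsSeq, 3L * n - 2L, 3L * n)
  if (last %in% STOP_CODONS) n - 1L else n
}

scanOverhangNotices <- function(overhang, direction) {
  seq <- toupper(overhang@sequence)
  L <- nchar(seq)
  if (L < 3L) return(character())
  f <- overhang@frameOffset
  if (direction == "Fw") {
    # in-frame codon positions p satisfy (L + 1 + f - p) mod 3 == 0
    pos <- seq_len(L - 2L)
    inFrame <- pos[(L + 1L + f - pos) %% 3L == 0L]
    codons <- substring(seq, inFrame, inFrame + 2L)
    if (any(codons == "ATG")) return("start-codon-in-overhang")
  } else {
    # the sense strand downstream of the insert is the reverse complement of
    # the overhang; its codons continue the insert's frame
    sense <- revComp(seq)
    pos <- seq_len(L - 2L)
    inFrame <- pos[(pos - 1L - f) %% 3L == 0L]
    codons <- substring(sense, inFrame, inFrame + 2L)
    if (any(codons %in% STOP_CODONS)) return("stop-codon-in-overhang")
  }
  character()
}

#' Attach an overhang to a primer
#'
#' Prepends a cloning overhang (5' of the annealing region). The annealing
#' region and its Tm are untouched: overhangs never contribute to the melting
#' temperature. The overhang is scanned in the insert's reading frame for an
#' ATG start codon (forward primers) or a stop codon on the encoded sense
#' strand (reverse primers), and a notice is recorded when one is found.
#'
#' @param primer a [Primer-class].
#' @param overhang an [Overhang-class] (may contain IUPAC degenerate codes).
#' @return The primer with the overhang attached and notices updated.
#' @export
attachOverhang <- function(primer, overhang) {
  stopifnot(is(primer, "Primer"), is(overhang, "Overhang"))
  if (!nzchar(overhang@sequence)) return(primer)
  notices <- union(primer@notices,
                   scanOverhangNotices(overhang, primer@direction))
  initialize(primer, overhang = overhang, notices = notices)
}

#' Restriction-cloning overhangs
#'
#' Builds a primer overhang for conventional restriction cloning: an optional
#' spacer (to allow efficient digestion near the fragment end) followed by
#' the enzyme's recognition sequence. Recognition sequences come from the
#' shipped REBASE-derived enzyme table
#' (\code{system.file("extdata", "restriction_enzymes.tsv", package =
#' "ConstructDesigner")}).
#'
#' @param enzyme enzyme name, e.g. \code{"BamHI"}.
#' @param spacer bases 5' of the recognition site (default \code{""}).
#' @param frameOffset reading-frame offset passed to [Overhang()].
#' @param enzymeTable optional data.frame(enzyme, site) overriding the
#'   shipped table.
#' @return An [Overhang-class] with origin \code{"restriction"}.
#' @examples
#' restrictionOverhang("BamHI", spacer = "aaa")
#' @export
restrictionOverhang <- function(enzyme, spacer = "", frameOffset = 0L,
                                enzymeTable = NULL) {
  if (is.null(enzymeTable)) {
    path <- system.file("extdata", "restriction_enzymes.tsv",
                        package = "ConstructDesigner")
    enzymeTable <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  row <- match(enzyme, enzymeTable$enzyme)
  if (is.na(row))
    stop("unknown enzyme '", enzyme, "'; available: ",
         paste(sort(enzymeTable$enzyme), collapse = ", "), call. = FALSE)
  seq <- paste0(if (nzchar(spacer)) validateSequence(spacer, "iupac-dna") else "",
                enzymeTable$site[row])
  new("Overhang", sequence = toupper(seq), origin = "restriction",
      frameOffset = as.integer(frameOffset))
}

#' Serialize primers as a spreadsheet-ready table
#'
#' One row per primer with its name (\code{prefix_Fw_position} /
#' \code{prefix_Rv_position}), direction, boundary residue, full sequence
#' (overhang in lower case, annealing region in upper case), length, Tm of
#' the annealing region and any notices. Name collisions (two primers with
#' the same direction and boundary) are errors.
#'
#' @param primers list of [Primer-class].
#' @param prefix name prefix chosen by the user.
#' @return A data.frame ready for [utils::write.csv()].
#' @export
primerTable <- function(primers, prefix) {
  stopifnot(length(primers) > 0L, is.character(prefix), nzchar(prefix))
  names_ <- vapply(primers, function(p)
    sprintf("%s_%s_%d", prefix, p@direction, p@boundaryResidue), character(1))
  if (anyDuplicated(names_))
    stop("duplicate primer names: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "),
         call. = FALSE)
  data.frame(
    name = names_,
    direction = vapply(primers, primerDirection, character(1)),
    boundary = vapply(primers, function(p) p@boundaryResidue, integer(1)),
    sequence = vapply(primers, primerSequence, character(1)),
    length = vapply(primers, function(p) nchar(primerSequence(p)), integer(1)),
    tm = round(vapply(primers, tmAnnealing, numeric(1)), 2),
    notices = vapply(primers, function(p)
      paste(p@notices, collapse = ";"), character(1)))
}

#' In-silico PCR with a designed primer pair
#'
#' Locates the forward annealing region and the reverse complement of the
#' reverse annealing region on the template, extends, and excises the
#' amplicon. The returned \code{core} is the matched template segment
#' (annealing to annealing); \code{amplicon} additionally carries the primer
#' overhangs, i.e. overhangFw + core + revComp(overhangRv).
#'
#' @param template template DNA (strict).
#' @param fw,rv forward/reverse [Primer-class].
#' @return list(core, amplicon) or an error when an annealing region does not
#'   match the template exactly once.
#' @export
pcrAmplify <- function(template, fw, rv) {
  template <- validateSequence(template, "strict-dna")
  fwSite <- gregexpr(fw@annealing, template, fixed = TRUE)[[1]]
  rvSite <- gregexpr(revComp(rv@annealing), template, fixed = TRUE)[[1]]
  if (fwSite[1] == -1L || length(fwSite) != 1L)
    stop("forward annealing region must match the template exactly once",
         call. = FALSE)
  if (rvSite[1] == -1L || length(rvSite) != 1L)
    stop("reverse annealing region must match the template exactly once",
         call. = FALSE)
  from <- as.integer(fwSite[1])
  to <- as.integer(rvSite[1]) + nchar(rv@annealing) - 1L
  if (to < from)
    stop("primer pair does not amplify a forward segment", call. = FALSE)
  core <- substr(template, from, to)
  list(core = core,
       amplicon = paste0(toupper(fw@overhang@sequence), core,
                         revComp0(rv@overhang@sequence)))
}

# revComp that passes empty strings through
revComp0 <- function(x) if (nzchar(x)) revComp(x) else ""
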