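# Single-letter codes for post-translational modifications.
PTM_LEGEND <- c(
  acetylation = "A",
  ubiquitination = "U",
  phosphorylation = "P",
  methylation = "M",
  glycosylation = "N",
  sumoylation = "S",
  disulfide = "^",
  other = "o")
PTM_MULTIPLE <- "+"

#' Build a post-translational-modification track
#'
#' One single-letter symbol per modified residue (A acetylation, U
#' ubiquitination, ^ disulfide link, ...); a residue carrying more than one
#' modification type is shown as '+'. Because recorded modifications always
#' refer to the canonical isoform, the track is disabled (all blank, with
#' \code{metadata$disabled = TRUE}) when an alternative splicing variant has
#' been selected.
#'
#' @param modifications data.frame with columns \code{residue} (1-based) and
#'   \code{type} (one of the names of the shipped legend; unknown types map
#'   to "other").
#' @param queryLength query protein length.
#' @param canonical FALSE when the user selected a non-canonical isoform.
#' @return An [AnnotationTrack-class].
#' @export
ptmTrack <- function(modifications, queryLength, canonical = TRUE) {
  blank <- strrep(" ", queryLength)
  if (!canonical)
    return(AnnotationTrack("PTM", blank,
                           legend = character(),
                           metadata = list(disabled = TRUE,
                                           reason = "non-canonical isoform")))
  if (nrow(modifications)) {
    if (any(modifications$residue < 1L | modifications$residue > queryLength))
      stop("modification residue outside the query (1..", queryLength, ")",
           call. = FALSE)
  }
  sym <- strsplit(blank, "", fixed = TRUE)[[1]]
  legendUsed <- character()
  for (res in unique(modifications$residue)) {
    types <- unique(modifications$type[modifications$residue == res])
    if (length(types) > 1L) {
      sym[res] <- PTM_MULTIPLE
      legendUsed[PTM_MULTIPLE] <- "multiple known modifications"
    } else {
      type <- if (types %in% names(PTM_LEGEND)) types else "other"
      sym[res] <- PTM_LEGEND[[type]]
      legendUsed[PTM_LEGEND[[type]]] <- type
    }
  }
  AnnotationTrack("PTM", paste(sym, collapse = ""), legend = legendUsed,
                  metadata = list(disabled = FALSE))
}

#' Build a span track
#'
#' Marks residue spans (e.g. predicted domains, coiled coils, NLS) with a
#' repeated symbol.
#'
#' @param name track name.
#' @param spans data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive).
#' @param queryLength query protein length.
#' @param symbol the fill symbol (default \code{"*"}).
#' @param meaning legend text for the symbol.
#' @return An [AnnotationTrack-class].
#' @export
spanTrack <- function(name, spans, queryLength, symbol = "*",
                      meaning = "span of the predicted domain") {
  sym <- rep(" ", queryLength)
  for (i in seq_len(nrow(spans))) {
    span <- seq.int(max(1L, spans$start[i]), min(queryLength, spans$end[i]))
    sym[span] <- symbol
  }
  AnnotationTrack(name, paste(sym, collapse = ""),
                  legend = stats::setNames(meaning, symbol))
}

#' Read a per-residue predictor output
#'
#' Ingests externally produced predictor results from a documented
#' two-column tabular file: either per-residue symbols (columns residue,
#' symbol) or spans (columns start, end).
#'
#' @param path TSV file with a header row.
#' @param name track name.
#' @param queryLength query protein length.
#' @param ... passed to [spanTrack()] when the file contains spans.
#' @return An [AnnotationTrack-class].
#' @export
readPredictorTrack <- function(path, name, queryLength, ...) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("residue", "symbol") %in% names(tab))) {
    sym <- rep(" ", queryLength)
    ok <- tab$residue >= 1L & tab$residue <= queryLength
    sym[tab$residue[ok]] <- tab$symbol[ok]
    return(AnnotationTrack(name, paste(sym, collapse = "")))
  }
  if (all(c("start", "end") %in% names(tab)))
    return(spanTrack(name, tab, queryLength, ...))
  stop("predictor file must have columns residue+symbol or start+end: ",
       path, call. = FALSE)
}

#' Render annotation tracks under the query sequence
#'
#' Produces the fixed-width text report: 60-column blocks with a residue
#' ruler, the query sequence row, and every track row vertically aligned
#' beneath it, followed by the merged legend.
#'
#' @param tracks list of [AnnotationTrack-class]; every track must have
#'   exactly one symbol per query residue.
#' @param query the query protein sequence.
#' @param width block width in columns (default 60).
#' @return The report as a single character scalar.
#' @export
mergeTracks <- function(tracks, query, width = 60L) {
  query <- validateSequence(query, "protein")
  L <- nchar(query)
  for (tr in tracks)
    if (nchar(tr@symbols) != L)
      stop("track '", tr@name, "' has ", nchar(tr@symbols),
           " symbols for a query of length ", L, call. = FALSE)
  labWidth <- max(5L, nchar("query"),
                  vapply(tracks, function(t) nchar(t@name), integer(1)))
  lines <- character()
  for (from in seq.int(1L, L, by = width)) {
    to <- min(from + width - 1L, L)
    # ruler: residue numbers right-aligned every 10 columns
    ruler <- rep(" ", to - from + 1L)
    for (p in seq.int(from, to)) {
      if (p %% 10L == 0L) {
        num <- as.character(p)
        at <- p - from + 1L
        if (at >= nchar(num)) {
          for (k in seq_len(nchar(num)))
            ruler[at - nchar(num) + k] <- substr(num, k, k)
        }
      }
    }
    lines <- c(lines,
               paste0(strrep(" ", labWidth + 1L), paste(ruler, collapse = "")),
               paste0(formatC("query", width = labWidth, flag = "-"), " ",
                      substr(query, from, to)))
    for (tr in tracks)
      lines <- c(lines,
                 paste0(formatC(tr@name, width = labWidth, flag = "-"), " ",
                        substr(tr@symbols, from, to)))
    lines <- c(lines, "")
  }
  legend <- unlist(lapply(tracks, function(t) {
    if (!length(t@legend)) return(character())
    sprintf("  %s  %s (%s)", names(t@legend), t@legend, t@name)
  }))
  if (length(legend))
    lines <- c(lines, "Legend:", unique(legend))
  paste(lines, collapse = "\n")
}

#' Write / read the symbol matrix of a track set
#'
#' TSV round-trip of the per-residue symbol matrix: one row per residue,
#' columns position, query and one per track.
#'
#' @param tracks list of [AnnotationTrack-class].
#' @param query the query protein sequence.
#' @param path TSV path.
#' @return `writeTrackMatrix()` returns `path` invisibly; `readTrackMatrix()`
#'   returns a data.frame with the same columns.
#' @name trackMatrix
#' @export
writeTrackMatrix <- function(tracks, query, path) {
  L <- nchar(query)
  tab <- data.frame(position = seq_len(L),
                    query = strsplit(query, "", fixed = TRUE)[[1]])
  for (tr in tracks)
    tab[[tr@name]] <- strsplit(tr@symbols, "", fixed = TRUE)[[1]]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname trackMatrix
#' @export
readTrackMatrix <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    quote = "")
}
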