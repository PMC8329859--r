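OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a tabular homology-hit file
#'
#' Reads 12-column BLAST outfmt-6-style TSV (no header) into a data.frame
#' with the standard column names.
#'
#' @param path path to the TSV file.
#' @return A data.frame with columns qseqid, sseqid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' @export
readHitsTable <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12L)
    stop("expected 12 tab-separated columns (BLAST outfmt 6), got ",
         ncol(tab), call. = FALSE)
  names(tab) <- OUTFMT6_COLS
  tab
}

#' Filter homology hits for homolog display
#'
#' Keeps hits that pass the significance rule (E-value at most
#' \code{maxEvalue}) and whose query coverage, computed per hit as
#' (qend - qstart + 1) / query length, is at least \code{minCoverage}.
#' Requiring high coverage favours true orthologues over proteins sharing a
#' single domain with the query.
#'
#' @param hits outfmt-6-style data.frame (see [readHitsTable()]).
#' @param queryLength query protein length in residues.
#' @param maxEvalue significance cutoff (default 0.001).
#' @param minCoverage minimum fractional coverage (default 0.75).
#' @return The retained rows of \code{hits}.
#' @export
filterHomologHits <- function(hits, queryLength, maxEvalue = 0.001,
                              minCoverage = 0.75) {
  if (!nrow(hits)) return(hits)
  coverage <- (hits$qend - hits$qstart + 1) / queryLength
  hits[hits$evalue <= maxEvalue & coverage >= minCoverage, , drop = FALSE]
}

#' Select near-identical hits for alignment mapping
#'
#' Picks up to \code{maxHits} hits with identity strictly greater than
#' \code{minIdentity} percent, sorted by identity descending (ties broken by
#' E-value ascending). These are the candidates used to map the query onto a
#' precomputed alignment of a near-identical homolog.
#'
#' @param hits outfmt-6-style data.frame.
#' @param minIdentity identity threshold in percent, exclusive (default 95).
#' @param maxHits cap on returned hits (default 5).
#' @return The selected rows of \code{hits}.
#' @export
selectMappingCandidates <- function(hits, minIdentity = 95, maxHits = 5L) {
  keep <- hits[hits$pident > minIdentity, , drop = FALSE]
  keep <- keep[order(-keep$pident, keep$evalue), , drop = FALSE]
  utils::head(keep, maxHits)
}

#' Classify structure-database hits into similarity tiers
#'
#' Assigns every hit to exactly one tier by percent identity: PDB_95
#' (>= 95), PDB50_to_95 ([50, 95)), PDB30_to_50 ([30, 50)), or none. Each
#' tier gets a per-residue track marking the covered query residues with
#' '='; PDB_95 hits additionally mark the deposited-construct boundaries
#' with '>' (start) and '<' (stop), carrying the structure id and chain as
#' hover metadata.
#'
#' @param hits outfmt-6-style data.frame; sseqid is expected to carry the
#'   structure id and chain (e.g. \code{"1ABC_A"}).
#' @param queryLength query protein length.
#' @return list(tiers, tracks): \code{tiers} is a factor (one level per hit
#'   in \{PDB_95, PDB50_to_95, PDB30_to_50, none\}); \code{tracks} is a named
#'   list of three [AnnotationTrack-class] objects.
#' @export
classifyPdbTiers <- function(hits, queryLength) {
  tierOf <- function(id) {
    if (id >= 95) "PDB_95"
    else if (id >= 50) "PDB50_to_95"
    else if (id >= 30) "PDB30_to_50"
    else "none"
  }
  levels_ <- c("PDB_95", "PDB50_to_95", "PDB30_to_50", "none")
  tiers <- factor(vapply(hits$pident, tierOf, character(1)),
                  levels = levels_)
  blank <- strrep(" ", queryLength)
  tracks <- list()
  for (tier in levels_[1:3]) {
    sym <- strsplit(blank, "", fixed = TRUE)[[1]]
    rows <- which(tiers == tier)
    for (i in rows) {
      span <- seq.int(max(1L, hits$qstart[i]), min(queryLength, hits$qend[i]))
      sym[span] <- "="
    }
    legend <- c("=" = "query residues covered by a hit in this tier")
    boundaries <- NULL
    if (tier == "PDB_95" && length(rows)) {
      boundaries <- data.frame(position = integer(), marker = character(),
                               structure = character())
      for (i in rows) {
        if (hits$qstart[i] >= 1L && hits$qstart[i] <= queryLength) {
          sym[hits$qstart[i]] <- ">"
          boundaries <- rbind(boundaries,
                              data.frame(position = hits$qstart[i],
                                         marker = ">",
                                         structure = hits$sseqid[i]))
        }
        if (hits$qend[i] >= 1L && hits$qend[i] <= queryLength) {
          sym[hits$qend[i]] <- "<"
          boundaries <- rbind(boundaries,
                              data.frame(position = hits$qend[i],
                                         marker = "<",
                                         structure = hits$sseqid[i]))
        }
      }
      legend <- c(legend,
                  ">" = "start of a deposited construct",
                  "<" = "stop of a deposited construct")
    }
    tracks[[tier]] <- AnnotationTrack(
      name = tier, symbols = paste(sym, collapse = ""), legend = legend,
      metadata = if (is.null(boundaries)) list() else
        list(boundaries = boundaries))
  }
  list(tiers = tiers, tracks = tracks)
}

#' Rename a database identifier for display
#'
#' Rewrites an opaque accession as \code{G.species_gene_(ACCESSION)} with the
#' genus abbreviated to its initial (e.g. Mus musculus / gmnn / H3BLK4_MOUSE
#' becomes \code{M.musculus_gmnn_(H3BLK4_MOUSE)}). Missing fields are
#' omitted; when no metadata is available the raw identifier is returned
#' unchanged.
#'
#' @param rawId the original identifier.
#' @param species binomial species name ("Genus species"), or NA.
#' @param gene gene symbol, or NA.
#' @param accession accession to show in parentheses, or NA.
#' @return The display name as a character scalar.
#' @export
renameIdentifier <- function(rawId, species = NA, gene = NA, accession = NA) {
  miss <- function(x) is.null(x) || length(x) == 0L || is.na(x) || !nzchar(x)
  if (miss(species)) return(rawId)
  parts <- strsplit(trimws(species), "[[:space:]]+")[[1]]
  abbrev <- if (length(parts) >= 2L)
    paste0(substr(parts[1], 1L, 1L), ".", paste(parts[-1], collapse = "_"))
  else parts[1]
  out <- abbrev
  if (!miss(gene)) out <- paste0(out, "_", gene)
  if (!miss(accession)) out <- paste0(out, "_(", accession, ")")
  out
}
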