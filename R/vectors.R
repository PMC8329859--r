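IUPAC_MATCHES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

iupacCompatible <- function(pattern, strict) {
  if (nchar(pattern) != nchar(strict)) return(FALSE)
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  s <- strsplit(toupper(strict), "", fixed = TRUE)[[1]]
  all(mapply(function(pc, sc) sc %in% IUPAC_MATCHES[[pc]], p, s))
}

vcError <- function(fieldPath, msg) {
  stop(sprintf("vector config: %s: %s", fieldPath, msg), call. = FALSE)
}

requireField <- function(entry, field, idx) {
  if (is.null(entry[[field]]))
    vcError(sprintf("vectors[%d].%s", idx, field), "missing required field")
  entry[[field]]
}

parseVectorEntry <- function(entry, idx) {
  name <- requireField(entry, "name", idx)
  backbone <- validateSequence(requireField(entry, "backbone", idx),
                               "strict-dna")
  ph <- requireField(entry, "placeholder", idx)
  if (is.null(ph$start) || is.null(ph$end))
    vcError(sprintf("vectors[%d].placeholder", idx), "needs start and end")
  if (ph$start < 1 || ph$end > nchar(backbone) || ph$start > ph$end)
    vcError(sprintf("vectors[%d].placeholder", idx),
            "span must lie within the backbone")
  mkOverhang <- function(field) {
    oh <- requireField(entry, field, idx)
    seq <- requireField(oh, "sequence", idx)
    Overhang(seq, origin = "vector",
             frameOffset = as.integer(oh$frame_offset %||% 0L))
  }
  ohFw <- mkOverhang("overhang_fw")
  ohRv <- mkOverhang("overhang_rv")
  # LIC overhangs are copies of the backbone flanking the insertion point
  upstream <- substr(backbone, ph$start - nchar(ohFw@sequence), ph$start - 1L)
  downstream <- substr(backbone, ph$end + 1L, ph$end + nchar(ohRv@sequence))
  if (!iupacCompatible(ohFw@sequence, upstream))
    vcError(sprintf("vectors[%d].overhang_fw", idx),
            "not consistent with the backbone 5' of the placeholder")
  if (!iupacCompatible(revComp(ohRv@sequence), downstream))
    vcError(sprintf("vectors[%d].overhang_rv", idx),
            "not consistent with the backbone 3' of the placeholder")
  tag <- entry$tag_protein %||% ""
  if (nzchar(tag)) tag <- validateSequence(tag, "protein")
  cterm <- entry$c_term_tag %||% ""
  if (nzchar(cterm)) cterm <- validateSequence(cterm, "protein")
  off <- if (is.null(entry$cleavage_offset)) NA_integer_
         else as.integer(entry$cleavage_offset)
  features <- data.frame(name = character(), start = integer(),
                         end = integer(), type = character())
  for (f in entry$features %||% list()) {
    if (is.null(f$name) || is.null(f$start) || is.null(f$end))
      vcError(sprintf("vectors[%d].features", idx),
              "each feature needs name, start, end")
    features <- rbind(features,
                      data.frame(name = f$name, start = as.integer(f$start),
                                 end = as.integer(f$end),
                                 type = f$type %||% "misc_feature"))
  }
  new("VectorSpec", name = name, overhangFw = ohFw, overhangRv = ohRv,
      tagProtein = tag, cleavageOffset = off, cTermTag = cterm,
      backbone = backbone, placeholderStart = as.integer(ph$start),
      placeholderEnd = as.integer(ph$end), features = features)
}

#' Load cloning-vector definitions from a config file
#'
#' Reads a YAML vector config (see the shipped, fully documented synthetic
#' example at \code{system.file("extdata", "vectors_synthetic.yaml", package
#' = "ConstructDesigner")}). Schema violations are reported with the field
#' path; duplicate vector names are errors; each overhang must be consistent
#' with the backbone flank next to the insertion placeholder.
#'
#' @param path path to the YAML file.
#' @return A named list of [VectorSpec-class].
#' @export
loadVectorConfig <- function(path) {
  if (!file.exists(path)) stop("vector config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$vectors) || !length(cfg$vectors))
    vcError("vectors", "missing or empty")
  specs <- lapply(seq_along(cfg$vectors),
                  function(i) parseVectorEntry(cfg$vectors[[i]], i))
  nm <- vapply(specs, vectorName, character(1))
  if (anyDuplicated(nm))
    vcError("vectors", paste("duplicate vector names:",
                             paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  stats::setNames(specs, nm)
}

#' Build an annotated plasmid map
#'
#' Replaces the vector's insertion placeholder with the construct DNA and
#' recalculates feature coordinates: features upstream of the placeholder
#' keep their positions, features downstream shift by (insert length -
#' placeholder length), and features overlapping the placeholder are
#' dropped. A CDS feature covering the insert (with its translation) is
#' added.
#'
#' @param vector a [VectorSpec-class].
#' @param insert construct DNA (strict, length divisible by 3).
#' @param constructName label for the insert feature and the record.
#' @return A circular [PlasmidRecord-class] of length
#'   backbone - placeholder + insert.
#' @export
buildPlasmidMap <- function(vector, insert, constructName) {
  stopifnot(is(vector, "VectorSpec"))
  if (!nzchar(insert)) stop("insert must be non-empty", call. = FALSE)
  insert <- validateSequence(insert, "strict-dna")
  if (nchar(insert) %% 3L != 0L)
    stop("insert length must be divisible by 3", call. = FALSE)
  phStart <- vector@placeholderStart
  phEnd <- vector@placeholderEnd
  backbone <- vector@backbone
  delta <- nchar(insert) - (phEnd - phStart + 1L)
  sequence <- paste0(substr(backbone, 1L, phStart - 1L), insert,
                     substr(backbone, phEnd + 1L, nchar(backbone)))
  feats <- emptyFeatureTable()
  bf <- vector@features
  for (i in seq_len(nrow(bf))) {
    if (bf$end[i] < phStart) {
      s <- bf$start[i]; e <- bf$end[i]
    } else if (bf$start[i] > phEnd) {
      s <- bf$start[i] + delta; e <- bf$end[i] + delta
    } else {
      next  # overlaps the placeholder; dropped
    }
    row <- data.frame(key = if (bf$type[i] == "CDS") "CDS" else "misc_feature",
                      start = s, end = e, strand = "+",
                      location = sprintf("%d..%d", s, e))
    row$qualifiers <- list(c(label = bf$name[i], note = bf$type[i]))
    feats <- rbind(feats, row)
  }
  insEnd <- phStart + nchar(insert) - 1L
  insRow <- data.frame(key = "CDS", start = phStart, end = insEnd,
                       strand = "+",
                       location = sprintf("%d..%d", phStart, insEnd))
  insRow$qualifiers <- list(c(label = constructName,
                              translation = translateCds(insert)$protein))
  feats <- rbind(feats, insRow)
  feats <- feats[order(feats$start, feats$end), , drop = FALSE]
  rownames(feats) <- NULL
  new("PlasmidRecord", name = constructName, sequence = sequence,
      circular = TRUE, features = feats)
}
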