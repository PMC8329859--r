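senseCodons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

codonsFor <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))[[aa]]
}

randomProtein <- function(n, startMet = TRUE) {
  aa <- sample(AA20, n, replace = TRUE)
  if (startMet) aa[1] <- "M"
  paste(aa, collapse = "")
}

backTranslate <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(aa, function(a) sample(codonsFor(a), 1L), character(1)),
        collapse = "")
}

mutateProtein <- function(protein, nSub = 0L, nIns = 0L, nDel = 0L) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (nSub > 0L) {
    pos <- sample(seq_along(aa), nSub)
    for (p in pos) aa[p] <- sample(setdiff(AA20, aa[p]), 1L)
  }
  if (nDel > 0L) aa <- aa[-sample(seq_along(aa), nDel)]
  if (nIns > 0L) {
    for (i in seq_len(nIns)) {
      p <- sample(seq_len(length(aa) + 1L), 1L)
      aa <- append(aa, sample(AA20, 1L), after = p - 1L)
    }
  }
  paste(aa, collapse = "")
}

#' Generate synthetic test fixtures
#'
#' Deterministic (per seed) generator for the synthetic records used
#' throughout the test-suite and the worked examples: clean ORFs, isoform
#' sets differing by parameterized edits, genomic sequences with embedded
#' ORFs, cloning-vector definitions and tabular homology-hit tables spanning
#' the filter thresholds.
#'
#' @param kind one of \code{"orf"}, \code{"isoform-set"}, \code{"genomic"},
#'   \code{"vector"}, \code{"hits"}.
#' @param seed integer seed; the same (kind, parameters, seed) always yields
#'   the same output.
#' @param ... kind-specific parameters:
#'   \describe{
#'     \item{orf}{\code{nCodons} (translation length, default 100): returns
#'       list(name, dna, protein); dna is ATG + sense codons + TAA.}
#'     \item{isoform-set}{\code{baseLength} (default 300), \code{edits}: a list
#'       of per-isoform edit counts, each c(sub=, ins=, del=): returns
#'       list(isoforms, cds) where cds encodes the first (canonical) isoform
#'       and carries a trailing stop.}
#'     \item{genomic}{\code{length} (default 3000), \code{orfCodons} (vector of
#'       translation lengths to embed), \code{strands} (recycled over ORFs):
#'       returns list(dna, orfTable).}
#'     \item{vector}{\code{backboneLength} (default 5000),
#'       \code{placeholderLength} (default 20), \code{tagProtein},
#'       \code{cleavageOffset}, \code{name}: returns a [VectorSpec-class].}
#'     \item{hits}{\code{queryLength} (default 200), \code{coverages} (percent,
#'       default 60..95 by 5), \code{identities}, \code{evalues}: returns a
#'       12-column BLAST outfmt-6-style data.frame, one row per coverage.}
#'   }
#' @return See above; structure depends on \code{kind}.
#' @examples
#' fx <- generateFixture("orf", nCodons = 30, seed = 1)
#' translateCds(fx$dna)$protein == fx$protein
#' @export
generateFixture <- function(kind, ..., seed) {
  stopifnot(!missing(seed))
  set.seed(as.integer(seed))
  params <- list(...)
  switch(kind,
    "orf" = fixtureOrf(params),
    "isoform-set" = fixtureIsoformSet(params),
    "genomic" = fixtureGenomic(params),
    "vector" = fixtureVector(params),
    "hits" = fixtureHits(params),
    stop("unknown fixture kind: ", kind, call. = FALSE)
  )
}

fixtureOrf <- function(params) {
  n <- params$nCodons %||% 100L
  stopifnot(n >= 1L)
  protein <- randomProtein(n)
  dna <- paste0(backTranslate(protein), "TAA")
  # guarantee a canonical start codon so the ORF is self-contained
  dna <- paste0("ATG", substr(dna, 4L, nchar(dna)))
  protein <- paste0("M", substr(protein, 2L, n))
  list(name = params$name %||% "synthetic_orf", dna = dna, protein = protein)
}

fixtureIsoformSet <- function(params) {
  n <- params$baseLength %||% 300L
  edits <- params$edits %||% list(c(sub = 0L), c(sub = 2L), c(sub = 0L, del = 25L))
  base <- randomProtein(n)
  isoforms <- character(length(edits))
  for (i in seq_along(edits)) {
    e <- edits[[i]]
    isoforms[i] <- mutateProtein(base,
                                 nSub = e[["sub"]] %||% 0L,
                                 nIns = if ("ins" %in% names(e)) e[["ins"]] else 0L,
                                 nDel = if ("del" %in% names(e)) e[["del"]] else 0L)
  }
  names(isoforms) <- sprintf("isoform-%d", seq_along(isoforms))
  list(isoforms = isoforms, cds = paste0(backTranslate(base), "TAA"))
}

fixtureGenomic <- function(params) {
  L <- params$length %||% 3000L
  orfCodons <- params$orfCodons %||% c(60L, 80L)
  strands <- rep_len(params$strands %||% "+", length(orfCodons))
  background <- paste(sample(STRICT_DNA, L, replace = TRUE), collapse = "")
  tab <- data.frame(start = integer(), end = integer(),
                    strand = character(), nCodons = integer(),
                    protein = character())
  pos <- 1L
  for (i in seq_along(orfCodons)) {
    fx <- fixtureOrf(list(nCodons = orfCodons[i]))
    dna <- fx$dna
    gap <- sample(20:80, 1L)
    start <- pos + gap
    end <- start + nchar(dna) - 1L
    if (end > L) stop("genomic fixture too short for requested ORFs")
    ins <- if (strands[i] == "+") dna else revComp(dna)
    background <- paste0(substr(background, 1L, start - 1L), ins,
                         substr(background, end + 1L, L))
    tab <- rbind(tab, data.frame(start = start, end = end - 3L,
                                 strand = strands[i], nCodons = orfCodons[i],
                                 protein = fx$protein))
    pos <- end + 1L
  }
  if (any(tab$strand == "-")) {
    neg <- tab$strand == "-"
    # coordinates of the sense span (stop codon excluded) on the forward strand
    tab$start[neg] <- tab$start[neg] + 3L
    tab$end[neg] <- tab$end[neg] + 3L
  }
  list(dna = background, orfTable = tab)
}

fixtureVector <- function(params) {
  bl <- as.integer(params$backboneLength %||% 5000L)
  pl <- as.integer(params$placeholderLength %||% 20L)
  tag <- params$tagProtein %||% "MHHHHHHENLYFQG"
  off <- params$cleavageOffset %||% 1L
  name <- params$name %||% "synthetic-lic-1"
  ohFwLen <- params$overhangFwLength %||% 15L
  ohRvLen <- params$overhangRvLength %||% 15L
  stopifnot(bl >= pl + ohFwLen + ohRvLen + 200L)
  backbone <- paste(sample(STRICT_DNA, bl, replace = TRUE), collapse = "")
  phStart <- as.integer(bl %/% 2L)
  phEnd <- phStart + pl - 1L
  ohFw <- substr(backbone, phStart - ohFwLen, phStart - 1L)
  ohRv <- revComp(substr(backbone, phEnd + 1L, phEnd + ohRvLen))
  features <- data.frame(
    name = c("promoter", "tag", "terminator"),
    start = c(phStart - 150L, phStart - ohFwLen, phEnd + 30L),
    end = c(phStart - 100L, phStart - 1L, phEnd + 80L),
    type = c("regulatory", "CDS", "regulatory"))
  new("VectorSpec", name = name,
      overhangFw = Overhang(ohFw, origin = "vector", frameOffset = 0L),
      overhangRv = Overhang(ohRv, origin = "vector", frameOffset = 0L),
      tagProtein = tag, cleavageOffset = as.integer(off),
      cTermTag = params$cTermTag %||% "",
      backbone = backbone, placeholderStart = phStart,
      placeholderEnd = phEnd, features = features)
}

fixtureHits <- function(params) {
  qlen <- params$queryLength %||% 200L
  cov <- params$coverages %||% seq(60, 95, by = 5)
  n <- length(cov)
  ident <- rep_len(params$identities %||% round(stats::runif(n, 30, 100), 1), n)
  eval <- rep_len(params$evalues %||% 10^stats::runif(n, -30, -4), n)
  qend <- pmin(qlen, as.integer(round(cov / 100 * qlen)))
  data.frame(
    qseqid = "query", sseqid = sprintf("subj%02d_A", seq_len(n)),
    pident = ident, length = qend, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = qend, sstart = 1L, send = qend,
    evalue = eval, bitscore = round(2 * qend * ident / 100, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
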