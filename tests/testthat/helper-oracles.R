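# Independent oracles used across the suite.

# Brute-force ORF scan: for every in-frame stop codon (per strand and frame),
# take the earliest start codon after the previous stop. Implemented by
# per-stop grouping, independently of the package's single-pass scanner.
bruteForceOrfs <- function(seq, minCodons, startCodons = c("ATG", "GTG", "TTG"),
                           bothStrands = TRUE) {
  scanStrand <- function(s, strand) {
    L <- nchar(s)
    out <- list()
    for (frame in 0:2) {
      starts <- seq.int(frame + 1L, by = 3L, length.out = (L - frame) %/% 3L)
      if (!length(starts)) next
      codons <- substring(s, starts, starts + 2L)
      stopIdx <- which(codons %in% c("TAA", "TAG", "TGA"))
      startIdx <- which(codons %in% startCodons)
      prev <- 0L
      for (si in stopIdx) {
        cand <- startIdx[startIdx > prev & startIdx < si]
        if (length(cand)) {
          k <- min(cand)
          if (si - k >= minCodons) {
            a <- starts[k]; b <- starts[si] - 1L
            coords <- if (strand == "+") c(a, b) else c(L - b + 1L, L - a + 1L)
            out[[length(out) + 1L]] <-
              data.frame(strand = strand, start = coords[1], end = coords[2],
                         cds = substr(s, a, b))
          }
        }
        prev <- si
      }
    }
    out
  }
  res <- scanStrand(seq, "+")
  if (bothStrands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    res <- c(res, scanStrand(rc, "-"))
  }
  if (!length(res))
    return(data.frame(strand = character(), start = integer(),
                      end = integer(), cds = character()))
  tab <- do.call(rbind, res)
  tab[order(tab$start, tab$strand, tab$end), , drop = FALSE]
}

orfTableOf <- function(orfs) {
  if (!length(orfs))
    return(data.frame(strand = character(), start = integer(),
                      end = integer(), cds = character()))
  tab <- do.call(rbind, lapply(orfs, function(o)
    data.frame(strand = orfStrand(o), start = orfSpan(o)[["start"]],
               end = orfSpan(o)[["end"]], cds = cds(o))))
  tab[order(tab$start, tab$strand, tab$end), , drop = FALSE]
}

# Exhaustive-extension Tm oracle: the smallest annealing length in
# [minLen, maxLen] whose Tm meets the target, scanning every length.
smallestTmLength <- function(segmentAt, minLen, maxLen, target) {
  for (L in seq.int(minLen, maxLen)) {
    if (meltingTemperature(segmentAt(L)) >= target) return(L)
  }
  NA_integer_
}

# Run a python snippet (Biopython is the independent cross-check for the
# nearest-neighbor Tm model and the GenBank flat-file format).
runPython <- function(code) {
  out <- system2("python", c("-"), input = code, stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  out
}

biopythonTmNN <- function(seqs) {
  code <- paste0(
    "from Bio.SeqUtils import MeltingTemp as mt\n",
    "for s in ", sprintf("[%s]", paste(sprintf("'%s'", seqs), collapse = ",")),
    ":\n",
    "    print(mt.Tm_NN(s, nn_table=mt.DNA_NN3, Na=50, dnac1=250, dnac2=250,",
    " saltcorr=5))\n")
  as.numeric(runPython(code))
}

# Parse a GenBank file with Biopython; returns list(length, sequence,
# features data.frame(key, start, end)) with 1-based inclusive spans.
biopythonReadGenBank <- function(path) {
  code <- paste0(
    "from Bio import SeqIO\n",
    sprintf("r = SeqIO.read('%s', 'genbank')\n", path),
    "print(len(r.seq)); print(str(r.seq).upper())\n",
    "for f in r.features:\n",
    "    print(f.type, int(f.location.start)+1, int(f.location.end))\n")
  out <- runPython(code)
  out <- out[!grepl("Warning|warn", out)]
  feats <- do.call(rbind, lapply(out[-(1:2)], function(line) {
    tok <- strsplit(trimws(line), " ")[[1]]
    data.frame(key = tok[1], start = as.integer(tok[2]),
               end = as.integer(tok[3]))
  }))
  list(length = as.integer(out[1]), sequence = out[2], features = feats)
}

randomStrictDna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

randomPeptide <- function(n)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
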