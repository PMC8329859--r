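orfFor <- function(protein, sourceId = "src1") {
  code <- Biostrings::GENETIC_CODE
  aa <- strsplit(protein, "")[[1]]
  dna <- paste(vapply(aa, function(a)
    names(code)[code == a][1], character(1)), collapse = "")
  OrfCandidate(sourceId, "+", 1L, nchar(dna), dna, protein)
}

substituteAa <- function(protein, k) {
  aa <- strsplit(protein, "")[[1]]
  pos <- sample(seq_along(aa), k)
  for (p in pos)
    aa[p] <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                            aa[p]), 1)
  paste(aa, collapse = "")
}

test_that("match status is perfect at 0, imperfect at 1-3, none at >=4 substitutions", {
  set.seed(31)
  for (seed in 1:3) {
    iso <- generateFixture("orf", nCodons = 80, seed = seed)$protein
    for (k in 0:6) {
      orf <- orfFor(if (k == 0) iso else substituteAa(iso, k))
      m <- matchOrfToIsoform(orf, iso)
      expected <- if (k == 0) "perfect" else if (k <= 3) "imperfect" else "none"
      expect_identical(matchStatus(m), expected)
      expect_identical(nrow(matchDifferences(m)), if (k <= 3) k else 0L)
    }
  }
})

test_that("length differences never match and differences are fully listed", {
  iso <- "MKVAEDLG"
  longer <- orfFor("MKVAEDLGG")
  expect_identical(matchStatus(matchOrfToIsoform(longer, iso)), "none")
  mutated <- orfFor("MKVREDLH")
  m <- matchOrfToIsoform(mutated, iso)
  d <- matchDifferences(m)
  expect_identical(d$residue, c(4L, 8L))
  expect_identical(d$isoformAa, c("A", "G"))
  expect_identical(d$orfAa, c("R", "H"))
})

test_that("reports pair isoforms with perfect matches and suppress imperfect ones", {
  set.seed(41)
  isoA <- generateFixture("orf", nCodons = 60, seed = 1)$protein
  isoB <- generateFixture("orf", nCodons = 70, seed = 2)$protein
  cands <- list(orfFor(isoA, "srcA"), orfFor(isoB, "srcB"),
                orfFor(substituteAa(isoA, 1), "srcA-mut"))
  reports <- buildIsoformReports(c(A = isoA, B = isoB), cands)
  expect_length(reports, 2L)
  stA <- vapply(isoformMatches(reports[[1]]), matchStatus, character(1))
  expect_identical(stA, "perfect")  # imperfect srcA-mut suppressed
  stB <- vapply(isoformMatches(reports[[2]]), matchStatus, character(1))
  expect_identical(stB, "perfect")
})

test_that("imperfect matches are the fallback and no-match flags are set", {
  set.seed(43)
  iso <- generateFixture("orf", nCodons = 60, seed = 5)$protein
  twoSub <- orfFor(substituteAa(iso, 2), "src2")
  rep1 <- buildIsoformReports(c(iso = iso), list(twoSub))[[1]]
  expect_identical(
    vapply(isoformMatches(rep1), matchStatus, character(1)), "imperfect")
  expect_false(rep1@noMatch)
  unrelated <- orfFor(substituteAa(iso, 10), "src3")
  rep2 <- buildIsoformReports(c(iso = iso), list(unrelated))[[1]]
  expect_length(isoformMatches(rep2), 0L)
  expect_true(rep2@noMatch)
})

writeGenBankFixture <- function(path, seq, cdsLocation) {
  lines <- c(
    sprintf("LOCUS       synthrec        %12d bp    DNA     linear   SYN 01-JAN-2026",
            nchar(seq)),
    "FEATURES             Location/Qualifiers",
    sprintf("     %-16s%s", "source", sprintf("1..%d", nchar(seq))),
    sprintf("     %-16s%s", "CDS", cdsLocation),
    "ORIGIN")
  for (s in seq.int(1, nchar(seq), by = 60)) {
    chunk <- substr(seq, s, min(s + 59, nchar(seq)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s,
                              paste(tolower(groups), collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
}

test_that("CDS features are extracted from GenBank records on both strands", {
  set.seed(51)
  fx <- generateFixture("orf", nCodons = 103, seed = 9)
  cdsWithStop <- fx$dna  # 309 coding bases + stop
  seq <- paste0(randomStrictDna(9), cdsWithStop, randomStrictDna(30))
  path <- withr::local_tempfile(fileext = ".gb")
  writeGenBankFixture(path, seq, sprintf("10..%d", 9 + nchar(cdsWithStop)))
  cand <- parseCdsCandidates(path)
  expect_length(cand, 1L)
  expect_identical(nchar(cds(cand[[1]])), 309L)
  expect_identical(translation(cand[[1]]), fx$protein)

  # complement-strand CDS translates to the same protein
  seqRc <- revComp(seq)
  path2 <- withr::local_tempfile(fileext = ".gb")
  loc <- sprintf("complement(%d..%d)",
                 nchar(seq) - (9 + nchar(cdsWithStop)) + 1, nchar(seq) - 9)
  writeGenBankFixture(path2, seqRc, loc)
  cand2 <- parseCdsCandidates(path2)
  expect_identical(translation(cand2[[1]]), fx$protein)
  expect_identical(orfStrand(cand2[[1]]), "-")
})

test_that("plain FASTA input falls back to the ORF scanner", {
  fx <- generateFixture("genomic", length = 2000, orfCodons = 60L, seed = 13)
  path <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(c(genomicrec = fx$dna), path, "dna")
  viaParse <- orfTableOf(parseCdsCandidates(path, minCodons = 50L))
  direct <- orfTableOf(findOrfs(fx$dna, minCodons = 50L))
  expect_equal(viaParse, direct)
})
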