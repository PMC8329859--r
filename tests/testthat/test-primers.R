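toyCds <- function(nCodons = 100, seed = 7) generateFixture("orf", nCodons = nCodons, seed = seed)$dna

test_that("Wallace and GC-fraction rules give their closed-form values", {
  expect_equal(meltingTemperature("AAAAAAAAAAAAAAA", "wallace"), 30)
  expect_equal(meltingTemperature("GCGCGCGCGC", "wallace"), 40)
  expect_equal(meltingTemperature("ACGTACGTACGTACGTACGT", "wallace"), 60)
  n <- 20; gc <- 10
  expect_equal(meltingTemperature("ACGTACGTACGTACGTACGT", "gc-fraction"),
               81.5 + 16.6 * log10(0.05) + 0.41 * (100 * gc / n) - 600 / n)
  expect_error(meltingTemperature("ACGN"), "invalid character 'N'")
})

test_that("nearest-neighbor Tm matches an independent implementation", {
  set.seed(17)
  seqs <- replicate(8, randomStrictDna(20))
  oracle <- biopythonTmNN(seqs)
  mine <- vapply(seqs, meltingTemperature, numeric(1))
  expect_true(all(abs(mine - oracle) < 0.1))
})

test_that("forward primers start at the boundary codon and satisfy Tm growth", {
  cds <- toyCds()
  p <- designForwardPrimer(cds, 1)
  expect_identical(substr(cds, 1, nchar(annealingRegion(p))),
                   annealingRegion(p))
  expect_true(tmAnnealing(p) >= 65 || "tm-unreachable" %in% primerNotices(p))
  # minimality against the exhaustive-extension oracle
  oracleLen <- smallestTmLength(function(L) substr(cds, 1, L), 15, 60, 65)
  if (!is.na(oracleLen))
    expect_identical(nchar(annealingRegion(p)), oracleLen)
  p20 <- designForwardPrimer(cds, 1, fixedLength = 20)
  expect_identical(annealingRegion(p20), substr(cds, 1, 20))
  expect_error(designForwardPrimer(toyCds(100), 101), "outside protein")
  p48 <- designForwardPrimer(cds, 48)
  expect_identical(substr(cds, 142, 141 + nchar(annealingRegion(p48))),
                   annealingRegion(p48))
})

test_that("reverse primers mirror the forward contract", {
  cds <- toyCds()
  p <- designReversePrimer(cds, 58)
  core <- revComp(annealingRegion(p))
  expect_identical(substr(cds, 174 - nchar(core) + 1, 174), core)
  oracleLen <- smallestTmLength(function(L)
    revComp(substr(cds, 174 - L + 1, 174)), 15, 60, 65)
  if (!is.na(oracleLen))
    expect_identical(nchar(annealingRegion(p)), oracleLen)
  # boundary case: stop at the protein's final residue
  pEnd <- designReversePrimer(cds, 100)
  coreEnd <- revComp(annealingRegion(pEnd))
  expect_identical(substr(cds, 300 - nchar(coreEnd) + 1, 300), coreEnd)
  expect_error(designReversePrimer(cds, 101), "outside protein")
  # too close to the CDS start to host a minimum-length annealing region
  expect_error(designReversePrimer(cds, 3), "run past")
})

test_that("overhang attachment flags in-frame start/stop codons, keeps Tm", {
  cds <- toyCds()
  fw <- designForwardPrimer(cds, 2)
  withAtg <- attachOverhang(fw, Overhang("caccATG", frameOffset = 0L))
  expect_true("start-codon-in-overhang" %in% primerNotices(withAtg))
  expect_identical(tmAnnealing(withAtg), tmAnnealing(fw))
  # same bases, shifted out of frame: no notice
  offFrame <- attachOverhang(fw, Overhang("caccATGc", frameOffset = 0L))
  expect_false("start-codon-in-overhang" %in% primerNotices(offFrame))
  rv <- designReversePrimer(cds, 50)
  # sense strand downstream reads revComp("tta") = "TAA": in-frame stop
  withStop <- attachOverhang(rv, Overhang("tta", frameOffset = 0L))
  expect_true("stop-codon-in-overhang" %in% primerNotices(withStop))
  degenerate <- attachOverhang(fw, Overhang("BTAG"))
  expect_identical(primerOverhang(degenerate)@sequence, "BTAG")
  expect_identical(primerOverhang(degenerate)@origin, "custom")
  expect_identical(attachOverhang(fw, Overhang("")), fw)
})

test_that("restriction overhangs come from the shipped enzyme table", {
  oh <- restrictionOverhang("BamHI", spacer = "aaa")
  expect_identical(oh@sequence, "AAAGGATCC")
  expect_identical(oh@origin, "restriction")
  expect_identical(restrictionOverhang("BamHI")@sequence, "GGATCC")
  expect_error(restrictionOverhang("XyzI"), "available: .*BamHI")
})

test_that("the primer table follows the naming and case conventions", {
  cds <- toyCds()
  primers <- c(lapply(c(1L, 48L), function(s) designForwardPrimer(cds, s)),
               lapply(c(48L, 58L), function(t) designReversePrimer(cds, t)))
  oh <- Overhang("cacc")
  primers[[1]] <- attachOverhang(primers[[1]], oh)
  tab <- primerTable(primers, "RBX5")
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$name,
                   c("RBX5_Fw_1", "RBX5_Fw_48", "RBX5_Rv_48", "RBX5_Rv_58"))
  expect_match(tab$sequence[1], "^cacc[ACGT]+$")
  expect_identical(tab$sequence[2], annealingRegion(primers[[2]]))
  dup <- c(primers, primers[1])
  expect_error(primerTable(dup, "RBX5"), "duplicate primer names")
})

test_that("in-silico PCR excises the exact boundary-to-boundary segment", {
  fx <- generateFixture("orf", nCodons = 90, seed = 23)
  fw <- attachOverhang(designForwardPrimer(fx$dna, 10), Overhang("cacc"))
  rv <- attachOverhang(designReversePrimer(fx$dna, 40), Overhang("tggt"))
  res <- pcrAmplify(fx$dna, fw, rv)
  expect_identical(translateCds(res$core)$protein, substr(fx$protein, 10, 40))
  expect_identical(res$amplicon,
                   paste0("CACC", res$core, revComp("TGGT")))
})
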