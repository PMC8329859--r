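test_that("homolog filters enforce the coverage and significance rules", {
  hits <- generateFixture("hits", queryLength = 200,
                          coverages = c(74, 75, 90),
                          evalues = c(1e-10, 1e-10, 1e-10), seed = 1)
  kept <- filterHomologHits(hits, queryLength = 200)
  cov <- (kept$qend - kept$qstart + 1) / 200
  expect_identical(nrow(kept), 2L)
  expect_true(all(cov >= 0.75))
  weak <- generateFixture("hits", queryLength = 200, coverages = c(90, 90),
                          evalues = c(1e-10, 0.01), seed = 2)
  expect_identical(nrow(filterHomologHits(weak, 200)), 1L)
  empty <- weak[0, ]
  expect_identical(nrow(filterHomologHits(empty, 200)), 0L)
})

test_that("raising a hit's coverage never removes it (monotonicity)", {
  set.seed(91)
  hits <- generateFixture("hits", queryLength = 200,
                          coverages = seq(50, 95, 5), seed = 3)
  base <- filterHomologHits(hits, 200)
  bumped <- hits
  bumped$qend <- pmin(200L, bumped$qend + 20L)
  after <- filterHomologHits(bumped, 200)
  expect_true(all(base$sseqid %in% after$sseqid))
})

test_that("mapping candidates are capped at five hits above 95% identity", {
  hits <- generateFixture("hits", queryLength = 200, coverages = rep(90, 10),
                          identities = seq(96, 99, length.out = 10), seed = 4)
  sel <- selectMappingCandidates(hits)
  expect_identical(nrow(sel), 5L)
  expect_true(all(diff(sel$pident) <= 0))  # identity descending
  border <- generateFixture("hits", queryLength = 200, coverages = c(90, 90),
                            identities = c(95, 95.1), seed = 5)
  sel2 <- selectMappingCandidates(border)
  expect_identical(sel2$pident, 95.1)  # exactly 95.0 excluded
  none <- generateFixture("hits", queryLength = 200, coverages = c(90),
                          identities = 80, seed = 6)
  expect_identical(nrow(selectMappingCandidates(none)), 0L)
})

test_that("structure hits partition into the three identity tiers", {
  hits <- generateFixture("hits", queryLength = 100,
                          coverages = c(50, 60, 70, 80),
                          identities = c(96, 70, 40, 29), seed = 7)
  res <- classifyPdbTiers(hits, 100)
  expect_identical(as.character(res$tiers),
                   c("PDB_95", "PDB50_to_95", "PDB30_to_50", "none"))
  # every identity lands in exactly one tier
  sweep <- generateFixture("hits", queryLength = 100,
                           coverages = rep(50, 201),
                           identities = seq(0, 100, 0.5), seed = 8)
  part <- classifyPdbTiers(sweep, 100)$tiers
  expect_false(anyNA(part))
  counts <- table(part)
  expect_identical(unname(counts["PDB_95"]), sum(sweep$pident >= 95))
  expect_identical(unname(counts["PDB50_to_95"]),
                   sum(sweep$pident >= 50 & sweep$pident < 95))
  expect_identical(unname(counts["PDB30_to_50"]),
                   sum(sweep$pident >= 30 & sweep$pident < 50))
})

test_that("PDB_95 tracks mark deposited-construct boundaries with metadata", {
  hits <- generateFixture("hits", queryLength = 100, coverages = 60,
                          identities = 97, seed = 9)
  res <- classifyPdbTiers(hits, 100)
  track <- res$tracks$PDB_95
  sym <- strsplit(trackSymbols(track), "")[[1]]
  expect_identical(sym[hits$qstart], ">")
  expect_identical(sym[hits$qend], "<")
  expect_true(all(sym[(hits$qstart + 1):(hits$qend - 1)] == "="))
  b <- track@metadata$boundaries
  expect_identical(sort(b$marker), c("<", ">"))
  expect_identical(unique(b$structure), hits$sseqid)
  lower <- res$tracks$PDB50_to_95
  expect_identical(gsub(" ", "", trackSymbols(lower)), "")
})

test_that("identifier renaming abbreviates the genus and tolerates gaps", {
  expect_identical(
    renameIdentifier("ENSMUSG00000006715", "Mus musculus", "gmnn",
                     "H3BLK4_MOUSE"),
    "M.musculus_gmnn_(H3BLK4_MOUSE)")
  expect_identical(
    renameIdentifier("ENSMUSG00000006715", "Mus musculus", NA,
                     "H3BLK4_MOUSE"),
    "M.musculus_(H3BLK4_MOUSE)")
  expect_identical(renameIdentifier("ENSMUSG00000006715"),
                   "ENSMUSG00000006715")
})

test_that("PTM tracks encode single and multiple modifications", {
  mods <- data.frame(residue = c(12L, 30L, 30L),
                     type = c("acetylation", "acetylation", "ubiquitination"))
  track <- ptmTrack(mods, queryLength = 40)
  sym <- strsplit(trackSymbols(track), "")[[1]]
  expect_identical(sym[12], "A")
  expect_identical(sym[30], "+")
  expect_identical(sum(sym != " "), 2L)
  disabled <- ptmTrack(mods, queryLength = 40, canonical = FALSE)
  expect_identical(trackSymbols(disabled), strrep(" ", 40))
  expect_true(disabled@metadata$disabled)
  bad <- data.frame(residue = 50L, type = "acetylation")
  expect_error(ptmTrack(bad, queryLength = 40), "outside the query")
})

test_that("merged reports align tracks under the query with full-length rows", {
  set.seed(101)
  query <- randomPeptide(130)
  tracks <- list(
    spanTrack("domain", data.frame(start = 10L, end = 60L), 130),
    ptmTrack(data.frame(residue = 5L, type = "acetylation"), 130))
  report <- mergeTracks(tracks, query)
  lines <- strsplit(report, "\n")[[1]]
  domLines <- grep("^domain", lines, value = TRUE)
  sym <- paste(substring(domLines, max(nchar("domain"), 5) + 2), collapse = "")
  expect_identical(nchar(sym), 130L)
  expect_identical(substr(sym, 10, 60), strrep("*", 51))
  expect_identical(substr(sym, 61, 130), strrep(" ", 70))
  expect_true(any(grepl("^Legend:", lines)))
  expect_error(mergeTracks(list(spanTrack("d", data.frame(start = 1L, end = 2L),
                                          10)), query),
               "10 symbols for a query of length 130")
})

test_that("the TSV symbol matrix round-trips losslessly", {
  set.seed(103)
  query <- randomPeptide(80)
  tracks <- list(
    spanTrack("domain", data.frame(start = 20L, end = 45L), 80),
    ptmTrack(data.frame(residue = c(3L, 9L),
                        type = c("acetylation", "disulfide")), 80))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrackMatrix(tracks, query, path)
  back <- readTrackMatrix(path)
  expect_identical(nrow(back), 80L)
  expect_identical(paste(back$query, collapse = ""), query)
  for (tr in tracks)
    expect_identical(paste(back[[tr@name]], collapse = ""), trackSymbols(tr))
})

test_that("hit tables round-trip through the outfmt-6 reader", {
  hits <- generateFixture("hits", queryLength = 150, seed = 13)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back <- readHitsTable(path)
  expect_identical(back$sseqid, hits$sseqid)
  expect_equal(back$pident, hits$pident)
  expect_error(readHitsTable(system.file("extdata",
                                         "restriction_enzymes.tsv",
                                         package = "ConstructDesigner")),
               "12 tab-separated columns")
})
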