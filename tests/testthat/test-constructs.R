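fixtureProteinCds <- function(nCodons = 100, seed = 7) {
  fx <- generateFixture("orf", nCodons = nCodons, seed = seed)
  list(protein = fx$protein, cds = fx$dna)
}

test_that("construct enumeration covers exactly the ordered boundary pairs", {
  fx <- fixtureProteinCds()
  cons <- enumerateConstructs(c(1, 48), c(48, 58), fx$protein, fx$cds)
  bounds <- t(vapply(cons, constructBoundaries, integer(2)))
  expect_equal(unname(bounds),
               matrix(c(1L, 48L, 1L, 58L, 48L, 48L, 48L, 58L),
                      ncol = 2, byrow = TRUE))
  # single-residue construct from a position that is both start and stop
  single <- cons[[3]]
  expect_identical(nchar(constructProtein(single)), 1L)
  # start > stop pairs are silently excluded
  expect_length(enumerateConstructs(10, 5, fx$protein, fx$cds), 0L)
  expect_error(enumerateConstructs(integer(), 5, fx$protein, fx$cds),
               "at least one start")
})

test_that("enumeration count equals |{(s,t): s <= t}| and dna translates back", {
  fx <- fixtureProteinCds()
  set.seed(61)
  for (i in 1:5) {
    starts <- sample(1:100, sample(1:4, 1))
    stops <- sample(1:100, sample(1:4, 1))
    cons <- enumerateConstructs(starts, stops, fx$protein, fx$cds)
    expected <- sum(outer(unique(starts), unique(stops), "<="))
    expect_length(cons, expected)
    for (con in cons)
      expect_identical(translateCds(constructDna(con))$protein,
                       constructProtein(con))
  }
})

test_that("molecular weight follows the average-mass model", {
  expect_equal(molecularWeight("GG"), 132.12, tolerance = 0.01 / 132)
  expect_error(molecularWeight(""), "invalid|empty")
})

test_that("isoelectric point converges and respects charge signs", {
  set.seed(71)
  for (i in 1:10) {
    pep <- randomPeptide(30)
    pi <- isoelectricPoint(pep)
    expect_lt(abs(chargeAtPh(pep, pi)), 1e-3)
  }
  expect_gt(isoelectricPoint(strrep("K", 10)), 7)
  expect_lt(isoelectricPoint(strrep("D", 10)), 7)
})

test_that("extinction coefficients count Trp, Tyr and cystine pairs", {
  expect_equal(unname(extinction280("GGG")), c(0, 0))
  expect_equal(unname(extinction280("WYYG")), c(8480, 8480))
  expect_equal(unname(extinction280("GCCG")), c(0, 125))
  expect_equal(unname(extinction280("GCCCG")), c(0, 125))  # floor(3/2) pairs
})

test_that("properties agree with the recorded ProtParam oracle fixtures", {
  tab <- utils::read.csv(test_path("protparam_oracle_synthetic.csv"),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    s <- tab$sequence[i]
    expect_lt(abs(molecularWeight(s) - tab$mw[i]) / tab$mw[i], 1e-4)
    expect_lt(abs(isoelectricPoint(s) - tab$pi[i]), 0.01)
    eps <- extinction280(s)
    expect_equal(unname(eps),
                     c(tab$eps280_reduced[i], tab$eps280_cystine[i]))
  }
})

test_that("tag fusion and protease cleavage follow the vector definition", {
  fx <- fixtureProteinCds(60, seed = 31)
  vec <- generateFixture("vector", backboneLength = 1000,
                         placeholderLength = 21,
                         tagProtein = "MHHHHHHENLYFQG",
                         cleavageOffset = 1L, seed = 5)
  cons <- enumerateConstructs(5, 40, fx$protein, fx$cds, vector = vec)[[1]]
  insert <- constructProtein(cons)
  expect_identical(cons@taggedProtein, paste0("MHHHHHHENLYFQG", insert))
  expect_identical(cons@cleavedProtein, paste0("G", insert))
  # mass additivity: removed fragment minus one water
  removed <- "MHHHHHHENLYFQ"
  expect_equal(mw(properties(cons, "tagged")) - mw(properties(cons, "cleaved")),
               molecularWeight(removed) - 18.01524, tolerance = 1e-6)
  noProt <- generateFixture("vector", backboneLength = 1000,
                            placeholderLength = 21, seed = 5)
  noProt@cleavageOffset <- NA_integer_
  con2 <- fuseAndCleave(cons, noProt)
  expect_length(con2@cleavedProtein, 0L)
  expect_null(properties(con2, "cleaved"))
})

test_that("the construct table round-trips through CSV and expands with a vector", {
  fx <- fixtureProteinCds()
  cons <- enumerateConstructs(c(1, 48), c(48, 58), fx$protein, fx$cds)
  tab <- constructTable(cons)
  expect_identical(nrow(tab), 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_identical(back$dna, tab$dna)
  expect_identical(back$protein, tab$protein)
  vec <- generateFixture("vector", backboneLength = 1000,
                         placeholderLength = 21, seed = 5)
  tab2 <- constructTable(enumerateConstructs(c(1, 48), c(48, 58), fx$protein,
                                             fx$cds, vector = vec))
  expect_true(all(c("tagged_mw", "cleaved_mw", "tagged_protein",
                    "cleaved_protein") %in% names(tab2)))
  expect_false(any(c("tagged_mw", "cleaved_protein") %in% names(tab)))
})

test_that("construct DNA export writes one row per construct", {
  fx <- fixtureProteinCds()
  cons <- enumerateConstructs(c(1, 48), c(48, 58), fx$protein, fx$cds)
  path <- withr::local_tempfile(fileext = ".csv")
  saveConstructDna(cons, path, prefix = "RBX5")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$construct[1], "RBX5_1-48")
  expect_identical(tab$dna, vapply(cons, constructDna, character(1)))
})
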