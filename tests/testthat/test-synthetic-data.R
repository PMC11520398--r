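test_that("genMolecules yields distinct valid molecules, deterministically", {
  m1 <- genMolecules(100L, seed = 7L)
  m2 <- genMolecules(100L, seed = 7L)
  expect_identical(m1, m2)
  expect_true(all(isValidSmiles(m1)))
  expect_equal(anyDuplicated(canonicalSmiles(m1)), 0L)
  nRings <- sum(vapply(m1, function(s) length(rings(parseSmiles(s))) > 0L,
                       TRUE))
  expect_gte(nRings, 10L)
})

test_that("descriptions are ordered fine-to-general and deterministic", {
  mol <- parseSmiles("c1ccccc1CCO")
  d1 <- genDescription(mol, 4L, seed = 2L)
  d2 <- genDescription(mol, 4L, seed = 2L)
  expect_identical(d1, d2)
  sent <- splitSentences(d1)
  expect_length(sent, 4L)
  expect_false(any(grepl("-", sent, fixed = TRUE)))
  # fine templates precede general ones
  kinds <- vapply(sent, function(s) {
    for (t in sentenceTemplates()) if (grepl(t$pattern, s)) return(t$kind)
    NA_character_
  }, "")
  expect_false(any(is.na(kinds)))
  expect_true(all(diff(match(kinds, c("fine", "general"))) >= 0))
})

test_that("aromatic molecules are described as aromatic", {
  d <- genDescription(parseSmiles("c1ccccc1CC"), 5L, seed = 9L)
  expect_match(d, "aromatic")
})

test_that("every generated sentence fact-checks against its molecule", {
  corp <- fixtureCorpus()
  recs <- corpusRecords(corp)
  for (i in seq_len(nrow(recs))) {
    checks <- factCheckDescription(recs$description[i], recs$smiles[i])
    expect_true(all(checks), info = recs$smiles[i])
  }
})

test_that("corpus bundles records, lexicon and properties consistently", {
  corp <- genCorpus(50L, seed = 13L)
  recs <- corpusRecords(corp)
  expect_equal(nrow(recs), 50L)
  expect_length(corpusLexicon(corp), 50L)
  expect_identical(unname(corpusLexicon(corp)[recs$name]), recs$smiles)
  props <- propertyTable(corp)
  expect_true(all(props$property %in% propertyInventory()))
  expect_lte(length(unique(props$property)), 15L)
  perMol <- table(props$moleculeId)
  expect_true(all(perMol >= 3L & perMol <= 15L))
  # generator guarantees: descriptions pass the dialogue-builder filters
  expect_false(any(grepl("-", recs$description, fixed = TRUE)))
  # names never leak into descriptions
  expect_false(any(mapply(grepl, recs$name, recs$description,
                          MoreArgs = list(ignore.case = TRUE))))
})

test_that("corpus generation is bit-identical for a fixed seed", {
  c1 <- genCorpus(15L, seed = 99L)
  c2 <- genCorpus(15L, seed = 99L)
  expect_identical(corpusRecords(c1), corpusRecords(c2))
  expect_identical(corpusLexicon(c1), corpusLexicon(c2))
  expect_identical(propertyTable(c1), propertyTable(c2))
})

test_that("corpus survives a write/read round trip", {
  dir <- withr::local_tempdir()
  corp <- genCorpus(10L, seed = 3L)
  writeCorpus(corp, dir)
  expect_true(file.exists(file.path(dir, "corpus.jsonl")))
  back <- readCorpus(dir)
  expect_identical(corpusRecords(back)$smiles, corpusRecords(corp)$smiles)
  expect_identical(corpusRecords(back)$description,
                   corpusRecords(corp)$description)
  expect_identical(corpusLexicon(back), corpusLexicon(corp))
  expect_equal(propertyTable(back), propertyTable(corp))
})
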