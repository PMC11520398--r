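test_that("sentence splitting and reversal behave as specified", {
  expect_equal(splitAndReverse("A one. B two. C three."),
               c("C three.", "B two.", "A one."))
  expect_length(splitAndReverse("Only one sentence."), 1L)
  s <- splitSentences("Use e.g. ethanol. Then stir.")
  expect_equal(s, c("Use e.g. ethanol.", "Then stir."))
  # round trip up to whitespace
  txt <- "First fact. Second fact. Third fact."
  expect_equal(paste(rev(splitAndReverse(txt)), collapse = " "), txt)
})

test_that("synonym replacement is whole-word, longest-first", {
  expect_equal(replaceSynonyms("Ethanol is volatile.", "ethanol"),
               "the molecule is volatile.")
  expect_equal(replaceSynonyms("nothing to do", "ethanol"), "nothing to do")
  got <- replaceSynonyms("Add acetic acid to the acid bath.",
                         c("acid", "acetic acid"))
  expect_equal(got, "Add the molecule to the the molecule bath.")
  # no replacement inside words
  expect_equal(replaceSynonyms("acidic solution", "acid"), "acidic solution")
})

test_that("the similarity gate excludes the final molecule and empty sets", {
  expect_null(selectIntermediate(c("CCO"), "CCO", seed = 1L))
  expect_null(selectIntermediate(c("invalid(("), "CCO", seed = 1L))
  # CCCO vs CCO has path-Tanimoto strictly inside (0.5, 1)
  sim <- suppressWarnings(tanimotoToRef("CCCO", "CCO", "path"))
  expect_gt(sim, 0.5); expect_lt(sim, 1)
  expect_equal(selectIntermediate(c("CCCO"), "CCO", seed = 1L), "CCCO")
  # a gate that nothing satisfies
  expect_null(selectIntermediate(c("CCCO"), "CCO", lo = 0.99, hi = 1,
                                 seed = 1L))
})

test_that("turn inputs append the previous molecule sentence verbatim", {
  expect_equal(makeTurnInput("Some text.", "CCO"),
               "Some text. It looks like CCO.")
  expect_equal(makeTurnInput("Some text.", NULL), "Some text.")
})

test_that("the default candidate generator meets its contract", {
  c1 <- defaultCandidateGenerator("", "CCCO", seed = 8L)
  c2 <- defaultCandidateGenerator("", "CCCO", seed = 8L)
  expect_identical(c1, c2)
  expect_length(c1, 5L)
  expect_true(all(isValidSmiles(c1)))
  expect_false(canonicalSmiles("CCCO") %in% canonicalSmiles(c1))
  sims <- suppressWarnings(tanimotoToRef(c1, "CCCO", "path"))
  expect_true(any(sims > 0.5 & sims < 1))
  # similarity ordering is descending over the distinct candidates
  expect_true(all(diff(sims[!duplicated(c1)]) <= 1e-12))
})

test_that("buildDialogue applies the filters in order with reasons", {
  hyph <- list(moleculeId = "X1", smiles = "CCO",
               description = "It is 2-propanol like. It is volatile.")
  r <- buildDialogue(hyph, seed = 1L)
  expect_s3_class(r, "dialogueRejection")
  expect_equal(r$reason, "hyphen")

  single <- list(moleculeId = "X2", smiles = "CCO",
                 description = "Only one sentence here.")
  r <- buildDialogue(single, seed = 1L)
  expect_equal(r$reason, "single_turn")

  # synonym masking happens before the filters
  named <- list(moleculeId = "X3", smiles = "CCO", name = "ethanox",
                description = "Ethanox has a hydroxyl group. Ethanox is volatile.")
  d <- buildDialogue(named, seed = 2L)
  if (is(d, "Dialogue")) {
    expect_false(any(grepl("ethanox", d@turns$text, ignore.case = TRUE)))
  }
})

test_that("accepted dialogues satisfy the construction invariants", {
  built <- fixtureDialogues()
  expect_gt(length(built$dialogues), 10L)
  for (d in built$dialogues) {
    n <- nrow(d@turns)
    expect_gte(n, 2L)
    expect_equal(n, length(d@sentences))
    expect_false(any(grepl("-", d@sentences, fixed = TRUE)))
    expect_equal(d@turns$expectedSmiles[n], d@finalSmiles)
    expect_equal(d@turns$k, seq_len(n))
    # cumulative text is the running concatenation of the sentences
    expect_equal(d@turns$text[n],
                 paste(d@sentences, collapse = " "))
    sims <- suppressWarnings(
      tanimotoToRef(d@turns$expectedSmiles[-n], d@finalSmiles, "path"))
    expect_true(all(sims > 0.5 & sims < 1))
  }
  # rejection reasons partition the rejected records
  recs <- corpusRecords(fixtureCorpus())
  expect_equal(length(built$dialogues) + nrow(built$rejections), nrow(recs))
  expect_true(all(built$rejections$reason %in%
                    c("single_turn", "hyphen", "no_candidate")))
})

test_that("dialogue building is reproducible and round-trips as JSONL", {
  corp <- genCorpus(8L, seed = 21L)
  b1 <- suppressWarnings(buildDialogues(corp, seed = 4L))
  b2 <- suppressWarnings(buildDialogues(corp, seed = 4L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeDialogues(b1, d1); writeDialogues(b2, d2)
  expect_identical(readLines(file.path(d1, "dialogues.jsonl")),
                   readLines(file.path(d2, "dialogues.jsonl")))
  back <- readDialogues(d1)
  expect_equal(length(back), length(b1$dialogues))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]@turns, b1$dialogues[[i]]@turns)
    expect_equal(back[[i]]@finalSmiles, b1$dialogues[[i]]@finalSmiles)
  }
})

test_that("dialogue splits are deterministic and roughly proportional", {
  built <- fixtureDialogues()
  s1 <- splitDialogues(built$dialogues)
  s2 <- splitDialogues(built$dialogues)
  expect_identical(s1, s2)
  expect_true(all(s1 %in% c("train", "validation", "test")))
  expect_gt(mean(s1 == "train"), 0.5)
})
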