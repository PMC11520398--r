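test_that("entity annotation finds lexicon names in textual order", {
  lex <- c(velanox = "CCO", dorunex = "CCN")
  ann <- annotateEntities("First dorunex then velanox.", lex)
  expect_equal(ann$name, c("dorunex", "velanox"))
  expect_equal(ann$smiles, c("CCN", "CCO"))
  expect_equal(nrow(annotateEntities("nothing here", lex)), 0L)
})

test_that("leakage removal uses canonical, not string, equality", {
  lex <- c(ethanox = "OCC", aminox = "CCN")
  txt <- "Mix ethanox with aminox."
  ann <- annotateEntities(txt, lex)
  # "OCC" leaks the answer "CCO" even though the strings differ
  p <- buildPrompt(txt, ann, answers = "CCO")
  expect_false(grepl("OCC", p$prompt, fixed = TRUE))
  expect_true(grepl("CCN", p$prompt, fixed = TRUE))
  # no answers: everything is kept
  p2 <- buildPrompt(txt, ann, answers = character(0))
  expect_equal(nrow(p2$annotations), 2L)
  expect_match(p2$prompt, "Known molecules: ethanox: OCC; aminox: CCN\\.$")
  # all hints leak: the prompt is the bare text
  p3 <- buildPrompt(txt, ann, answers = c("CCO", "NCC"))
  expect_equal(p3$prompt, txt)
})

test_that("no dialogue prompt contains an answer molecule", {
  built <- fixtureDialogues()
  corp <- fixtureCorpus()
  lex <- corpusLexicon(corp)
  recs <- corpusRecords(corp)
  # dialogue texts are name-free by construction, so exercise the filter on
  # turn texts extended with sentences that name the dialogue's own
  # molecule (a guaranteed leak) plus an unrelated one
  nWithHints <- 0L
  leaks <- 0L
  for (d in built$dialogues) {
    own <- recs$name[recs$moleculeId == d@dialogueId]
    other <- setdiff(names(lex), own)[1]
    answers <- canonicalSmiles(unique(c(d@turns$expectedSmiles,
                                        d@finalSmiles)))
    for (k in seq_len(nrow(d@turns))) {
      txt <- paste0(d@turns$text[k], " The sample contains ", own, " and ",
                    other, ".")
      p <- buildPrompt(txt, annotateEntities(txt, lex), answers)
      if (nrow(p$annotations)) nWithHints <- nWithHints + 1L
      hinted <- p$annotations$smiles
      hinted <- hinted[isValidSmiles(hinted)]
      leaks <- leaks + sum(canonicalSmiles(hinted) %in% answers)
      expect_false(any(grepl(paste0(": ", lex[[own]], "[;.]"), p$prompt)))
    }
  }
  expect_gt(nWithHints, 0L)  # the check is not vacuous
  expect_equal(leaks, 0L)
})
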