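test_that("span corruption masks the contracted fraction and is lossless", {
  toks <- sprintf("w%03d", 1:100)
  mk <- maskSpans(toks, maskRate = 0.15, seed = 4L)
  nMasked <- sum(!grepl("^<X", mk$targets))
  expect_gte(nMasked, 14L)
  expect_lte(nMasked, 16L)
  expect_identical(reconstructSpans(mk$corrupted, mk$targets), toks)
  expect_identical(maskSpans(toks, 0.15, seed = 4L), mk)
  # lossless across lengths, rates and seeds
  set.seed(8)
  for (trial in 1:50) {
    n <- sample(2:60, 1)
    tk <- sprintf("t%d", seq_len(n))
    rate <- runif(1, 0.05, 0.6)
    m <- maskSpans(tk, rate, seed = trial)
    expect_identical(reconstructSpans(m$corrupted, m$targets), tk)
    nm <- sum(!grepl("^<X", m$targets))
    expect_lte(abs(nm - round(rate * n)), 1L)
  }
  expect_error(maskSpans("one", 0.15), "at least 2")
})

test_that("SMILES masking never splits an atom token", {
  toks <- smilesTokens("Clc1ccccc1Br")
  expect_true("Cl" %in% toks && "Br" %in% toks)
  mk <- maskSpans(toks, 0.3, seed = 2L)
  expect_identical(paste(reconstructSpans(mk$corrupted, mk$targets),
                         collapse = ""), "Clc1ccccc1Br")
})

test_that("mapping records list matched SMILES in textual order", {
  lex <- c(ethanox = "CCO", propanox = "CCC", methanox = "C")
  recs <- makeMappingRecords("Mix propanox with ethanox carefully.", lex)
  t2m <- recs[recs$task == "map_text2mol", ]
  expect_equal(nrow(t2m), 1L)
  expect_equal(t2m$target, "CCC CCO")
  expect_true(startsWith(t2m$source, taskPrefixes()[["map_text2mol"]]))
  m2n <- recs[recs$task == "map_mol2name", ]
  expect_equal(m2n$target, c("propanox", "ethanox"))
  expect_equal(nrow(makeMappingRecords("no chemicals here", lex)), 0L)
})

test_that("overlapping names resolve to the longest match", {
  lex <- c("methyl" = "C", "methylamine" = "CN")
  recs <- makeMappingRecords("Add methylamine now.", lex)
  t2m <- recs[recs$task == "map_text2mol", ]
  expect_equal(t2m$target, "CN")
  # agreement with the exhaustive span oracle on random name soups
  set.seed(5)
  lex2 <- c("acid" = "CC(=O)O", "acetic acid" = "CC(=O)O",
            "amine" = "CN", "chloro amine" = "ClCN")
  for (i in 1:20) {
    txt <- paste(sample(c(names(lex2), "water", "salt"), 5, replace = TRUE),
                 collapse = " and ")
    got <- annotateEntities(txt, lex2)
    want <- oracleEntitySpans(txt, lex2)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$name, vapply(want, function(h) h$name, ""))
      expect_equal(got$start, vapply(want, function(h) h$start, 1L))
    }
  }
})

test_that("property records carry the recorded value in the target", {
  corp <- fixtureCorpus()
  props <- propertyTable(corp)
  id <- props$moleculeId[1]
  recs <- makePropertyRecords(id, corp)
  expect_equal(nrow(recs), sum(props$moleculeId == id))
  sub <- props[props$moleculeId == id, ]
  for (i in seq_len(nrow(sub))) {
    row <- recs[grepl(sub$property[i], recs$source, fixed = TRUE), ]
    expect_equal(nrow(row), 1L)
    expect_true(grepl(sub$value[i], row$target, fixed = TRUE))
  }
  expect_error(makePropertyRecords("nope", corp), "unknown molecule")
})

test_that("spatial records assert true facts about atoms", {
  recs <- makeSpatialRecords("c1ccccc1", nQueries = 6L, seed = 3L)
  arom <- recs[grepl("aromatic\\?", recs$source), ]
  if (nrow(arom)) {
    expect_true(all(grepl("is aromatic and lies in a ring of 6 atoms",
                          arom$target)))
  }
  etherO <- makeSpatialRecords("CCO", nQueries = 12L, seed = 1L)
  nbrO <- etherO[grepl("connected to atom 2\\?", etherO$source), ]
  if (nrow(nbrO)) {
    expect_true(all(grepl("connected to 1 atoms: C", nbrO$target)))
  }
  corp <- fixtureCorpus()
  expect_true(all(factCheckKnowledge(recs, corp)))
})

test_that("the mixed knowledge set honours mixture weights within one", {
  corp <- fixtureCorpus()
  w <- c(mlm_text = 2, mlm_smiles = 1, map_text2mol = 1, map_mol2name = 1,
         property = 2, spatial = 2)
  ks <- buildKnowledgeSet(corp, nTotal = 90L, weights = w, seed = 6L)
  expect_equal(nrow(ks), 90L)
  counts <- table(factor(ks$task, levels = names(w)))
  want <- 90 * w / sum(w)
  expect_true(all(abs(counts - want) <= 1))
  # every source starts with its task prefix, targets non-empty
  pref <- taskPrefixes()
  expect_true(all(mapply(startsWith, ks$source, pref[ks$task])))
  expect_true(all(nzchar(ks$target)))
  # all checkable targets are true
  expect_true(all(factCheckKnowledge(ks, corp)))
})

test_that("knowledge records survive a JSONL round trip", {
  dir <- withr::local_tempdir()
  corp <- fixtureCorpus()
  ks <- buildKnowledgeSet(corp, nTotal = 30L, seed = 2L)
  path <- file.path(dir, "k.jsonl")
  writeKnowledgeRecords(ks, path)
  back <- readKnowledgeRecords(path)
  rownames(ks) <- NULL
  expect_equal(back, ks)
})
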