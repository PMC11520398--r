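test_that("levenshtein matches the DP oracle and the metric axioms", {
  expect_equal(levenshtein("CCO", "CCO"), 0L)
  expect_equal(levenshtein("CCO", "CC=O"), 1L)
  set.seed(11)
  alph <- c("C", "c", "N", "O", "(", ")", "=", "1")
  rnd <- function() paste(sample(alph, sample(0:12, 1), replace = TRUE),
                          collapse = "")
  for (i in seq_len(1000L)) {
    a <- rnd(); b <- rnd()
    d <- levenshtein(a, b)
    expect_equal(d, oracleLevenshtein(a, b))
    expect_equal(d, levenshtein(b, a))
    expect_equal(levenshtein(a, a), 0L)
  }
  # triangle inequality on a smaller sample
  for (i in seq_len(200L)) {
    a <- rnd(); b <- rnd(); cc <- rnd()
    expect_lte(levenshtein(a, cc), levenshtein(a, b) + levenshtein(b, cc))
  }
})

test_that("SMILES BLEU matches hand-computed n-gram precisions", {
  expect_equal(smilesBleu("CCO", "CCO"), 1.0)
  expect_equal(smilesBleu("NNN", "CCO"), 0.0)
  # pred "CCO" vs gold "CCOC": p1 = 3/3, p2 = 2/2, p3 = 1/1 (effective
  # order 3 = min(4, |pred|)), brevity penalty exp(1 - 4/3)
  expect_equal(smilesBleu("CCO", "CCOC"), exp(1 - 4 / 3), tolerance = 1e-12)
  # pred "CCN" vs gold "CCO": p3 = 0 with no smoothing -> 0
  expect_equal(smilesBleu("CCN", "CCO"), 0.0)
  expect_equal(smilesBleu("", "CCO"), 0.0)
})

test_that("ROUGE-1 equals the hand-counted unigram F1", {
  # pred 5 words, gold 6 words, all 5 pred words in gold:
  # P = 1, R = 5/6, F = 2PR/(P+R) = 10/11
  tm <- textMetrics("the molecule is an acid",
                    "the molecule is an aromatic acid")
  expect_equal(tm[["rouge1"]], 10 / 11, tolerance = 1e-12)
})

test_that("identical and empty predictions hit the metric extremes", {
  tm <- textMetrics("The molecule is volatile.", "The molecule is volatile.")
  expect_true(all(abs(tm - 1) < 1e-6))
  tm0 <- textMetrics("", "The molecule is volatile.")
  expect_true(all(tm0 == 0))
})

test_that("exact match works through canonicalization", {
  expect_equal(exactMatch(c("OCC", "C", "CC"), "CCO"),
               c(em = 1L, hit3 = 1L))
  expect_equal(exactMatch(c("C", "CC", "CCC"), "CCO"),
               c(em = 0L, hit3 = 0L))
  expect_equal(exactMatch(c("C", "CCO", "CC"), "CCO"),
               c(em = 0L, hit3 = 1L))
  # unparseable predictions never match
  expect_equal(exactMatch(c("C((", "CCO"), "CCO"), c(em = 0L, hit3 = 1L))
})

test_that("fingerprint similarity scoring penalizes invalid predictions", {
  expect_equal(fts("CCO", "CCO", "morgan"), 1.0)
  expect_equal(fts("C((", "CCO", "morgan"), 0.0)
  s1 <- fts("CCCO", "CCO", "path")
  s2 <- fts("CCO", "CCCO", "path")
  expect_equal(s1, s2)
  expect_gt(s1, 0); expect_lt(s1, 1)
})

test_that("evaluatePredictions aggregates per-item means", {
  golds <- c("CCO", "c1ccccc1", "CC(=O)O")
  perfect <- lapply(seq_along(golds), function(i) {
    list(itemId = paste0("it", i), top3 = rep(golds[i], 3), gold = golds[i])
  })
  rep <- evaluatePredictions(perfect, "generation")
  agg <- aggregateMetrics(rep)
  expect_equal(agg[["em"]], 1.0)
  expect_equal(agg[["hit3"]], 1.0)
  expect_equal(agg[["leven"]], 0.0)
  expect_equal(agg[["rdk"]], 1.0)
  expect_equal(agg[["mac"]], 1.0)
  expect_equal(agg[["morgan"]], 1.0)
  # single-item report equals the item row
  one <- evaluatePredictions(perfect[1], "generation")
  expect_equal(unname(aggregateMetrics(one)),
               unname(unlist(perItemMetrics(one)[, -1])))
})

test_that("EM never exceeds hit@3 on randomized predictions", {
  set.seed(9)
  pool <- genMolecules(15L, seed = 2L)
  preds <- lapply(1:40, function(i) {
    list(itemId = paste0("r", i), top3 = sample(pool, 3),
         gold = sample(pool, 1))
  })
  rep <- evaluatePredictions(preds, "generation")
  per <- perItemMetrics(rep)
  expect_true(all(per$em <= per$hit3))
  agg <- aggregateMetrics(rep)
  expect_lte(agg[["em"]], agg[["hit3"]])
  expect_true(all(per$bleu >= 0 & per$bleu <= 1))
  expect_true(all(per$rdk >= 0 & per$rdk <= 1))
})

test_that("understanding evaluation mirrors the text metric columns", {
  preds <- list(
    list(itemId = "a", text = "The molecule is an organic compound.",
         gold = "The molecule is an organic compound."),
    list(itemId = "b", text = "Completely unrelated words here.",
         gold = "The molecule is an organic compound.")
  )
  rep <- evaluatePredictions(preds, "understanding")
  agg <- aggregateMetrics(rep)
  expect_named(agg, c("bleu2", "bleu4", "rouge1", "rouge2", "rougeL",
                      "meteor"))
  expect_true(all(agg >= 0 & agg <= 1))
  dir <- withr::local_tempdir()
  writeEvalReport(rep, file.path(dir, "und"))
  js <- jsonlite::fromJSON(file.path(dir, "und.json"))
  expect_equal(js[["BL-2"]], unname(agg[["bleu2"]]))
})
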