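test_that("analytic gradients match finite differences", {
  V <- 12L; H <- 5L; L <- 2L
  route <- MolConverse:::.withSeed(3, MolConverse:::.initRoute(V, H, L))
  src <- matrix(c(1L, 3L, 4L, 5L, 1L, 1L, 6L, 7L), 2, 4, byrow = TRUE)
  tgtIn <- matrix(c(2L, 8L, 9L, 2L, 10L, 1L), 2, 3, byrow = TRUE)
  tgtOut <- matrix(c(8L, 9L, 3L, 10L, 3L, 1L), 2, 3, byrow = TRUE)
  mask <- matrix(c(1, 1, 1, 1, 1, 0), 2, 3, byrow = TRUE)
  res <- MolConverse:::.routeBatch(route, src, tgtIn, tgtOut, mask, 1L)
  fp <- MolConverse:::.flattenParams(route)
  fg <- MolConverse:::.flattenParams(res$grads)
  eps <- 1e-6
  set.seed(7)
  for (k in names(fp)) {
    for (i in sample(length(fp[[k]]), min(3L, length(fp[[k]])))) {
      fpp <- fp; fpp[[k]][i] <- fp[[k]][i] + eps
      lp <- MolConverse:::.routeBatch(
        MolConverse:::.applyFlat(route, fpp), src, tgtIn, tgtOut, mask, 1L,
        lossOnly = TRUE)$loss
      fpm <- fp; fpm[[k]][i] <- fp[[k]][i] - eps
      lm <- MolConverse:::.routeBatch(
        MolConverse:::.applyFlat(route, fpm), src, tgtIn, tgtOut, mask, 1L,
        lossOnly = TRUE)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- fg[[k]][i]
      expect_lt(abs(num - ana), 1e-4 * max(1, abs(num) + abs(ana)))
    }
  }
})

test_that("model construction is deterministic and routes are independent", {
  vocab <- c(MolConverse:::.SPECIAL_TOKENS, letters[1:10])
  cfg <- converseConfig(hidden = 8L, layers = 2L, seed = 5L)
  m1 <- converseModel(vocab, cfg)
  m2 <- converseModel(vocab, cfg)
  expect_identical(m1@molRoute, m2@molRoute)
  expect_identical(m1@textRoute, m2@textRoute)
  # twin parameter sets differ (independent initialization)
  expect_false(identical(m1@molRoute$Wout, m1@textRoute$Wout))
  expect_lt(nParameters(converseModel(vocab,
                                      converseConfig(hidden = 64L,
                                                     layers = 2L))), 2e6)
  mshare <- converseModel(vocab, converseConfig(hidden = 8L, layers = 1L,
                                                shareEmbeddings = TRUE))
  expect_identical(mshare@molRoute$Esrc, mshare@textRoute$Esrc)
})

test_that("pretraining reduces loss and honours the task mixture", {
  corp <- fixtureCorpus()
  ks <- buildKnowledgeSet(corp, nTotal = 48L, seed = 7L)
  exs <- knowledgeExamples(ks)
  model <- converseModel(modelVocabulary(exs),
                         converseConfig(hidden = 24L, layers = 1L,
                                        seed = 2L))
  model <- pretrainModel(model, ks, steps = 40L, batchSize = 12L, seed = 3L)
  traj <- lossTrajectory(model)
  first <- mean(traj$loss[traj$step <= 3])
  last <- mean(traj$loss[traj$step > max(traj$step) - 3])
  expect_lt(last, first)
  # six tasks all trained
  expect_setequal(unique(traj$task), names(taskPrefixes()))
})

test_that("training trajectories are bit-reproducible for a fixed seed", {
  corp <- fixtureCorpus()
  ks <- buildKnowledgeSet(corp, nTotal = 24L, seed = 7L)
  exs <- knowledgeExamples(ks)
  cfg <- converseConfig(hidden = 16L, layers = 1L, seed = 2L)
  run <- function() {
    m <- converseModel(modelVocabulary(exs), cfg)
    m <- pretrainModel(m, ks, steps = 15L, batchSize = 8L, seed = 9L)
    lossTrajectory(m)
  }
  expect_identical(run(), run())
})

test_that("checkpoints restore a model exactly", {
  corp <- fixtureCorpus()
  ks <- buildKnowledgeSet(corp, nTotal = 24L, seed = 7L)
  m <- converseModel(modelVocabulary(knowledgeExamples(ks)),
                     converseConfig(hidden = 16L, layers = 1L, seed = 2L))
  m <- pretrainModel(m, ks, steps = 5L, batchSize = 8L, seed = 1L)
  dir <- withr::local_tempdir()
  saveModel(m, dir)
  back <- loadModel(dir)
  expect_identical(back@molRoute, m@molRoute)
  expect_identical(back@textRoute, m@textRoute)
  expect_equal(back@config$vocab, m@config$vocab)
  # decoding from the restored model matches the original
  expect_identical(generateMolecules(back, "The molecule contains no rings."),
                   generateMolecules(m, "The molecule contains no rings."))
})

test_that("generation returns ranked, deterministic, length-bounded output", {
  corp <- fixtureCorpus()
  built <- fixtureDialogues()
  dias <- built$dialogues[1:4]
  exs <- dialogueExamples(dias)
  model <- converseModel(modelVocabulary(exs),
                         converseConfig(hidden = 24L, layers = 1L,
                                        seed = 6L, maxLen = 60L))
  model <- trainModel(model, exs, steps = 30L, batchSize = 8L, seed = 2L,
                      sampler = "uniform")
  out <- generateMolecules(model, dias[[1]]@turns$text[1], k = 3L)
  expect_length(out, 3L)
  expect_identical(out, generateMolecules(model, dias[[1]]@turns$text[1],
                                          k = 3L))
  desc <- generateDescription(model, dias[[1]]@finalSmiles)
  expect_lte(length(strsplit(desc, " ")[[1]]), model@config$maxLen)
  aug <- dualAugment(model, c("CCO", "CCN"))
  expect_equal(nrow(aug), 2L)
  expect_true(all(aug$augmented))
})
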