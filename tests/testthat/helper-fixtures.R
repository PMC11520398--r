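# Shared fixtures, built once per test run and cached.

.fixtureEnv <- new.env()

fixtureCorpus <- function(n = 30L, seed = 5L) {
  key <- sprintf("corpus_%d_%d", n, seed)
  if (is.null(.fixtureEnv[[key]])) .fixtureEnv[[key]] <- genCorpus(n, seed)
  .fixtureEnv[[key]]
}

fixtureDialogues <- function(n = 30L, seed = 5L, buildSeed = 11L) {
  key <- sprintf("dias_%d_%d_%d", n, seed, buildSeed)
  if (is.null(.fixtureEnv[[key]])) {
    .fixtureEnv[[key]] <- suppressWarnings(buildDialogues(
      fixtureCorpus(n, seed), config = dialogueConfig(retainLowSim = 0),
      seed = buildSeed))
  }
  .fixtureEnv[[key]]
}
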