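# User-facing model layer: vocabulary construction, the ConverseModel S4
# handle with its twin routes, multi-task pretraining, dialogue fine-tuning,
# dual augmentation and top-k generation.

.SPECIAL_TOKENS <- c("<pad>", "<bos>", "<eos>", "<unk>",
                     sprintf("<X%d>", 0:9))
.FINETUNE_PREFIXES <- c(generate = "[GENERATE]", describe = "[DESCRIBE]")

# Mixed tokenizer for model sequences: bracketed task prefixes and span
# sentinels stay whole, embedded SMILES are atom-tokenized, everything else
# is word-tokenized.
.modelTokens <- function(text) {
  out <- character(0)
  for (p in strsplit(text, " ", fixed = TRUE)[[1]]) {
    if (!nzchar(p)) next
    if (grepl("^\\[[A-Z0-9]+\\]$", p) || grepl("^<X[0-9]+>$", p)) {
      out <- c(out, p)
    } else {
      out <- c(out, .mixedTokens(p))
    }
  }
  out
}

.detok <- function(tokens, route) {
  if (route == "mol") paste(tokens, collapse = "") else
    paste(tokens, collapse = " ")
}

# ---- training examples ------------------------------------------------------

.example <- function(srcToks, tgtToks, route, task) {
  list(src = srcToks, tgt = tgtToks, route = route, task = task)
}

.TASK_ROUTE <- c(mlm_text = "text", mlm_smiles = "mol",
                 map_text2mol = "mol", map_mol2name = "text",
                 property = "text", spatial = "text",
                 dialogue = "mol", describe = "text")

#' Turn knowledge records into model training examples
#'
#' Routes each record by its target language: SMILES-out tasks (SMILES MLM,
#' text-to-molecule mapping) go to the molecule route, text-out tasks to the
#' text route.
#'
#' @param records data.frame of KnowledgeRecords.
#' @return List of tokenized training examples.
#' @export
knowledgeExamples <- function(records) {
  lapply(seq_len(nrow(records)), function(i) {
    task <- records$task[i]
    .example(.modelTokens(records$source[i]),
             .modelTokens(records$target[i]),
             .TASK_ROUTE[[task]], task)
  })
}

#' Turn dialogues into generation fine-tuning examples
#'
#' One example per turn: the source is the turn input (cumulative text plus
#' "It looks like ..." with the previous turn's reference molecule --
#' teacher forcing), the target the turn's expected molecule.
#'
#' @param dialogues List of \linkS4class{Dialogue} objects.
#' @return List of tokenized training examples (task "dialogue").
#' @export
dialogueExamples <- function(dialogues) {
  out <- list()
  for (d in dialogues) {
    t <- d@turns
    for (k in seq_len(nrow(t))) {
      prev <- if (k > 1L) t$expectedSmiles[k - 1L] else NULL
      src <- paste(.FINETUNE_PREFIXES[["generate"]],
                   makeTurnInput(t$text[k], prev))
      out[[length(out) + 1L]] <- .example(
        .modelTokens(src), smilesTokens(t$expectedSmiles[k]),
        "mol", "dialogue")
    }
  }
  out
}

#' Turn molecule-description pairs into understanding examples
#'
#' @param pairs data.frame with columns smiles and description.
#' @return List of tokenized training examples (task "describe").
#' @export
understandingExamples <- function(pairs) {
  lapply(seq_len(nrow(pairs)), function(i) {
    src <- paste(.FINETUNE_PREFIXES[["describe"]], pairs$smiles[i])
    .example(.modelTokens(src), wordTokens(pairs$description[i]),
             "text", "describe")
  })
}

#' Build a model vocabulary from training examples
#'
#' @param examples List of tokenized examples.
#' @return Character vector of tokens (specials and task prefixes first).
#' @export
modelVocabulary <- function(examples) {
  toks <- unique(unlist(lapply(examples, function(e) c(e$src, e$tgt))))
  # radix sort = C collation regardless of locale, so vocabularies (and
  # therefore token ids and parameter initialization) are reproducible
  # across sessions
  unique(c(.SPECIAL_TOKENS, unname(taskPrefixes()),
           unname(.FINETUNE_PREFIXES), sort(toks, method = "radix")))
}

# ---- model construction -----------------------------------------------------

#' Model configuration
#'
#' @param hidden Hidden and embedding width; default 64.
#' @param layers GRU layers per encoder/decoder; default 2.
#' @param maxLen Maximum source/target length in tokens; default 100.
#' @param seed Initialization seed.
#' @param shareEmbeddings Share embedding tables between the two routes?
#'   Default FALSE (fully independent parameter sets).
#' @param lr Adam learning rate; default 5e-3 (toy-scale overfitting).
#' @param clip Global gradient-norm clip; default 5.
#' @return Named list.
#' @export
converseConfig <- function(hidden = 64L, layers = 2L, maxLen = 100L,
                           seed = 1L, shareEmbeddings = FALSE, lr = 5e-3,
                           clip = 5) {
  stopifnot(hidden > 0, layers > 0, maxLen > 4)
  list(hidden = as.integer(hidden), layers = as.integer(layers),
       maxLen = as.integer(maxLen), seed = as.integer(seed),
       shareEmbeddings = isTRUE(shareEmbeddings), lr = lr, clip = clip)
}

#' Build a twin encoder-decoder model
#'
#' Two independent GRU encoder-decoder parameter sets over a shared joint
#' vocabulary: one decodes molecules, the other text. Initialization is
#' deterministic per seed.
#'
#' @param vocab Character vector from [modelVocabulary()].
#' @param config See [converseConfig()].
#' @return A \linkS4class{ConverseModel}.
#' @export
converseModel <- function(vocab, config = converseConfig()) {
  stopifnot(length(vocab) > length(.SPECIAL_TOKENS))
  V <- length(vocab)
  .withSeed(config$seed, {
    mol <- .initRoute(V, config$hidden, config$layers)
    txt <- .initRoute(V, config$hidden, config$layers)
    if (config$shareEmbeddings) {
      txt$Esrc <- mol$Esrc
      txt$Etgt <- mol$Etgt
    }
    new("ConverseModel",
        config = c(config, list(vocab = vocab)),
        molRoute = mol, textRoute = txt,
        trainState = list(step = 0L, losses = numeric(0),
                          trajectory = data.frame(step = integer(0),
                                                  task = character(0),
                                                  loss = numeric(0)),
                          opt = list(mol = list(), text = list())))
  })
}

#' Number of trainable parameters
#'
#' @param model A \linkS4class{ConverseModel}.
#' @return Integer parameter count over both routes.
#' @export
nParameters <- function(model) {
  cnt <- function(route) sum(vapply(.flattenParams(route), length, 0L))
  cnt(model@molRoute) + cnt(model@textRoute)
}

setMethod("show", "ConverseModel", function(object) {
  cfg <- object@config
  cat("ConverseModel: twin GRU encoder-decoder\n",
      " hidden", cfg$hidden, "| layers", cfg$layers, "| vocab",
      length(cfg$vocab), "| params", nParameters(object), "\n",
      " trained steps:", object@trainState$step, "\n")
})

.vocabIds <- function(model) {
  stats::setNames(seq_along(model@config$vocab), model@config$vocab)
}

.encodeIds <- function(toks, ids, maxLen) {
  v <- unname(ids[toks])
  v[is.na(v)] <- ids[["<unk>"]]
  utils::head(v, maxLen)
}

# ---- training ---------------------------------------------------------------

.padBatch <- function(exIds, padId, bosId, eosId) {
  B <- length(exIds)
  S <- max(vapply(exIds, function(e) length(e$src), 0L))
  Tn <- max(vapply(exIds, function(e) length(e$tgt), 0L)) + 1L  # room for EOS
  src <- matrix(padId, B, S)
  tgtIn <- matrix(padId, B, Tn)
  tgtOut <- matrix(padId, B, Tn)
  mask <- matrix(0, B, Tn)
  for (b in seq_len(B)) {
    s <- exIds[[b]]$src
    src[b, (S - length(s) + 1L):S] <- s            # left-pad the encoder
    tg <- c(exIds[[b]]$tgt, eosId)
    tgtIn[b, seq_along(tg)] <- c(bosId, tg[-length(tg)])
    tgtOut[b, seq_along(tg)] <- tg
    mask[b, seq_along(tg)] <- 1
  }
  list(src = src, tgtIn = tgtIn, tgtOut = tgtOut, mask = mask)
}

#' Train a model on tokenized examples
#'
#' Runs mini-batch Adam steps. With \code{sampler = "task"} each batch is
#' stratified so per-task counts follow the examples' task mixture to
#' within one example; with \code{"uniform"} batches are sampled uniformly
#' with replacement; with \code{"epoch"} examples are visited in shuffled
#' epochs so every example is seen equally often (the default for
#' fine-tuning, where even coverage matters for memorization).
#' Per-task cross-entropies are appended to the loss trajectory. Training is
#' bit-reproducible given (seed, config, data).
#'
#' @param model A \linkS4class{ConverseModel}.
#' @param examples List of tokenized examples.
#' @param steps Number of optimizer steps.
#' @param batchSize Examples per step; default 16.
#' @param seed Sampling seed.
#' @param sampler "task" or "uniform".
#' @param checkpointDir Optional directory; a checkpoint is written every
#'   \code{checkpointEvery} steps.
#' @param checkpointEvery Interval in steps (0 = never).
#' @param lrDecay Multiplicative step decay applied at 50% and 80% of
#'   \code{steps} (effective rate lr, lr*lrDecay, lr*lrDecay^2); default
#'   0.3. Set to 1 for a constant rate.
#' @param lr Optional base learning rate overriding the model config (e.g.
#'   for a low-rate annealing phase after the main run).
#' @return The updated model.
#' @export
trainModel <- function(model, examples, steps, batchSize = 16L, seed = 1L,
                       sampler = c("task", "uniform", "epoch"),
                       checkpointDir = NULL, checkpointEvery = 0L,
                       lrDecay = 0.3, lr = NULL) {
  sampler <- match.arg(sampler)
  stopifnot(length(examples) >= 1L, steps >= 1L)
  ids <- .vocabIds(model)
  maxLen <- model@config$maxLen
  exIds <- lapply(examples, function(e) {
    list(src = .encodeIds(e$src, ids, maxLen),
         tgt = .encodeIds(e$tgt, ids, maxLen),
         route = e$route, task = e$task)
  })
  padId <- ids[["<pad>"]]; bosId <- ids[["<bos>"]]; eosId <- ids[["<eos>"]]
  tasks <- vapply(exIds, function(e) e$task, "")
  taskFreq <- table(tasks) / length(tasks)
  byTask <- split(seq_along(exIds), tasks)
  batchSize <- min(batchSize, length(exIds))

  st <- model@trainState
  traj <- list(st$trajectory)
  epochOrder <- integer(0)
  .withSeed(seed, {
    for (step in seq_len(steps)) {
      take <- if (sampler == "epoch") {
        if (length(epochOrder) < batchSize) {
          epochOrder <- c(epochOrder, sample.int(length(exIds)))
        }
        out <- epochOrder[seq_len(batchSize)]
        epochOrder <- epochOrder[-seq_len(batchSize)]
        out
      } else if (sampler == "task") {
        counts <- .apportion(batchSize,
                             stats::setNames(as.numeric(taskFreq),
                                             names(taskFreq)))
        unlist(lapply(names(counts), function(tk) {
          pool <- byTask[[tk]]
          if (!counts[[tk]]) return(integer(0))
          pool[sample.int(length(pool), counts[[tk]],
                          replace = counts[[tk]] > length(pool))]
        }))
      } else {
        sample.int(length(exIds), batchSize,
                   replace = batchSize > length(exIds))
      }
      batch <- exIds[take]
      st$step <- st$step + 1L
      # one gradient step per route, accumulating over its tasks
      for (routeName in unique(vapply(batch, function(e) e$route, ""))) {
        sub <- batch[vapply(batch, function(e) e$route, "") == routeName]
        route <- if (routeName == "mol") model@molRoute else model@textRoute
        grads <- NULL
        for (tk in unique(vapply(sub, function(e) e$task, ""))) {
          tsub <- sub[vapply(sub, function(e) e$task, "") == tk]
          pb <- .padBatch(tsub, padId, bosId, eosId)
          res <- .routeBatch(route, pb$src, pb$tgtIn, pb$tgtOut, pb$mask,
                            padId)
          w <- length(tsub) / length(sub)
          grads <- if (is.null(grads)) {
            rapply(res$grads, function(x) x * w, how = "replace")
          } else {
            .sumParams(grads, res$grads, w)
          }
          st$losses[tk] <- res$loss
          traj[[length(traj) + 1L]] <- data.frame(
            step = st$step, task = tk, loss = res$loss,
            stringsAsFactors = FALSE)
        }
        lrEff <- (lr %||% model@config$lr) *
          lrDecay^((step > 0.5 * steps) + (step > 0.8 * steps))
        up <- .adamStep(route, grads, st$opt[[routeName]],
                        lr = lrEff, clip = model@config$clip)
        st$opt[[routeName]] <- up$state
        if (routeName == "mol") model@molRoute <- up$route
        else model@textRoute <- up$route
      }
      if (checkpointEvery > 0L && !is.null(checkpointDir) &&
          st$step %% checkpointEvery == 0L) {
        model@trainState <- st
        model@trainState$trajectory <- do.call(rbind, traj)
        saveModel(model, file.path(checkpointDir,
                                   sprintf("step%06d", st$step)))
      }
    }
  })
  st$trajectory <- do.call(rbind, traj)
  model@trainState <- st
  model
}

.sumParams <- function(a, b, w) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- .sumParams(a[[i]], b[[i]], w)
    a
  } else a + b * w
}

#' Multi-task pretraining on knowledge records
#'
#' Mixes all task types in every batch (per-task counts within one example
#' of the mixture weights implied by the record set).
#'
#' @param model A \linkS4class{ConverseModel}.
#' @param records data.frame of KnowledgeRecords.
#' @param steps,batchSize,seed,checkpointDir,checkpointEvery See
#'   [trainModel()].
#' @return The updated model.
#' @export
pretrainModel <- function(model, records, steps = 200L, batchSize = 16L,
                          seed = 1L, checkpointDir = NULL,
                          checkpointEvery = 0L) {
  if (!nrow(records)) stop("empty record stream")
  trainModel(model, knowledgeExamples(records), steps, batchSize, seed,
             sampler = "task", checkpointDir = checkpointDir,
             checkpointEvery = checkpointEvery)
}

#' Fine-tune the molecule route on dialogues
#'
#' @param model A \linkS4class{ConverseModel}.
#' @param dialogues List of \linkS4class{Dialogue} objects.
#' @param augmented Optional data.frame (smiles, description) of
#'   dual-augmentation pairs added as single-turn generation examples.
#' @param steps,batchSize,seed See [trainModel()].
#' @return The updated model.
#' @export
fineTuneDialogues <- function(model, dialogues, augmented = NULL,
                              steps = 300L, batchSize = 16L, seed = 1L) {
  exs <- dialogueExamples(dialogues)
  if (!is.null(augmented) && nrow(augmented)) {
    exs <- c(exs, lapply(seq_len(nrow(augmented)), function(i) {
      src <- paste(.FINETUNE_PREFIXES[["generate"]],
                   augmented$description[i])
      .example(.modelTokens(src), smilesTokens(augmented$smiles[i]),
               "mol", "dialogue")
    }))
  }
  trainModel(model, exs, steps, batchSize, seed, sampler = "epoch")
}

#' Fine-tune the text route on molecule-description pairs
#'
#' @param model A \linkS4class{ConverseModel}.
#' @param pairs data.frame with smiles and description.
#' @param steps,batchSize,seed See [trainModel()].
#' @return The updated model.
#' @export
fineTuneUnderstanding <- function(model, pairs, steps = 300L,
                                  batchSize = 16L, seed = 1L) {
  trainModel(model, understandingExamples(pairs), steps, batchSize, seed,
             sampler = "epoch")
}

# ---- inference --------------------------------------------------------------

#' Generate the k most likely molecules for a prompt
#'
#' Beam search (width >= 2k) on the molecule route; returns distinct decoded
#' SMILES strings in rank order. If the beam yields fewer than k distinct
#' strings the list is padded with the top hypothesis.
#'
#' @param model A trained \linkS4class{ConverseModel}.
#' @param prompt Turn input text (see [makeTurnInput()]).
#' @param k Number of molecules; default 3.
#' @return Character vector of length k.
#' @export
generateMolecules <- function(model, prompt, k = 3L) {
  stopifnot(k >= 1L)
  ids <- .vocabIds(model)
  src <- .encodeIds(.modelTokens(paste(.FINETUNE_PREFIXES[["generate"]],
                                       prompt)),
                    ids, model@config$maxLen)
  hyps <- .beamDecode(model@molRoute, src, ids[["<bos>"]], ids[["<eos>"]],
                      k = k, maxLen = model@config$maxLen)
  vocab <- model@config$vocab
  outs <- unique(vapply(hyps, function(h) .detok(vocab[h$ids], "mol"), ""))
  outs <- outs[nzchar(outs)]
  if (!length(outs)) outs <- "C"
  if (length(outs) < k) outs <- c(outs, rep(outs[1], k - length(outs)))
  outs[seq_len(k)]
}

#' Generate a property description for a molecule
#'
#' Greedy (beam width 1 equivalent) decoding of the text route.
#'
#' @param model A trained \linkS4class{ConverseModel}.
#' @param smiles Molecule SMILES.
#' @return Description text.
#' @export
generateDescription <- function(model, smiles) {
  stopifnot(nzchar(smiles))
  ids <- .vocabIds(model)
  src <- .encodeIds(.modelTokens(paste(.FINETUNE_PREFIXES[["describe"]],
                                       smiles)),
                    ids, model@config$maxLen)
  hyps <- .beamDecode(model@textRoute, src, ids[["<bos>"]], ids[["<eos>"]],
                      k = 1L, maxLen = model@config$maxLen, beamWidth = 1L)
  if (!length(hyps)) return("")
  .detok(model@config$vocab[hyps[[1]]$ids], "text")
}

#' Dual augmentation: describe molecules with the understanding route
#'
#' The fine-tuned understanding model generates one description per
#' molecule; the pairs are flagged augmented so evaluation sets can exclude
#' them, and can be merged into generation fine-tuning via
#' [fineTuneDialogues()].
#'
#' @param model A trained \linkS4class{ConverseModel}.
#' @param molecules Character vector of SMILES.
#' @return data.frame with smiles, description, augmented = TRUE.
#' @export
dualAugment <- function(model, molecules) {
  data.frame(
    smiles = molecules,
    description = vapply(molecules, function(m) generateDescription(model, m),
                         "", USE.NAMES = FALSE),
    augmented = TRUE,
    stringsAsFactors = FALSE
  )
}

# ---- persistence ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes the parameter sets (binary), a JSON config and the training-curve
#' TSV into \code{dir}.
#'
#' @param model A \linkS4class{ConverseModel}.
#' @param dir Checkpoint directory (created).
#' @return \code{dir}, invisibly.
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(molRoute = model@molRoute, textRoute = model@textRoute,
               trainState = model@trainState),
          file.path(dir, "params.rds"))
  cfg <- model@config
  jsonlite::write_json(cfg[setdiff(names(cfg), "vocab")],
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  writeLines(cfg$vocab, file.path(dir, "vocab.txt"), useBytes = TRUE)
  .writeTsv(model@trainState$trajectory, file.path(dir, "losses.tsv"))
  invisible(dir)
}

#' Load a model checkpoint written by [saveModel()]
#'
#' @param dir Checkpoint directory.
#' @return A \linkS4class{ConverseModel}.
#' @export
loadModel <- function(dir) {
  p <- readRDS(file.path(dir, "params.rds"))
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  cfg$vocab <- readLines(file.path(dir, "vocab.txt"), warn = FALSE)
  new("ConverseModel", config = cfg, molRoute = p$molRoute,
      textRoute = p$textRoute, trainState = p$trainState)
}

#' Training-loss trajectory
#'
#' @param model A \linkS4class{ConverseModel}.
#' @return data.frame with step, task, loss.
#' @export
lossTrajectory <- function(model) model@trainState$trajectory
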