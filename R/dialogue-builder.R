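# Multi-turn dialogue construction from molecule-description records.
#
# A description is split into sentences and reversed, so cumulative turn
# text grows from general properties to fine structural detail. Every
# non-final turn gets an intermediate target molecule chosen among five
# generated candidates through a fingerprint-similarity gate (path-scheme
# Tanimoto to the final answer strictly above `lo` and strictly below `hi`),
# which withholds the final answer while keeping turns on-topic. Items with
# a single turn, or with "-" in a sentence (chemical nomenclature would leak
# the answer), are rejected.

.ABBREV_GUARD <- c("e.g.", "i.e.", "vs.", "approx.", "ca.", "cf.")

#' Split text into sentences
#'
#' Rule-based segmentation on terminal punctuation followed by whitespace,
#' with a small abbreviation guard list.
#'
#' @param text A character string.
#' @return Character vector of sentences.
#' @export
splitSentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  if (length(parts) < 2L) return(parts)
  out <- parts[1]
  for (p in parts[-1]) {
    lastWord <- sub("^.*\\s", "", out[length(out)])
    if (tolower(lastWord) %in% .ABBREV_GUARD) {
      out[length(out)] <- paste(out[length(out)], p)
    } else {
      out <- c(out, p)
    }
  }
  out
}

#' Split a description into sentences and reverse their order
#'
#' The reversed order makes detail increase over turns: curated
#' molecule descriptions run from fine structure to overall properties, so
#' reversing yields general first, specific last.
#'
#' @param description Description text.
#' @return Character vector of sentences, reversed.
#' @export
splitAndReverse <- function(description) {
  stopifnot(nzchar(description))
  rev(splitSentences(description))
}

#' Replace molecule synonyms by a neutral referential phrase
#'
#' Case-insensitive whole-word replacement of each synonym by "the
#' molecule", longest synonym first, so nested names are not doubly
#' replaced. Prevents names in the text from leaking the answer.
#'
#' @param text Input text.
#' @param synonyms Character vector of names to mask.
#' @return Masked text.
#' @examples
#' replaceSynonyms("Ethanol is volatile.", "ethanol")
#' @export
replaceSynonyms <- function(text, synonyms) {
  if (!length(synonyms)) return(text)
  for (syn in synonyms[order(-nchar(synonyms))]) {
    if (!nzchar(syn)) next
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", syn), "\\b")
    text <- gsub(pat, "the molecule", text, ignore.case = TRUE, perl = TRUE)
  }
  text
}

#' Dialogue-builder configuration
#'
#' @param lo,hi Open similarity-gate interval for intermediate molecules
#'   (path-fingerprint Tanimoto to the final answer must satisfy
#'   \code{lo < s < hi}); defaults 0.5 and 1.
#' @param retainLowSim Probability of keeping a turn whose gate is empty by
#'   falling back to the most similar candidate (a few low-similarity items
#'   are retained for variety); default 0.05.
#' @param nCandidates Candidates requested per turn; default 5.
#' @return A named list.
#' @export
dialogueConfig <- function(lo = 0.5, hi = 1.0, retainLowSim = 0.05,
                           nCandidates = 5L) {
  stopifnot(lo < hi, lo >= 0, hi <= 1, retainLowSim >= 0, retainLowSim <= 1)
  list(lo = lo, hi = hi, retainLowSim = retainLowSim,
       nCandidates = as.integer(nCandidates))
}

#' Select an intermediate target molecule through the similarity gate
#'
#' Keeps candidates that parse and whose path-fingerprint Tanimoto to the
#' final molecule lies strictly inside (lo, hi), then picks one at random.
#'
#' @param candidates Character vector of candidate SMILES.
#' @param final The final answer SMILES.
#' @param lo,hi Open gate bounds.
#' @param seed Integer seed for the random pick.
#' @return A SMILES string, or NULL when no candidate is eligible.
#' @export
selectIntermediate <- function(candidates, final, lo = 0.5, hi = 1.0,
                               seed = 1L) {
  stopifnot(lo < hi, length(candidates) >= 1L)
  if (!isValidSmiles(final)) .invalidSmiles(final, "final molecule")
  ok <- isValidSmiles(candidates)
  if (!any(ok)) return(NULL)
  sims <- suppressWarnings(tanimotoToRef(candidates[ok], final, scheme = "path"))
  eligible <- candidates[ok][sims > lo & sims < hi]
  if (!length(eligible)) return(NULL)
  .withSeed(seed, sample(eligible, 1L))
}

#' Compose the model input for one turn
#'
#' Cumulative description text, plus the sentence "It looks like {SMILES}."
#' referencing the previous turn's molecule when one exists.
#'
#' @param cumulativeText Concatenated sentences up to this turn.
#' @param previousMolecule SMILES of the previous turn's molecule, or NULL.
#' @return Model input text.
#' @export
makeTurnInput <- function(cumulativeText, previousMolecule = NULL) {
  if (is.null(previousMolecule) || !nzchar(previousMolecule %||% "")) {
    return(cumulativeText)
  }
  paste0(cumulativeText, " It looks like ", previousMolecule, ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- candidate generation ---------------------------------------------------

.CANDIDATE_SUBS <- list(C = c("N", "O", "S"), N = c("C", "O"), O = c("C", "N"),
                        F = c("Cl", "Br"), Cl = c("F", "Br"), Br = c("Cl", "F"))

#' Default structural-perturbation candidate generator
#'
#' Stands in for a large captioning model: proposes molecules near the final
#' answer by token-level edits (atom substitution, chain extension, terminal
#' deletion, branch insertion), keeps those that parse and are not
#' canonical-equal to the answer, and returns the top \code{n} ordered by
#' descending path-fingerprint similarity to the answer. Deterministic per
#' seed. Duplicates the closest perturbations when fewer than \code{n}
#' distinct ones exist.
#'
#' @param cumulativeText Turn text (unused by this generator; kept for
#'   interface compatibility with learned generators).
#' @param final Final answer SMILES (must parse).
#' @param seed Integer seed.
#' @param n Number of candidates (default 5).
#' @return Character vector of \code{n} SMILES.
#' @export
defaultCandidateGenerator <- function(cumulativeText, final, seed = 1L,
                                      n = 5L) {
  if (!isValidSmiles(final)) .invalidSmiles(final, "candidate basis")
  toks <- smilesTokens(final)
  .withSeed(seed, {
    raw <- character(0)
    atomPos <- which(toks %in% names(.CANDIDATE_SUBS))
    for (trial in seq_len(40L)) {
      op <- sample(c("sub", "append", "delete", "branch"), 1L,
                   prob = c(0.45, 0.25, 0.15, 0.15))
      cand <- switch(op,
        sub = {
          if (!length(atomPos)) next
          p <- if (length(atomPos) == 1L) atomPos else sample(atomPos, 1L)
          t2 <- toks
          t2[p] <- sample(.CANDIDATE_SUBS[[toks[p]]], 1L)
          paste(t2, collapse = "")
        },
        append = paste0(final, sample(c("C", "O", "N", "CC"), 1L)),
        delete = {
          if (length(toks) < 2L || !toks[length(toks)] %in% c("C", "N", "O")) next
          paste(toks[-length(toks)], collapse = "")
        },
        branch = {
          if (!length(atomPos)) next
          p <- if (length(atomPos) == 1L) atomPos else sample(atomPos, 1L)
          paste(c(toks[seq_len(p)], "(C)", toks[-seq_len(p)]), collapse = "")
        }
      )
      raw <- c(raw, cand)
    }
    ok <- raw[isValidSmiles(raw)]
    if (length(ok)) {
      finalCan <- canonicalSmiles(final)
      cans <- canonicalSmiles(ok)
      keep <- !duplicated(cans) & cans != finalCan
      ok <- ok[keep]
    }
    if (!length(ok)) {
      # degenerate answers (e.g. single atoms) may defeat every edit; pad
      # with a simple homolog so the contract of n candidates holds
      ok <- paste0(final, "C")
      ok <- ok[isValidSmiles(ok)]
      if (!length(ok)) ok <- "C"
    }
    sims <- suppressWarnings(tanimotoToRef(ok, final, scheme = "path"))
    ok <- ok[order(-sims)]
    ok[((seq_len(n) - 1L) %% length(ok)) + 1L]
  })
}

# ---- dialogue assembly ------------------------------------------------------

.rejection <- function(id, reason) {
  structure(list(moleculeId = id, reason = reason),
            class = "dialogueRejection")
}

#' Build one dialogue from a molecule-description record
#'
#' Applies, in order: synonym masking, sentence split and reversal, the "-"
#' filter, the single-turn filter; then requests candidates for each
#' non-final turn and passes them through the similarity gate. With
#' probability \code{retainLowSim} a turn with an empty gate keeps its most
#' similar candidate instead of rejecting the item.
#'
#' @param record List or one-row data.frame with moleculeId, smiles,
#'   description and optionally name (masked as a synonym).
#' @param candidateGenerator Function (text, final, seed, n) -> SMILES
#'   vector; default [defaultCandidateGenerator()].
#' @param config See [dialogueConfig()].
#' @param seed Integer seed.
#' @return A \linkS4class{Dialogue}, or a \code{dialogueRejection} list with
#'   reason "single_turn", "hyphen" or "no_candidate".
#' @export
buildDialogue <- function(record, candidateGenerator = defaultCandidateGenerator,
                          config = dialogueConfig(), seed = 1L) {
  rec <- as.list(record)
  stopifnot(!is.null(rec$smiles), !is.null(rec$description))
  id <- rec$moleculeId %||% "D1"
  if (!isValidSmiles(rec$smiles)) .invalidSmiles(rec$smiles, "record molecule")

  masked <- replaceSynonyms(rec$description,
                            c(rec$name %||% character(0),
                              rec$synonyms %||% character(0)))
  sentences <- splitAndReverse(masked)
  if (any(grepl("-", sentences, fixed = TRUE))) return(.rejection(id, "hyphen"))
  if (length(sentences) < 2L) return(.rejection(id, "single_turn"))

  n <- length(sentences)
  expected <- character(n)
  expected[n] <- rec$smiles
  for (k in seq_len(n - 1L)) {
    tk <- paste(sentences[seq_len(k)], collapse = " ")
    kseed <- as.integer((seed + 7919L * k) %% .Machine$integer.max)
    cands <- candidateGenerator(tk, rec$smiles, seed = kseed,
                                n = config$nCandidates)
    chosen <- selectIntermediate(cands, rec$smiles, lo = config$lo,
                                 hi = config$hi, seed = kseed + 1L)
    if (is.null(chosen)) {
      keep <- config$retainLowSim > 0 &&
        .withSeed(kseed + 2L, stats::runif(1)) < config$retainLowSim
      if (!keep) return(.rejection(id, "no_candidate"))
      ok <- cands[isValidSmiles(cands)]
      finalCan <- canonicalSmiles(rec$smiles)
      ok <- ok[canonicalSmiles(ok) != finalCan]
      if (!length(ok)) return(.rejection(id, "no_candidate"))
      sims <- suppressWarnings(tanimotoToRef(ok, rec$smiles, scheme = "path"))
      chosen <- ok[which.max(sims)]
    }
    expected[k] <- chosen
  }

  cum <- vapply(seq_len(n), function(k) {
    paste(sentences[seq_len(k)], collapse = " ")
  }, "")
  new("Dialogue",
      dialogueId = as.character(id),
      sentences = sentences,
      turns = data.frame(k = seq_len(n), text = cum, expectedSmiles = expected,
                         stringsAsFactors = FALSE),
      finalSmiles = rec$smiles)
}

#' Build dialogues for a whole corpus
#'
#' @param corpus A \linkS4class{SyntheticCorpus} (or a data.frame of
#'   records).
#' @param candidateGenerator,config,seed As in [buildDialogue()].
#' @return List with \code{dialogues} (list of \linkS4class{Dialogue}) and
#'   \code{rejections} (data.frame moleculeId/reason).
#' @export
buildDialogues <- function(corpus, candidateGenerator = defaultCandidateGenerator,
                           config = dialogueConfig(), seed = 1L) {
  records <- if (is(corpus, "SyntheticCorpus")) corpusRecords(corpus) else corpus
  dialogues <- list()
  rej <- list()
  for (i in seq_len(nrow(records))) {
    res <- buildDialogue(records[i, ], candidateGenerator, config,
                         seed = as.integer((seed + i * 104729L) %% .Machine$integer.max))
    if (is(res, "Dialogue")) {
      dialogues[[length(dialogues) + 1L]] <- res
    } else {
      rej[[length(rej) + 1L]] <- data.frame(moleculeId = res$moleculeId,
                                            reason = res$reason,
                                            stringsAsFactors = FALSE)
    }
  }
  list(
    dialogues = dialogues,
    rejections = if (length(rej)) do.call(rbind, rej) else
      data.frame(moleculeId = character(0), reason = character(0),
                 stringsAsFactors = FALSE)
  )
}

#' @rdname Dialogue-class
#' @export
setMethod("dialogueTurns", "Dialogue", function(x) x@turns)

#' @rdname Dialogue-class
#' @export
setMethod("finalSmiles", "Dialogue", function(x) x@finalSmiles)

setMethod("show", "Dialogue", function(object) {
  cat("Dialogue", object@dialogueId, "with", nrow(object@turns), "turns ->",
      object@finalSmiles, "\n")
})

#' Assign dialogues to train/validation/test splits by id hash
#'
#' A platform-independent string hash of the dialogue id makes the split
#' reproducible and independent of corpus order.
#'
#' @param dialogues List of \linkS4class{Dialogue} objects.
#' @param proportions Named numeric vector summing to 1; default
#'   c(train = 0.8, validation = 0.1, test = 0.1).
#' @return Factor of split labels, one per dialogue.
#' @export
splitDialogues <- function(dialogues,
                           proportions = c(train = 0.8, validation = 0.1,
                                           test = 0.1)) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9)
  hashOf <- function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 100000L
    h / 100000
  }
  cuts <- cumsum(proportions)
  labels <- names(proportions)
  vapply(dialogues, function(d) {
    labels[which(hashOf(d@dialogueId) < cuts + 1e-12)[1]]
  }, "")
}

#' Write dialogues as JSONL (plus a rejection log)
#'
#' One object per line: \code{{dialogue_id, turns: [{k, text,
#' expected_smiles}], final_smiles}}.
#'
#' @param built Result of [buildDialogues()].
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
writeDialogues <- function(built, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(built$dialogues, function(d) {
    list(
      dialogue_id = d@dialogueId,
      turns = lapply(seq_len(nrow(d@turns)), function(k) {
        list(k = d@turns$k[k], text = d@turns$text[k],
             expected_smiles = d@turns$expectedSmiles[k])
      }),
      final_smiles = d@finalSmiles
    )
  })
  writeJsonl(recs, file.path(dir, "dialogues.jsonl"))
  .writeTsv(built$rejections, file.path(dir, "rejections.tsv"))
  invisible(dir)
}

#' Read dialogues written by [writeDialogues()]
#'
#' @param dir Directory containing dialogues.jsonl.
#' @return List of \linkS4class{Dialogue} objects.
#' @export
readDialogues <- function(dir) {
  lapply(readJsonl(file.path(dir, "dialogues.jsonl")), function(r) {
    turns <- r$turns
    if (is.data.frame(turns)) {
      tdf <- data.frame(k = as.integer(turns$k), text = turns$text,
                        expectedSmiles = turns$expected_smiles,
                        stringsAsFactors = FALSE)
    } else {
      tdf <- do.call(rbind, lapply(turns, function(t) {
        data.frame(k = as.integer(t$k), text = t$text,
                   expectedSmiles = t$expected_smiles, stringsAsFactors = FALSE)
      }))
    }
    new("Dialogue", dialogueId = r$dialogue_id,
        sentences = vapply(seq_len(nrow(tdf)), function(k) {
          if (k == 1L) tdf$text[1] else {
            substring(tdf$text[k], nchar(tdf$text[k - 1L]) + 2L)
          }
        }, ""),
        turns = tdf, finalSmiles = r$final_smiles)
  })
}
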