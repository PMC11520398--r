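# Knowledge-injection pretraining examples: span-corruption MLM on text and
# SMILES, name<->SMILES mapping correlation, experimental-property QA and
# spatial-structure QA. Every example is a (task, source, target) triple
# whose source starts with the task's prefix token; property and spatial
# targets are built from chem_core ground truth and are machine-checkable.

#' Task prefix tokens
#'
#' Prefixes prepended to the source sequence of each pretraining task so a
#' single multi-task model can route behaviour.
#'
#' @return Named character vector over the six task types.
#' @export
taskPrefixes <- function() {
  c(mlm_text = "[MLMTEXT]", mlm_smiles = "[MLMSMILES]",
    map_text2mol = "[TEXT2MOL]", map_mol2name = "[MOL2NAME]",
    property = "[PROPERTY]", spatial = "[SPATIAL]")
}

.knowledgeRecord <- function(task, source, target) {
  data.frame(task = task, source = source, target = target,
             stringsAsFactors = FALSE)
}

# ---- span corruption --------------------------------------------------------

#' Mask token spans, T5 span-corruption style
#'
#' Replaces contiguous spans by sentinel tokens; the target lists each
#' sentinel followed by the tokens it hides, ending with a closing sentinel,
#' so corruption is lossless. The number of masked tokens is within one
#' token of \code{round(maskRate * length(tokens))}; spans average about 3
#' tokens and are separated by at least one kept token. Deterministic per
#' seed.
#'
#' @param tokens Character vector of at least 2 tokens.
#' @param maskRate Fraction of tokens to mask, in (0, 1); default 0.15.
#' @param seed Integer seed.
#' @return List with \code{corrupted} and \code{targets} token vectors.
#' @examples
#' maskSpans(strsplit("the quick brown fox jumps over the lazy dog", " ")[[1]],
#'           maskRate = 0.3, seed = 1)
#' @export
maskSpans <- function(tokens, maskRate = 0.15, seed = 1L) {
  stopifnot(maskRate > 0, maskRate < 1)
  len <- length(tokens)
  if (len < 2L) stop("sequence must have at least 2 tokens")
  nMask <- max(1L, round(maskRate * len))
  nMask <- min(nMask, len - 1L)
  .withSeed(seed, {
    nSpans <- max(1L, round(nMask / 3))
    # spans need a separating kept token; shrink span count if infeasible
    while (nSpans > 1L && (len - nMask) < (nSpans - 1L)) nSpans <- nSpans - 1L
    # random composition of nMask into nSpans positive parts
    if (nSpans == 1L) {
      spanLens <- nMask
    } else {
      cutsAt <- sort(sample(nMask - 1L, nSpans - 1L))
      spanLens <- diff(c(0L, cutsAt, nMask))
    }
    # gaps: g0 >= 0, inner gaps >= 1, gEnd >= 0, summing to len - nMask
    u <- len - nMask
    extra <- u - (nSpans - 1L)
    gaps <- as.integer(stats::rmultinom(1, extra, rep(1, nSpans + 1L)))
    if (nSpans > 1L) gaps[2:nSpans] <- gaps[2:nSpans] + 1L

    corrupted <- character(0)
    targets <- character(0)
    pos <- 1L
    for (s in seq_len(nSpans)) {
      keep <- gaps[s]
      if (keep > 0L) {
        corrupted <- c(corrupted, tokens[pos:(pos + keep - 1L)])
        pos <- pos + keep
      }
      sentinel <- sprintf("<X%d>", s - 1L)
      corrupted <- c(corrupted, sentinel)
      targets <- c(targets, sentinel, tokens[pos:(pos + spanLens[s] - 1L)])
      pos <- pos + spanLens[s]
    }
    if (pos <= len) corrupted <- c(corrupted, tokens[pos:len])
    targets <- c(targets, sprintf("<X%d>", nSpans))
    list(corrupted = corrupted, targets = targets)
  })
}

#' Reconstruct the original tokens from a span corruption
#'
#' @param corrupted,targets As returned by [maskSpans()].
#' @return The original token vector.
#' @export
reconstructSpans <- function(corrupted, targets) {
  isSent <- grepl("^<X[0-9]+>$", targets)
  spans <- split(targets[!isSent], cumsum(isSent)[!isSent])
  names(spans) <- targets[isSent][unique(cumsum(isSent)[!isSent])]
  out <- character(0)
  for (tok in corrupted) {
    if (grepl("^<X[0-9]+>$", tok)) {
      out <- c(out, spans[[tok]])
    } else {
      out <- c(out, tok)
    }
  }
  out
}

#' Build MLM records for a corpus
#'
#' Text MLM corrupts word tokens of descriptions; SMILES MLM corrupts
#' atom-level tokens of molecules.
#'
#' @param corpus A \linkS4class{SyntheticCorpus}.
#' @param n Number of records per kind.
#' @param maskRate Span-corruption rate; default 0.15.
#' @param seed Integer seed.
#' @return data.frame of KnowledgeRecords (task, source, target).
#' @export
makeMlmRecords <- function(corpus, n = 10L, maskRate = 0.15, seed = 1L) {
  recs <- corpusRecords(corpus)
  pref <- taskPrefixes()
  .withSeed(seed, {
    rows <- list()
    idx <- sample(nrow(recs), n, replace = n > nrow(recs))
    for (i in idx) {
      mk <- maskSpans(wordTokens(recs$description[i]), maskRate,
                      seed = sample.int(1e6, 1L))
      rows[[length(rows) + 1L]] <- .knowledgeRecord(
        "mlm_text",
        paste(c(pref[["mlm_text"]], mk$corrupted), collapse = " "),
        paste(mk$targets, collapse = " ")
      )
    }
    idx <- sample(nrow(recs), n, replace = n > nrow(recs))
    for (i in idx) {
      toks <- smilesTokens(recs$smiles[i])
      if (length(toks) < 2L) next
      mk <- maskSpans(toks, maskRate, seed = sample.int(1e6, 1L))
      rows[[length(rows) + 1L]] <- .knowledgeRecord(
        "mlm_smiles",
        paste(c(pref[["mlm_smiles"]], mk$corrupted), collapse = " "),
        paste(mk$targets, collapse = " ")
      )
    }
    do.call(rbind, rows)
  })
}

# ---- mapping correlation ----------------------------------------------------

# Longest-match, non-overlapping, case-insensitive detection of lexicon
# names in text; spans returned in textual order.
.detectEntities <- function(text, lexicon) {
  hits <- list()
  lower <- tolower(text)
  for (name in names(lexicon)) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                              tolower(name)), "\\b")
    for (m in gregexpr(pat, lower, perl = TRUE)) {
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
      for (k in seq_along(starts)) {
        if (starts[k] > 0L) {
          hits[[length(hits) + 1L]] <- list(
            name = name, smiles = unname(lexicon[[name]]),
            start = starts[k], end = starts[k] + lens[k] - 1L
          )
        }
      }
    }
  }
  if (!length(hits)) return(hits)
  # longest match wins; ties broken by earlier start
  ord <- order(vapply(hits, function(h) -(h$end - h$start), 0),
               vapply(hits, function(h) h$start, 0))
  hits <- hits[ord]
  chosen <- list()
  taken <- logical(nchar(text))
  for (h in hits) {
    if (!any(taken[h$start:h$end])) {
      taken[h$start:h$end] <- TRUE
      chosen[[length(chosen) + 1L]] <- h
    }
  }
  chosen[order(vapply(chosen, function(h) h$start, 0))]
}

#' Build mapping-correlation records from one text
#'
#' Detects lexicon names in the text (longest match, non-overlapping) and
#' emits one text-to-molecule record whose target lists the SMILES of all
#' matches in order of appearance, plus one molecule-to-name record per
#' match. No records when nothing matches.
#'
#' @param text A natural-language string.
#' @param lexicon Named character vector name -> SMILES.
#' @return data.frame of KnowledgeRecords (possibly 0 rows).
#' @export
makeMappingRecords <- function(text, lexicon) {
  stopifnot(length(lexicon) > 0L)
  pref <- taskPrefixes()
  ents <- .detectEntities(text, lexicon)
  if (!length(ents)) {
    return(.knowledgeRecord(character(0), character(0), character(0)))
  }
  rows <- list(.knowledgeRecord(
    "map_text2mol",
    paste(pref[["map_text2mol"]], text),
    paste(vapply(ents, function(e) e$smiles, ""), collapse = " ")
  ))
  for (e in ents) {
    rows[[length(rows) + 1L]] <- .knowledgeRecord(
      "map_mol2name", paste(pref[["map_mol2name"]], e$smiles), e$name)
  }
  do.call(rbind, rows)
}

# Carrier sentences that mention lexicon names, used to manufacture mapping
# data from a corpus whose descriptions are name-free by construction.
.carrierSentence <- function(names) {
  if (length(names) == 1L) {
    sprintf("The sample contains %s.", names)
  } else {
    sprintf("The sample contains %s and %s.",
            paste(names[-length(names)], collapse = ", "),
            names[length(names)])
  }
}

# ---- property knowledge -----------------------------------------------------

.propertySentence <- function(property, value) {
  if (property %in% c("melting point", "boiling point", "flash point",
                      "refractive index", "density", "vapor pressure",
                      "viscosity")) {
    sprintf("The %s of the molecule is %s.", property, value)
  } else {
    sprintf("The molecule is %s.", value)
  }
}

#' Build experimental-property records for one molecule
#'
#' One record per property row: the source asks for the property of the
#' SMILES, the target states the recorded value in a sentence.
#'
#' @param moleculeId Molecule id present in the corpus.
#' @param corpus A \linkS4class{SyntheticCorpus} (provides SMILES and the
#'   property table).
#' @return data.frame of KnowledgeRecords.
#' @export
makePropertyRecords <- function(moleculeId, corpus) {
  recs <- corpusRecords(corpus)
  row <- match(moleculeId, recs$moleculeId)
  if (is.na(row)) stop("unknown molecule id: ", moleculeId)
  props <- propertyTable(corpus)
  props <- props[props$moleculeId == moleculeId, , drop = FALSE]
  if (!nrow(props)) stop("molecule ", moleculeId, " has no property rows")
  pref <- taskPrefixes()[["property"]]
  do.call(rbind, lapply(seq_len(nrow(props)), function(i) {
    .knowledgeRecord(
      "property",
      sprintf("%s %s What is the %s of the molecule?", pref,
              recs$smiles[row], props$property[i]),
      .propertySentence(props$property[i], props$value[i])
    )
  }))
}

# ---- spatial knowledge ------------------------------------------------------

.elementList <- function(elements) {
  if (length(elements) == 1L) return(elements)
  paste(paste(elements[-length(elements)], collapse = ", "), "and",
        elements[length(elements)])
}

.spatialAnswer <- function(mol, atomIndex, what) {
  env <- atomEnvironment(mol, atomIndex)
  if (what == "neighbors") {
    if (!nrow(env$neighbors)) {
      sprintf("Atom %d is connected to no other atoms.", atomIndex)
    } else {
      sprintf("Atom %d is connected to %d atoms: %s.", atomIndex,
              nrow(env$neighbors), .elementList(env$neighbors$element))
    }
  } else if (what == "aromaticity") {
    base <- if (env$aromatic) {
      sprintf("Atom %d is aromatic", atomIndex)
    } else {
      sprintf("Atom %d is not aromatic", atomIndex)
    }
    if (length(env$ringSizes)) {
      sprintf("%s and lies in a ring of %d atoms.", base, env$ringSizes[1])
    } else paste0(base, ".")
  } else {
    if (length(env$ringSizes)) {
      sprintf("Atom %d is in a ring of %d atoms.", atomIndex,
              env$ringSizes[1])
    } else sprintf("Atom %d is not in any ring.", atomIndex)
  }
}

.SPATIAL_QUESTION <- c(
  neighbors = "Which atoms are connected to atom %d?",
  aromaticity = "Is atom %d aromatic?",
  ring = "Is atom %d part of a ring?"
)

#' Build spatial-structure records for one molecule
#'
#' Each record queries one atom (chosen by seed) for its neighbours, its
#' aromaticity, or its ring membership; targets are templated true answers
#' from [atomEnvironment()].
#'
#' @param mol A \linkS4class{Molecule} or SMILES string.
#' @param nQueries Number of records (>= 1).
#' @param seed Integer seed.
#' @return data.frame of KnowledgeRecords.
#' @export
makeSpatialRecords <- function(mol, nQueries = 3L, seed = 1L) {
  if (is.character(mol)) mol <- parseSmiles(mol)
  stopifnot(nQueries >= 1L)
  pref <- taskPrefixes()[["spatial"]]
  n <- nrow(atoms(mol))
  .withSeed(seed, {
    do.call(rbind, lapply(seq_len(nQueries), function(q) {
      atomIndex <- sample.int(n, 1L) - 1L
      what <- sample(names(.SPATIAL_QUESTION), 1L)
      .knowledgeRecord(
        "spatial",
        sprintf("%s %s %s", pref, smiles(mol),
                sprintf(.SPATIAL_QUESTION[[what]], atomIndex)),
        .spatialAnswer(mol, atomIndex, what)
      )
    }))
  })
}

# ---- corpus-level mixing and fact checking ---------------------------------

#' Build a mixed multi-task knowledge set from a corpus
#'
#' Emits all six task types; per-task record counts follow the mixture
#' weights to within one example.
#'
#' @param corpus A \linkS4class{SyntheticCorpus}.
#' @param nTotal Total number of records to aim for.
#' @param weights Named mixture weights over the six tasks (normalized
#'   internally); default uniform.
#' @param maskRate MLM span-corruption rate.
#' @param seed Integer seed.
#' @return data.frame of KnowledgeRecords.
#' @export
buildKnowledgeSet <- function(corpus, nTotal = 120L,
                              weights = NULL, maskRate = 0.15, seed = 1L) {
  tasks <- names(taskPrefixes())
  if (is.null(weights)) weights <- stats::setNames(rep(1, 6), tasks)
  stopifnot(setequal(names(weights), tasks))
  weights <- weights[tasks] / sum(weights)
  counts <- .apportion(nTotal, weights)
  recs <- corpusRecords(corpus)
  lex <- corpusLexicon(corpus)
  props <- propertyTable(corpus)

  .withSeed(seed, {
    out <- list()

    mlm <- makeMlmRecords(corpus, n = max(counts[["mlm_text"]],
                                          counts[["mlm_smiles"]]),
                          maskRate = maskRate, seed = sample.int(1e6, 1L))
    out$mlm_text <- utils::head(mlm[mlm$task == "mlm_text", ],
                                counts[["mlm_text"]])
    out$mlm_smiles <- utils::head(mlm[mlm$task == "mlm_smiles", ],
                                  counts[["mlm_smiles"]])

    t2m <- list(); m2n <- list()
    guard <- 0L
    while ((length(t2m) < counts[["map_text2mol"]] ||
            length(m2n) < counts[["map_mol2name"]]) && guard < 10L * nTotal) {
      guard <- guard + 1L
      k <- sample(1:3, 1L)
      nm <- sample(names(lex), min(k, length(lex)))
      mapped <- makeMappingRecords(.carrierSentence(nm), lex)
      for (i in seq_len(nrow(mapped))) {
        if (mapped$task[i] == "map_text2mol" &&
            length(t2m) < counts[["map_text2mol"]]) {
          t2m[[length(t2m) + 1L]] <- mapped[i, ]
        }
        if (mapped$task[i] == "map_mol2name" &&
            length(m2n) < counts[["map_mol2name"]]) {
          m2n[[length(m2n) + 1L]] <- mapped[i, ]
        }
      }
    }
    out$map_text2mol <- do.call(rbind, t2m)
    out$map_mol2name <- do.call(rbind, m2n)

    withProps <- unique(props$moleculeId)
    prop <- list()
    while (length(prop) < counts[["property"]]) {
      id <- sample(withProps, 1L)
      pr <- makePropertyRecords(id, corpus)
      for (i in seq_len(nrow(pr))) {
        if (length(prop) < counts[["property"]]) {
          prop[[length(prop) + 1L]] <- pr[i, ]
        }
      }
    }
    out$property <- do.call(rbind, prop)

    spat <- list()
    while (length(spat) < counts[["spatial"]]) {
      i <- sample(nrow(recs), 1L)
      sp <- makeSpatialRecords(recs$smiles[i], nQueries = 1L,
                               seed = sample.int(1e6, 1L))
      spat[[length(spat) + 1L]] <- sp
    }
    out$spatial <- do.call(rbind, spat)

    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

# Largest-remainder apportionment of n among weights (sums exactly to n).
.apportion <- function(n, weights) {
  raw <- n * weights
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Fact-check knowledge records against the molecular graphs
#'
#' Verifies every spatial target (by re-deriving the atom environment) and
#' every property target (against the corpus property table). Other task
#' types pass vacuously.
#'
#' @param records data.frame of KnowledgeRecords.
#' @param corpus The \linkS4class{SyntheticCorpus} they were built from.
#' @return Logical vector, one entry per record.
#' @export
factCheckKnowledge <- function(records, corpus) {
  props <- propertyTable(corpus)
  recs <- corpusRecords(corpus)
  vapply(seq_len(nrow(records)), function(i) {
    task <- records$task[i]
    src <- records$source[i]
    tgt <- records$target[i]
    if (task == "spatial") {
      m <- regmatches(src, regexec(
        "^\\S+ (\\S+) (Which atoms are connected to atom ([0-9]+)\\?|Is atom ([0-9]+) aromatic\\?|Is atom ([0-9]+) part of a ring\\?)$",
        src))[[1]]
      if (!length(m)) return(FALSE)
      mol <- parseSmiles(m[2])
      atomIndex <- as.integer(c(m[4], m[5], m[6])[nzchar(c(m[4], m[5], m[6]))][1])
      what <- if (grepl("connected", m[3])) "neighbors"
        else if (grepl("aromatic", m[3])) "aromaticity" else "ring"
      identical(tgt, .spatialAnswer(mol, atomIndex, what))
    } else if (task == "property") {
      m <- regmatches(src, regexec(
        "^\\S+ (\\S+) What is the (.+) of the molecule\\?$", src))[[1]]
      if (!length(m)) return(FALSE)
      can <- canonicalSmiles(m[2])
      ids <- recs$moleculeId[canonicalSmiles(recs$smiles) == can]
      hit <- props[props$moleculeId %in% ids & props$property == m[3], ]
      any(vapply(hit$value, function(v) {
        grepl(v, tgt, fixed = TRUE) &&
          identical(tgt, .propertySentence(m[3], v))
      }, TRUE))
    } else {
      TRUE
    }
  }, TRUE)
}

#' Write knowledge records as JSONL
#'
#' @param records data.frame of KnowledgeRecords.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeKnowledgeRecords <- function(records, path) {
  writeJsonl(records, path)
}

#' Read knowledge records written by [writeKnowledgeRecords()]
#'
#' @param path JSONL file.
#' @return data.frame of KnowledgeRecords.
#' @export
readKnowledgeRecords <- function(path) {
  do.call(rbind, lapply(readJsonl(path), function(r) {
    .knowledgeRecord(r$task, r$source, r$target)
  }))
}
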