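# Synthetic molecule-description corpus with verifiable ground truth.
#
# Molecules come from a closed grammar (alkane/alcohol/amine/acid chains of
# 1-8 carbons, optional methyl branch, optional benzene/cyclopropane/
# cyclohexane ring, optional halogen). Descriptions are assembled from an
# enumerated template registry in which every template carries a
# verification predicate over the parsed molecular graph, so an automated
# fact checker can prove each emitted sentence true. Sentences run from fine
# structural detail to general properties, mirroring the style of public
# molecule-description corpora.

.GRAMMAR <- list(
  chainLen = 1:8,
  group = c("alkane", "alcohol", "amine", "acid"),
  ring = c("none", "benzene", "cyclopropane", "cyclohexane"),
  halogen = c("none", "F", "Cl", "Br"),
  branch = c(FALSE, TRUE)
)

.assembleSmiles <- function(chainLen, group, ring, halogen, branch) {
  chain <- if (branch && chainLen >= 3L) {
    paste0("CC(C)", strrep("C", chainLen - 3L), "C")
  } else strrep("C", chainLen)
  suffix <- switch(group, alkane = "", alcohol = "O", amine = "N",
                   acid = "(=O)O")
  ringPart <- switch(ring, none = "", benzene = "c1ccccc1",
                     cyclopropane = "C1CC1", cyclohexane = "C1CCCCC1")
  halPart <- if (halogen == "none") "" else halogen
  paste0(halPart, ringPart, chain, suffix)
}

#' Generate distinct synthetic molecules
#'
#' Samples the closed molecular grammar until \code{n} canonically distinct
#' valid molecules are collected. Deterministic per seed.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed.
#' @return Character vector of \code{n} SMILES (as written by the grammar,
#'   not canonicalized).
#' @examples
#' genMolecules(5, seed = 1)
#' @export
genMolecules <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  .withSeed(seed, {
    seen <- character(0)
    out <- character(0)
    guard <- 0L
    while (length(out) < n) {
      guard <- guard + 1L
      if (guard > 200L * n + 5000L) {
        stop("molecular grammar exhausted before reaching n = ", n)
      }
      smi <- .assembleSmiles(
        chainLen = sample(.GRAMMAR$chainLen, 1L),
        group = sample(.GRAMMAR$group, 1L),
        ring = sample(.GRAMMAR$ring, 1L, prob = c(0.45, 0.25, 0.15, 0.15)),
        halogen = sample(.GRAMMAR$halogen, 1L, prob = c(0.6, 0.1, 0.2, 0.1)),
        branch = sample(.GRAMMAR$branch, 1L, prob = c(0.65, 0.35))
      )
      can <- canonicalSmiles(smi)
      if (!can %in% seen) {
        seen <- c(seen, can)
        out <- c(out, smi)
      }
    }
    out
  })
}

# ---- template registry ------------------------------------------------------

# Each template: id, kind ("fine" structural / "general" property), applies()
# over a Molecule, build() emitting the sentence, and a verification regex +
# predicate used by the fact checker. Sentences never contain "-" and never
# name the molecule.

.hasAcid <- function(mol) {
  a <- atoms(mol); b <- bonds(mol)
  for (ci in a$index[a$element == "C"]) {
    env <- rbind(b[b$i == ci, c("j", "order")],
                 stats::setNames(b[b$j == ci, c("i", "order")], c("j", "order")))
    os <- env[a$element[env$j + 1L] == "O", , drop = FALSE]
    if (nrow(os) >= 2L && any(os$order == "double") && any(os$order == "single")) {
      return(TRUE)
    }
  }
  FALSE
}

.hasHydroxyl <- function(mol) {
  a <- atoms(mol); b <- bonds(mol)
  for (oi in a$index[a$element == "O"]) {
    deg <- sum(b$i == oi | b$j == oi)
    ords <- b$order[b$i == oi | b$j == oi]
    if (deg == 1L && all(ords == "single")) return(TRUE)
  }
  FALSE
}

.hasPrimaryAmine <- function(mol) {
  a <- atoms(mol); b <- bonds(mol)
  for (ni in a$index[a$element == "N"]) {
    deg <- sum(b$i == ni | b$j == ni)
    ords <- b$order[b$i == ni | b$j == ni]
    if (deg == 1L && all(ords == "single") && !a$aromatic[ni + 1L]) return(TRUE)
  }
  FALSE
}

.hasElement <- function(mol, el) el %in% atoms(mol)$element

.hasAromaticSixRing <- function(mol) {
  any(vapply(rings(mol), function(r) {
    length(r) == 6L && all(atoms(mol)$aromatic[r + 1L])
  }, TRUE))
}

.ringSizes <- function(mol) sort(unique(lengths(rings(mol))))

.isBranched <- function(mol) {
  a <- atoms(mol); b <- bonds(mol)
  any(vapply(a$index[a$element == "C"], function(ci) {
    nb <- c(b$j[b$i == ci], b$i[b$j == ci])
    sum(a$element[nb + 1L] == "C") >= 3L
  }, TRUE))
}

.HALOGEN_WORD <- c(F = "fluorine", Cl = "chlorine", Br = "bromine")

.TEMPLATES <- list(
  list(id = "hydroxyl", kind = "fine",
       applies = .hasHydroxyl,
       build = function(mol) "The molecule contains a hydroxyl group.",
       pattern = "^The molecule contains a hydroxyl group\\.$",
       verify = function(mol, m) .hasHydroxyl(mol)),
  list(id = "acid", kind = "fine",
       applies = .hasAcid,
       build = function(mol) "The molecule contains a carboxylic acid group.",
       pattern = "^The molecule contains a carboxylic acid group\\.$",
       verify = function(mol, m) .hasAcid(mol)),
  list(id = "amine", kind = "fine",
       applies = .hasPrimaryAmine,
       build = function(mol) "The molecule contains a primary amine group.",
       pattern = "^The molecule contains a primary amine group\\.$",
       verify = function(mol, m) .hasPrimaryAmine(mol)),
  list(id = "halogen", kind = "fine",
       applies = function(mol) any(names(.HALOGEN_WORD) %in% atoms(mol)$element),
       build = function(mol) {
         el <- intersect(names(.HALOGEN_WORD), atoms(mol)$element)[1]
         sprintf("The molecule carries a %s substituent.", .HALOGEN_WORD[[el]])
       },
       pattern = "^The molecule carries a (fluorine|chlorine|bromine) substituent\\.$",
       verify = function(mol, m) {
         el <- names(.HALOGEN_WORD)[match(m[2], .HALOGEN_WORD)]
         .hasElement(mol, el)
       }),
  list(id = "aromatic_ring", kind = "fine",
       applies = .hasAromaticSixRing,
       build = function(mol) "The molecule includes an aromatic ring of 6 atoms.",
       pattern = "^The molecule includes an aromatic ring of 6 atoms\\.$",
       verify = function(mol, m) .hasAromaticSixRing(mol)),
  list(id = "ring_size", kind = "fine",
       applies = function(mol) length(rings(mol)) > 0L,
       build = function(mol) {
         sprintf("The molecule includes a ring of %d atoms.",
                 min(.ringSizes(mol)))
       },
       pattern = "^The molecule includes a ring of ([0-9]+) atoms\\.$",
       verify = function(mol, m) as.integer(m[2]) %in% .ringSizes(mol)),
  list(id = "acyclic", kind = "fine",
       applies = function(mol) length(rings(mol)) == 0L,
       build = function(mol) "The molecule contains no rings.",
       pattern = "^The molecule contains no rings\\.$",
       verify = function(mol, m) length(rings(mol)) == 0L),
  list(id = "branched", kind = "fine",
       applies = .isBranched,
       build = function(mol) "The molecule has a branched carbon skeleton.",
       pattern = "^The molecule has a branched carbon skeleton\\.$",
       verify = function(mol, m) .isBranched(mol)),
  list(id = "heavy_atoms", kind = "fine",
       applies = function(mol) TRUE,
       build = function(mol) {
         sprintf("The molecule has %d heavy atoms.", nrow(atoms(mol)))
       },
       pattern = "^The molecule has ([0-9]+) heavy atoms\\.$",
       verify = function(mol, m) as.integer(m[2]) == nrow(atoms(mol))),
  list(id = "aromatic_general", kind = "general",
       applies = function(mol) any(atoms(mol)$aromatic),
       build = function(mol) "The molecule is an aromatic compound.",
       pattern = "^The molecule is an aromatic compound\\.$",
       verify = function(mol, m) any(atoms(mol)$aromatic)),
  list(id = "role_acid", kind = "general",
       applies = .hasAcid,
       build = function(mol) "The molecule has a role as an acidic reagent.",
       pattern = "^The molecule has a role as an acidic reagent\\.$",
       verify = function(mol, m) .hasAcid(mol)),
  list(id = "role_alcohol", kind = "general",
       applies = function(mol) .hasHydroxyl(mol) && !.hasAcid(mol),
       build = function(mol) "The molecule has a role as an alcohol solvent.",
       pattern = "^The molecule has a role as an alcohol solvent\\.$",
       verify = function(mol, m) .hasHydroxyl(mol)),
  list(id = "role_amine", kind = "general",
       applies = .hasPrimaryAmine,
       build = function(mol) "The molecule has a role as a basic reagent.",
       pattern = "^The molecule has a role as a basic reagent\\.$",
       verify = function(mol, m) .hasPrimaryAmine(mol)),
  list(id = "role_halogenated", kind = "general",
       applies = function(mol) any(names(.HALOGEN_WORD) %in% atoms(mol)$element),
       build = function(mol) "The molecule has a role as a halogenated reagent.",
       pattern = "^The molecule has a role as a halogenated reagent\\.$",
       verify = function(mol, m) any(names(.HALOGEN_WORD) %in% atoms(mol)$element)),
  list(id = "role_hydrocarbon", kind = "general",
       applies = function(mol) all(atoms(mol)$element == "C"),
       build = function(mol) "The molecule has a role as a hydrocarbon feedstock.",
       pattern = "^The molecule has a role as a hydrocarbon feedstock\\.$",
       verify = function(mol, m) all(atoms(mol)$element == "C")),
  list(id = "organic_general", kind = "general",
       applies = function(mol) .hasElement(mol, "C"),
       build = function(mol) "The molecule is an organic compound.",
       pattern = "^The molecule is an organic compound\\.$",
       verify = function(mol, m) .hasElement(mol, "C"))
)

#' The sentence template registry
#'
#' Every description sentence the generator can emit comes from this
#' registry; each entry pairs a builder with a verification predicate so the
#' fact checker can prove emitted sentences true against the molecular
#' graph. A plain-text listing ships in
#' \code{system.file("extdata", "sentence_templates.tsv", package = "MolConverse")}.
#'
#' @return List of template entries (id, kind, pattern and functions).
#' @export
sentenceTemplates <- function() .TEMPLATES

#' Generate a verifiable molecule description
#'
#' Builds 2-6 sentences from the template registry: structural (fine)
#' sentences first, general-property sentences last, matching the
#' fine-to-general ordering of curated molecule-description corpora. No
#' sentence contains "-" and the molecule is only ever called "the
#' molecule".
#'
#' @param mol A \linkS4class{Molecule} (or SMILES string).
#' @param nSentences Number of sentences, between 2 and 6.
#' @param seed Integer seed.
#' @return A single description string (sentences joined by spaces).
#' @examples
#' genDescription(parseSmiles("CCO"), 3, seed = 7)
#' @export
genDescription <- function(mol, nSentences = 3L, seed = 1L) {
  if (is.character(mol)) mol <- parseSmiles(mol)
  stopifnot(nSentences >= 2L, nSentences <= 6L)
  .withSeed(seed, {
    fine <- Filter(function(t) t$kind == "fine" && t$applies(mol), .TEMPLATES)
    gen <- Filter(function(t) t$kind == "general" && t$applies(mol), .TEMPLATES)
    nGen <- max(1L, min(length(gen), nSentences - ceiling(nSentences / 2)))
    nFine <- min(length(fine), nSentences - nGen)
    nGen <- min(length(gen), nSentences - nFine)
    pick <- function(pool, k) {
      if (k <= 0L) return(list())
      pool[sort(sample(length(pool), k))]
    }
    chosen <- c(pick(fine, nFine), pick(gen, nGen))
    paste(vapply(chosen, function(t) t$build(mol), ""), collapse = " ")
  })
}

#' Check description sentences against the molecular graph
#'
#' Matches each sentence to its template and runs the template's
#' verification predicate on the molecule. Sentences that match no template
#' fail.
#'
#' @param description Description text (template-generated sentences).
#' @param mol A \linkS4class{Molecule} or SMILES string.
#' @return Named logical vector, one entry per sentence.
#' @export
factCheckDescription <- function(description, mol) {
  if (is.character(mol)) mol <- parseSmiles(mol)
  sentences <- splitSentences(description)
  vapply(sentences, function(s) {
    for (t in .TEMPLATES) {
      m <- regmatches(s, regexec(t$pattern, s))[[1]]
      if (length(m)) return(isTRUE(t$verify(mol, m)))
    }
    FALSE
  }, TRUE)
}

# ---- lexicon, properties, corpus -------------------------------------------

.NAME_STEMS <- c("vel", "dor", "mal", "zet", "quar", "fen", "lus", "tor",
                 "bex", "cal", "nim", "pra", "sil", "gro", "hul", "jas")
.NAME_SUFFIXES <- c("anox", "ilor", "umab", "etine", "oxal", "ivane",
                    "arune", "unex")

# Deterministic pseudo-name for molecule i; never appears in descriptions
# (descriptions only say "the molecule"), so synonym masking is exercised
# end to end.
.syntheticName <- function(i) {
  i <- i - 1L
  stem1 <- .NAME_STEMS[(i %% length(.NAME_STEMS)) + 1L]
  stem2 <- .NAME_STEMS[((i %/% length(.NAME_STEMS)) %% length(.NAME_STEMS)) + 1L]
  suf <- .NAME_SUFFIXES[((i %/% (length(.NAME_STEMS)^2)) %% length(.NAME_SUFFIXES)) + 1L]
  paste0(stem1, stem2, suf)
}

#' The experimental-property inventory
#'
#' Fifteen physical and chemical property types (solubility, color,
#' corrosivity and so on) used by the property table generator and the
#' property-knowledge pretraining task.
#'
#' @return Character vector of 15 property names.
#' @export
propertyInventory <- function() {
  c("solubility", "color", "corrosivity", "odor", "physical state",
    "melting point", "boiling point", "density", "flash point", "stability",
    "viscosity", "vapor pressure", "acidity", "flammability",
    "refractive index")
}

.PROPERTY_VALUES <- list(
  "solubility" = c("highly soluble in water", "slightly soluble in water",
                   "insoluble in water", "miscible with ethanol"),
  "color" = c("white", "colorless", "pale yellow", "light brown"),
  "corrosivity" = c("corrosive to metals", "noncorrosive",
                    "mildly corrosive to skin"),
  "odor" = c("odorless", "pungent", "sweet smelling", "fruity"),
  "physical state" = c("liquid at room temperature",
                       "solid at room temperature",
                       "gas at room temperature"),
  "melting point" = c("around 15 degrees Celsius",
                      "around 80 degrees Celsius",
                      "below zero degrees Celsius"),
  "boiling point" = c("around 78 degrees Celsius",
                      "around 120 degrees Celsius",
                      "above 200 degrees Celsius"),
  "density" = c("less dense than water", "denser than water",
                "about as dense as water"),
  "flash point" = c("around 13 degrees Celsius", "around 60 degrees Celsius",
                    "not flammable"),
  "stability" = c("stable under normal conditions",
                  "sensitive to light", "sensitive to air"),
  "viscosity" = c("low viscosity", "moderate viscosity", "high viscosity"),
  "vapor pressure" = c("high vapor pressure", "low vapor pressure"),
  "acidity" = c("weakly acidic", "weakly basic", "neutral"),
  "flammability" = c("highly flammable", "combustible", "not combustible"),
  "refractive index" = c("about 1.36", "about 1.42", "about 1.50")
)

#' Generate a synthetic molecule-description corpus
#'
#' Bundles molecules, verifiable descriptions, a synthetic name lexicon and
#' an experimental-property table (3-15 rows per molecule, drawn from the
#' 15-type property inventory). Bit-identical across runs for a fixed seed.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @return A \linkS4class{SyntheticCorpus}.
#' @examples
#' corp <- genCorpus(5, seed = 1)
#' corpusRecords(corp)$smiles
#' @export
genCorpus <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  smis <- genMolecules(n, seed = seed)
  .withSeed(seed + 1000003L, {
    ids <- sprintf("M%04d", seq_len(n))
    names <- vapply(seq_len(n), .syntheticName, "")
    descs <- character(n)
    props <- vector("list", n)
    inv <- propertyInventory()
    for (i in seq_len(n)) {
      nSent <- sample(2:6, 1L)
      descs[i] <- genDescription(smis[i], nSent, seed = sample.int(1e6, 1L))
      nProp <- sample(3:15, 1L)
      pnames <- sample(inv, nProp)
      pvals <- vapply(pnames, function(p) sample(.PROPERTY_VALUES[[p]], 1L), "")
      props[[i]] <- data.frame(moleculeId = ids[i], property = pnames,
                               value = pvals, stringsAsFactors = FALSE,
                               row.names = NULL)
    }
    new("SyntheticCorpus",
        records = data.frame(moleculeId = ids, smiles = smis, name = names,
                             description = descs, stringsAsFactors = FALSE),
        lexicon = stats::setNames(smis, names),
        propertyTable = do.call(rbind, props),
        seed = as.integer(seed))
  })
}

#' @rdname SyntheticCorpus-class
#' @export
setMethod("corpusRecords", "SyntheticCorpus", function(x) x@records)

#' @rdname SyntheticCorpus-class
#' @export
setMethod("corpusLexicon", "SyntheticCorpus", function(x) x@lexicon)

#' @rdname SyntheticCorpus-class
#' @export
setMethod("propertyTable", "SyntheticCorpus", function(x) x@propertyTable)

setMethod("show", "SyntheticCorpus", function(object) {
  cat("SyntheticCorpus:", nrow(object@records), "records,",
      length(object@lexicon), "lexicon entries,",
      nrow(object@propertyTable), "property rows (seed",
      object@seed, ")\n")
})

#' Write a corpus to disk (JSONL records, TSV lexicon and properties)
#'
#' @param corpus A \linkS4class{SyntheticCorpus}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeJsonl(corpus@records, file.path(dir, "corpus.jsonl"))
  .writeTsv(data.frame(name = names(corpus@lexicon),
                       smiles = unname(corpus@lexicon),
                       stringsAsFactors = FALSE),
            file.path(dir, "lexicon.tsv"))
  .writeTsv(corpus@propertyTable, file.path(dir, "properties.tsv"))
  writeLines(as.character(corpus@seed), file.path(dir, "seed.txt"))
  invisible(dir)
}

#' Read a corpus written by [writeCorpus()]
#'
#' @param dir Directory containing corpus.jsonl, lexicon.tsv, properties.tsv.
#' @return A \linkS4class{SyntheticCorpus}.
#' @export
readCorpus <- function(dir) {
  recs <- readJsonl(file.path(dir, "corpus.jsonl"))
  records <- do.call(rbind, lapply(recs, function(r) {
    data.frame(moleculeId = r$moleculeId, smiles = r$smiles, name = r$name,
               description = r$description, stringsAsFactors = FALSE)
  }))
  lex <- .readTsv(file.path(dir, "lexicon.tsv"))
  seedPath <- file.path(dir, "seed.txt")
  seed <- if (file.exists(seedPath)) as.integer(readLines(seedPath)[1]) else NA_integer_
  new("SyntheticCorpus",
      records = records,
      lexicon = stats::setNames(lex$smiles, lex$name),
      propertyTable = .readTsv(file.path(dir, "properties.tsv")),
      seed = seed)
}
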