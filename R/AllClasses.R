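#' @import methods
NULL

#' Molecule: a SMILES string with its parsed graph
#'
#' Holds the input SMILES, its canonical form, and the heavy-atom graph:
#' atoms in parse order (0-based indices, element symbol, aromatic flag,
#' formal charge), bonds with order single/double/triple/aromatic, and the
#' smallest set of smallest rings as 0-based atom-index vectors.
#'
#' @slot smiles Input SMILES string.
#' @slot canonicalSmiles Canonical SMILES (OpenBabel canonical form).
#' @slot atoms data.frame with columns index, element, aromatic, charge.
#' @slot bonds data.frame with columns i, j, order.
#' @slot rings list of integer vectors (0-based atom indices per ring).
#' @seealso [parseSmiles()], [atomEnvironment()]
#' @exportClass Molecule
setClass("Molecule", representation(
  smiles = "character",
  canonicalSmiles = "character",
  atoms = "data.frame",
  bonds = "data.frame",
  rings = "list"
))

setValidity("Molecule", function(object) {
  msgs <- character(0)
  a <- object@atoms
  b <- object@bonds
  if (nrow(a) == 0L) msgs <- c(msgs, "no atoms")
  if (nrow(a) && !identical(a$index, seq_len(nrow(a)) - 1L)) {
    msgs <- c(msgs, "atom indices must be 0..n-1 in parse order")
  }
  if (nrow(b)) {
    if (any(b$i < 0L | b$j < 0L | b$i >= nrow(a) | b$j >= nrow(a))) {
      msgs <- c(msgs, "bond endpoint out of range")
    }
    if (!all(b$order %in% c("single", "double", "triple", "aromatic"))) {
      msgs <- c(msgs, "unknown bond order")
    }
  }
  for (r in object@rings) {
    if (length(r) < 3L) msgs <- c(msgs, "ring smaller than 3 atoms")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fingerprint: a binary substructure descriptor as a bit set
#'
#' @slot scheme One of "path" (OpenBabel FP2, linear fragments up to 7
#'   atoms), "maccs" (MACCS keys) or "morgan" (ECFP4, circular radius 2).
#' @slot bits Sorted integer vector of set bit positions (0-based).
#' @slot nBits Total width of the bit space.
#' @seealso [molFingerprint()], [tanimoto()]
#' @exportClass Fingerprint
setClass("Fingerprint", representation(
  scheme = "character",
  bits = "integer",
  nBits = "integer"
))

setValidity("Fingerprint", function(object) {
  msgs <- character(0)
  if (!object@scheme %in% c("path", "maccs", "morgan")) {
    msgs <- c(msgs, "scheme must be path/maccs/morgan")
  }
  if (length(object@bits) && (any(object@bits < 0L) ||
                              any(object@bits >= object@nBits))) {
    msgs <- c(msgs, "bit index outside [0, nBits)")
  }
  if (is.unsorted(object@bits, strictly = TRUE) && length(object@bits) > 1L) {
    msgs <- c(msgs, "bits must be strictly increasing")
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticCorpus: molecule-description records with known ground truth
#'
#' A generated parallel corpus in the style of public molecule-description
#' datasets: each record pairs a SMILES with a multi-sentence description in
#' which every stated fact is derivable from the molecular graph. The corpus
#' carries a synthetic name lexicon and an experimental-property table
#' consistent with the molecules.
#'
#' @slot records data.frame with columns moleculeId, smiles, name,
#'   description.
#' @slot lexicon named character vector mapping synthetic name -> SMILES.
#' @slot propertyTable data.frame with columns moleculeId, property, value.
#' @slot seed Integer seed the corpus was generated from.
#' @seealso [genCorpus()]
#' @exportClass SyntheticCorpus
setClass("SyntheticCorpus", representation(
  records = "data.frame",
  lexicon = "character",
  propertyTable = "data.frame",
  seed = "integer"
))

setValidity("SyntheticCorpus", function(object) {
  msgs <- character(0)
  need <- c("moleculeId", "smiles", "name", "description")
  if (!all(need %in% names(object@records))) {
    msgs <- c(msgs, "records must have moleculeId/smiles/name/description")
  }
  if (is.null(names(object@lexicon)) && length(object@lexicon)) {
    msgs <- c(msgs, "lexicon must be a named character vector")
  }
  if (!all(c("moleculeId", "property", "value") %in% names(object@propertyTable))) {
    msgs <- c(msgs, "propertyTable must have moleculeId/property/value")
  }
  if (length(msgs)) msgs else TRUE
})

#' Dialogue: a multi-turn molecule-design conversation
#'
#' Turns carry cumulative description text (sentences accumulated in reversed
#' description order, so detail increases over turns) and the expected
#' molecule per turn; the final turn's molecule is the source molecule.
#'
#' @slot dialogueId Identifier of the source record.
#' @slot sentences Character vector of sentences in turn order.
#' @slot turns data.frame with columns k, text (cumulative), expectedSmiles.
#' @slot finalSmiles SMILES of the final answer molecule.
#' @seealso [buildDialogue()]
#' @exportClass Dialogue
setClass("Dialogue", representation(
  dialogueId = "character",
  sentences = "character",
  turns = "data.frame",
  finalSmiles = "character"
))

setValidity("Dialogue", function(object) {
  msgs <- character(0)
  t <- object@turns
  if (nrow(t) < 2L) msgs <- c(msgs, "a dialogue needs at least 2 turns")
  if (!all(c("k", "text", "expectedSmiles") %in% names(t))) {
    msgs <- c(msgs, "turns must have k/text/expectedSmiles")
  }
  if (nrow(t) >= 2L && !identical(t$k, seq_len(nrow(t)))) {
    msgs <- c(msgs, "turn indices must be 1..n")
  }
  if (nrow(t) && t$expectedSmiles[nrow(t)] != object@finalSmiles) {
    msgs <- c(msgs, "last turn's expected molecule must equal finalSmiles")
  }
  if (any(grepl("-", object@sentences, fixed = TRUE))) {
    msgs <- c(msgs, "sentences must not contain '-'")
  }
  if (length(msgs)) msgs else TRUE
})

#' EvalReport: per-item metrics and their aggregate means
#'
#' @slot task "understanding" or "generation".
#' @slot perItem data.frame of per-item metric values.
#' @slot aggregate Named numeric vector of column means.
#' @slot nItems Number of scored items.
#' @seealso [evaluatePredictions()]
#' @exportClass EvalReport
setClass("EvalReport", representation(
  task = "character",
  perItem = "data.frame",
  aggregate = "numeric",
  nItems = "integer"
))

setValidity("EvalReport", function(object) {
  msgs <- character(0)
  if (!object@task %in% c("understanding", "generation")) {
    msgs <- c(msgs, "task must be understanding/generation")
  }
  if (object@nItems != nrow(object@perItem)) {
    msgs <- c(msgs, "nItems must match perItem rows")
  }
  if (object@task == "generation" && all(c("em", "hit3") %in% names(object@aggregate))) {
    if (object@aggregate[["em"]] > object@aggregate[["hit3"]] + 1e-12) {
      msgs <- c(msgs, "exact match cannot exceed hit@3")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ConverseModel: twin encoder-decoder sequence-to-sequence model
#'
#' Two independent GRU encoder-decoder parameter sets over a shared joint
#' vocabulary: the molecule route decodes SMILES, the text route decodes
#' natural-language descriptions. Routing is by target language.
#'
#' @slot config List of model hyperparameters (hidden size, layers, maxLen,
#'   seed, vocabulary).
#' @slot molRoute List of parameter matrices for the molecule-out route.
#' @slot textRoute List of parameter matrices for the text-out route.
#' @slot trainState List with step counter, per-task running losses and the
#'   loss trajectory.
#' @seealso [converseModel()], [pretrainModel()], [generateMolecules()]
#' @exportClass ConverseModel
setClass("ConverseModel", representation(
  config = "list",
  molRoute = "list",
  textRoute = "list",
  trainState = "list"
))
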