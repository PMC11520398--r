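# Retrieval-augmented prompting: annotate chemical names in the input text
# with their SMILES from a local lexicon and append them as hints, after
# forcefully removing any SMILES that is (structurally) the same molecule as
# an answer -- otherwise the hint would leak the answer.

#' Annotate chemical entities in text
#'
#' Longest-match, non-overlapping lexicon lookup; annotations are returned
#' in textual order.
#'
#' @param text Input text.
#' @param lexicon Named character vector name -> SMILES.
#' @return data.frame with columns name, smiles, start, end (character
#'   offsets, 1-based inclusive).
#' @export
annotateEntities <- function(text, lexicon) {
  stopifnot(length(lexicon) > 0L)
  ents <- .detectEntities(text, lexicon)
  if (!length(ents)) {
    return(data.frame(name = character(0), smiles = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(ents, function(e) {
    data.frame(name = e$name, smiles = e$smiles, start = e$start,
               end = e$end, stringsAsFactors = FALSE)
  }))
}

#' Build a prompted model input with leakage removal
#'
#' Drops every annotation whose canonical SMILES equals the canonical form
#' of any answer molecule (structural, not string, equality), then appends
#' the surviving hints as a trailing block
#' \code{"Known molecules: name1: SMILES1; ..."}.
#'
#' @param text Input text.
#' @param annotations data.frame from [annotateEntities()].
#' @param answers Character vector of answer SMILES (may be empty).
#' @return List with \code{text}, \code{annotations} (the surviving rows)
#'   and \code{prompt} (the final model input).
#' @examples
#' lex <- c(ethanol = "OCC")
#' ann <- annotateEntities("Mix ethanol with water.", lex)
#' buildPrompt("Mix ethanol with water.", ann, answers = "CCO")$prompt
#' @export
buildPrompt <- function(text, annotations, answers = character(0)) {
  keep <- annotations
  if (nrow(annotations) && length(answers)) {
    ansCan <- unique(canonicalSmilesOrNA(answers))
    ansCan <- ansCan[!is.na(ansCan)]
    annCan <- canonicalSmilesOrNA(annotations$smiles)
    keep <- annotations[is.na(annCan) | !(annCan %in% ansCan), , drop = FALSE]
  }
  prompt <- if (nrow(keep)) {
    paste0(text, " Known molecules: ",
           paste(sprintf("%s: %s", keep$name, keep$smiles), collapse = "; "),
           ".")
  } else text
  list(text = text, annotations = keep, prompt = prompt)
}

#' Prompt every turn of a dialogue set
#'
#' For each turn the answers are the dialogue's expected molecules (all
#' turns) and its final molecule, so no hint can reveal any of them.
#'
#' @param dialogues List of \linkS4class{Dialogue} objects.
#' @param lexicon Named character vector name -> SMILES.
#' @return data.frame with dialogueId, k, prompt, nHints.
#' @export
promptDialogues <- function(dialogues, lexicon) {
  rows <- lapply(dialogues, function(d) {
    answers <- unique(c(d@turns$expectedSmiles, d@finalSmiles))
    do.call(rbind, lapply(seq_len(nrow(d@turns)), function(k) {
      ann <- annotateEntities(d@turns$text[k], lexicon)
      p <- buildPrompt(d@turns$text[k], ann, answers)
      data.frame(dialogueId = d@dialogueId, k = k, prompt = p$prompt,
                 nHints = nrow(p$annotations), stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
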