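# Tokenization: atom-level SMILES tokens and lowercased word tokens for
# natural language. Shared by the masking task, the candidate generator and
# the seq2seq model.

.SMILES_TOKEN_RE <- paste0(
  "(\\[[^\\]]+\\]",          # bracket atoms as single tokens
  "|Cl|Br",                  # two-letter organic-subset elements
  "|[BCNOPSFI]",             # one-letter organic subset
  "|[bcnops]",               # aromatic atoms
  "|%[0-9]{2}",              # two-digit ring closures
  "|[0-9]",                  # ring digits
  "|[-=#:()./\\\\+@]",       # bonds, branches, misc
  ")"
)

#' Tokenize a SMILES string at the atom level
#'
#' Bracket atoms, two-letter elements and two-digit ring closures are kept
#' whole, so masking or decoding never splits an atom symbol.
#'
#' @param smiles A SMILES string.
#' @return Character vector of tokens; concatenating them restores the
#'   input.
#' @examples
#' smilesTokens("Clc1ccccc1")  # "Cl" stays one token
#' @export
smilesTokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  m <- gregexpr(.SMILES_TOKEN_RE, smiles)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  if (paste(toks, collapse = "") != smiles) {
    .invalidSmiles(smiles, "untokenizable characters")
  }
  toks
}

#' Tokenize natural-language text into words
#'
#' Lowercases and splits into word and punctuation tokens. Used for text
#' metrics and the text side of the model.
#'
#' @param text A character string.
#' @param lower Lowercase first? Default TRUE.
#' @return Character vector of tokens.
#' @export
wordTokens <- function(text, lower = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (lower) text <- tolower(text)
  toks <- regmatches(text, gregexpr("[A-Za-z0-9']+|[.,;:!?()]", text))[[1]]
  toks
}

# Tokenizes model input text that may embed SMILES: words that consist only
# of SMILES alphabet characters, contain no lowercase vowel and parse as a
# molecule of >= 2 atoms are split atom-level; everything else is a word
# token. Deterministic and reversible enough for the toy corpus.
.mixedTokens <- function(text) {
  pieces <- strsplit(text, " ", fixed = TRUE)[[1]]
  out <- character(0)
  for (p in pieces) {
    if (!nzchar(p)) next
    core <- sub("[.,;]$", "", p)
    trail <- if (nchar(core) < nchar(p)) substr(p, nchar(p), nchar(p)) else NULL
    looksSmiles <- nzchar(core) &&
      !grepl("[aeiu]", core) &&
      grepl("^[A-Za-z0-9()\\[\\]=#%@+./\\\\-]+$", core) &&
      nchar(core) >= 2L &&
      isValidSmiles(core)
    if (looksSmiles) {
      out <- c(out, smilesTokens(core), trail)
    } else {
      out <- c(out, wordTokens(p))
    }
  }
  out
}
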