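#' @rdname Molecule-class
#' @param x,object An object.
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))

#' @rdname Molecule-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname Molecule-class
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname Molecule-class
#' @export
setGeneric("rings", function(x) standardGeneric("rings"))

#' Canonical SMILES
#'
#' Canonicalizes SMILES so that graph-isomorphic writings map to one string;
#' the basis for exact-match scoring and leakage checks. Idempotent.
#'
#' @param x A SMILES character vector or a \linkS4class{Molecule}.
#' @return Character vector of canonical SMILES.
#' @examples
#' canonicalSmiles(c("OCC", "CCO"))  # identical outputs
#' @export
setGeneric("canonicalSmiles", function(x) standardGeneric("canonicalSmiles"))

#' Molecular fingerprints
#'
#' @param x A \linkS4class{Molecule} or SMILES string.
#' @param scheme "path" (linear fragments up to 7 atoms, OpenBabel FP2),
#'   "maccs" (MACCS keys) or "morgan" (circular, radius 2 / ECFP4).
#' @return A \linkS4class{Fingerprint}.
#' @export
setGeneric("molFingerprint", function(x, scheme = c("path", "maccs", "morgan"))
  standardGeneric("molFingerprint"))

#' Tanimoto similarity between two fingerprints
#'
#' @param a,b \linkS4class{Fingerprint} objects with the same scheme.
#' @return Similarity |A&B| / |A|B| in [0, 1]. Two empty fingerprints give
#'   0 with a warning.
#' @export
setGeneric("tanimoto", function(a, b) standardGeneric("tanimoto"))

#' @rdname SyntheticCorpus-class
#' @export
setGeneric("corpusRecords", function(x) standardGeneric("corpusRecords"))

#' @rdname SyntheticCorpus-class
#' @export
setGeneric("corpusLexicon", function(x) standardGeneric("corpusLexicon"))

#' @rdname SyntheticCorpus-class
#' @export
setGeneric("propertyTable", function(x) standardGeneric("propertyTable"))

#' @rdname Dialogue-class
#' @export
setGeneric("dialogueTurns", function(x) standardGeneric("dialogueTurns"))

#' @rdname Dialogue-class
#' @export
setGeneric("finalSmiles", function(x) standardGeneric("finalSmiles"))

#' @rdname EvalReport-class
#' @export
setGeneric("aggregateMetrics", function(x) standardGeneric("aggregateMetrics"))

#' @rdname EvalReport-class
#' @export
setGeneric("perItemMetrics", function(x) standardGeneric("perItemMetrics"))
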