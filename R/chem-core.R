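# Molecular parsing, canonicalization, fingerprints and similarity.
# Canonical SMILES and all fingerprint schemes are delegated to OpenBabel
# through ChemmineOB; the graph itself (and strict validity) comes from the
# package's own reader in smiles-parse.R because OpenBabel silently repairs
# malformed input.

.chemCache <- new.env(parent = emptyenv())

#' Parse a SMILES string into a Molecule
#'
#' Reads the heavy-atom graph in parse order, perceives aromaticity for
#' Kekule-written six-membered C/N rings, and computes the smallest set of
#' smallest rings. Hydrogens are implicit; atom indices are 0-based over
#' heavy atoms in parse order. Invalid input signals an error of class
#' \code{invalidSmilesError} carrying the offending string in
#' \code{$smiles}.
#'
#' @param smiles A single SMILES string.
#' @return A \linkS4class{Molecule}.
#' @examples
#' mol <- parseSmiles("c1ccccc1O")  # phenol
#' nrow(atoms(mol))                 # 7 heavy atoms
#' rings(mol)                       # one 6-ring
#' @export
parseSmiles <- function(smiles) {
  g <- .smilesToGraph(smiles)
  rings <- .sssr(nrow(g$atoms), g$bonds)
  ar <- .perceiveAromaticity(g$atoms, g$bonds, rings)
  can <- .obCanonical(smiles)
  if (is.na(can)) .invalidSmiles(smiles, "toolkit cannot canonicalize")
  new("Molecule",
      smiles = smiles,
      canonicalSmiles = can,
      atoms = ar$atoms, bonds = ar$bonds, rings = rings)
}

#' Is a SMILES string valid?
#'
#' Valid means the package parser accepts it and the chemistry toolkit can
#' canonicalize it (which excludes, e.g., aromatic rings that cannot be
#' kekulized).
#'
#' @param smiles Character vector of candidate SMILES.
#' @return Logical vector.
#' @export
isValidSmiles <- function(smiles) {
  parseOk <- vapply(smiles, function(s) {
    !inherits(tryCatch(.smilesToGraph(s), invalidSmilesError = function(e) e),
              "invalidSmilesError")
  }, logical(1), USE.NAMES = FALSE)
  if (any(parseOk)) {
    parseOk[parseOk] <- !is.na(suppressWarnings(.obCanonical(smiles[parseOk])))
  }
  parseOk
}

# Batched, cached OpenBabel canonicalization. Molecules OpenBabel cannot
# process (e.g. aromatic rings that fail kekulization) yield NA; when a
# batch comes back misaligned the members are converted one by one.
.obCanonical <- function(smiles) {
  if (!length(smiles)) return(character(0))
  key <- paste0("can\r", smiles)
  hit <- vapply(key, exists, TRUE, envir = .chemCache, USE.NAMES = FALSE)
  if (any(!hit)) {
    todo <- unique(smiles[!hit])
    convert <- function(x) {
      out <- ChemmineOB::convertFormat("SMI", "CAN",
                                       paste(x, collapse = "\n"))
      lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
      lines <- sub("[\t ]+$", "", lines)
      lines[nzchar(lines)]
    }
    lines <- convert(todo)
    if (length(lines) != length(todo)) {
      lines <- vapply(todo, function(s) {
        one <- convert(s)
        if (length(one) == 1L) one else NA_character_
      }, "", USE.NAMES = FALSE)
    }
    for (k in seq_along(todo)) {
      assign(paste0("can\r", todo[k]), lines[k], envir = .chemCache)
    }
  }
  vapply(key, get, "", envir = .chemCache, USE.NAMES = FALSE)
}

#' @rdname canonicalSmiles
#' @export
setMethod("canonicalSmiles", "character", function(x) {
  ok <- isValidSmiles(x)
  if (any(!ok)) .invalidSmiles(x[!ok][1], "cannot canonicalize")
  .obCanonical(x)
})

#' @rdname canonicalSmiles
#' @export
setMethod("canonicalSmiles", "Molecule", function(x) x@canonicalSmiles)

#' Canonicalize predicted SMILES, tolerating invalid strings
#'
#' @param x Character vector; entries that do not parse yield NA rather than
#'   an error (model predictions may be malformed).
#' @return Character vector with NA for invalid entries.
#' @export
canonicalSmilesOrNA <- function(x) {
  ok <- isValidSmiles(x)
  out <- rep(NA_character_, length(x))
  if (any(ok)) out[ok] <- .obCanonical(x[ok])
  out
}

#' @rdname Molecule-class
#' @export
setMethod("smiles", "Molecule", function(x) x@smiles)

#' @rdname Molecule-class
#' @export
setMethod("atoms", "Molecule", function(x) x@atoms)

#' @rdname Molecule-class
#' @export
setMethod("bonds", "Molecule", function(x) x@bonds)

#' @rdname Molecule-class
#' @export
setMethod("rings", "Molecule", function(x) x@rings)

setMethod("show", "Molecule", function(object) {
  cat("Molecule:", object@smiles, "\n",
      " canonical:", object@canonicalSmiles, "\n",
      " ", nrow(object@atoms), "heavy atoms,", nrow(object@bonds), "bonds,",
      length(object@rings), "ring(s)\n")
})

.FP_OB_NAME <- c(path = "FP2", maccs = "MACCS", morgan = "ECFP4")

# Batched, cached fingerprint bit sets. Keyed by canonical SMILES so that
# alternative writings of one graph share an entry (and provably share bits).
.fingerprintBits <- function(smiles, scheme) {
  can <- .obCanonical(smiles)
  key <- paste0("fp:", scheme, "\r", can)
  hit <- vapply(key, exists, TRUE, envir = .chemCache, USE.NAMES = FALSE)
  if (any(!hit)) {
    todo <- unique(can[!hit])
    mols <- ChemmineOB::forEachMol("SMILES", paste(todo, collapse = "\n"),
                                   identity)
    m <- ChemmineOB::fingerprint_OB(mols, .FP_OB_NAME[[scheme]])
    if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
    if (nrow(m) != length(todo)) stop("fingerprint batch size mismatch")
    for (k in seq_along(todo)) {
      assign(paste0("fp:", scheme, "\r", todo[k]),
             list(bits = which(m[k, ] != 0) - 1L, nBits = ncol(m)),
             envir = .chemCache)
    }
  }
  lapply(key, get, envir = .chemCache)
}

#' @rdname molFingerprint
#' @export
setMethod("molFingerprint", "Molecule", function(x, scheme = c("path", "maccs", "morgan")) {
  scheme <- match.arg(scheme)
  b <- .fingerprintBits(x@canonicalSmiles, scheme)[[1]]
  new("Fingerprint", scheme = scheme, bits = as.integer(b$bits),
      nBits = as.integer(b$nBits))
})

#' @rdname molFingerprint
#' @export
setMethod("molFingerprint", "character", function(x, scheme = c("path", "maccs", "morgan")) {
  scheme <- match.arg(scheme)
  ok <- isValidSmiles(x[1])
  if (!ok) .invalidSmiles(x[1], "cannot fingerprint")
  b <- .fingerprintBits(x[1], scheme)[[1]]
  new("Fingerprint", scheme = scheme, bits = as.integer(b$bits),
      nBits = as.integer(b$nBits))
})

setMethod("show", "Fingerprint", function(object) {
  cat("Fingerprint[", object@scheme, "]: ", length(object@bits), "/",
      object@nBits, " bits set\n", sep = "")
})

#' @rdname tanimoto
#' @export
setMethod("tanimoto", signature("Fingerprint", "Fingerprint"), function(a, b) {
  if (a@scheme != b@scheme) {
    stop("fingerprint scheme mismatch: ", a@scheme, " vs ", b@scheme)
  }
  .tanimotoBits(a@bits, b@bits)
})

.tanimotoBits <- function(x, y) {
  if (!length(x) && !length(y)) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  inter <- length(intersect(x, y))
  inter / (length(x) + length(y) - inter)
}

#' Pairwise Tanimoto of many SMILES against one reference
#'
#' Batched helper used by the dialogue-builder similarity gate.
#'
#' @param smiles Character vector of valid SMILES.
#' @param ref A single reference SMILES.
#' @param scheme Fingerprint scheme (default "path", the gate's scheme).
#' @return Numeric vector of similarities in [0, 1].
#' @export
tanimotoToRef <- function(smiles, ref, scheme = c("path", "maccs", "morgan")) {
  scheme <- match.arg(scheme)
  bits <- .fingerprintBits(c(ref, smiles), scheme)
  refbits <- bits[[1]]$bits
  vapply(bits[-1], function(b) .tanimotoBits(b$bits, refbits), 0)
}

#' Atom environment query
#'
#' Reports the bonded neighbours, aromaticity and ring membership of one
#' atom; the source of truth for the spatial-structure pretraining task.
#'
#' @param mol A \linkS4class{Molecule}.
#' @param atomIndex 0-based heavy-atom index in parse order.
#' @return List with \code{neighbors} (data.frame index/element in ascending
#'   index order), \code{aromatic} flag, and ascending \code{ringSizes} of
#'   the rings containing the atom.
#' @examples
#' atomEnvironment(parseSmiles("CCO"), 2L)  # the oxygen: one C neighbour
#' @export
atomEnvironment <- function(mol, atomIndex) {
  stopifnot(is(mol, "Molecule"))
  n <- nrow(mol@atoms)
  if (!is.numeric(atomIndex) || length(atomIndex) != 1L ||
      atomIndex < 0 || atomIndex >= n) {
    stop("atomIndex out of range [0, ", n - 1L, "]")
  }
  atomIndex <- as.integer(atomIndex)
  b <- mol@bonds
  nb <- sort(c(b$j[b$i == atomIndex], b$i[b$j == atomIndex]))
  list(
    neighbors = data.frame(
      index = nb,
      element = mol@atoms$element[nb + 1L],
      stringsAsFactors = FALSE
    ),
    aromatic = mol@atoms$aromatic[atomIndex + 1L],
    ringSizes = sort(lengths(Filter(function(r) atomIndex %in% r, mol@rings)))
  )
}
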