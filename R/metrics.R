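# Evaluation suite for molecule understanding (text metrics) and molecule
# generation (exact match / hit@3 on canonical SMILES, character-level
# BLEU, Levenshtein distance, and fingerprint Tanimoto similarities).

# ---- n-gram machinery -------------------------------------------------------

.ngrams <- function(tokens, n) {
  len <- length(tokens)
  if (len < n) return(character(0))
  vapply(seq_len(len - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = "\r")
  }, "")
}

.clippedMatches <- function(predNg, refNg) {
  if (!length(predNg)) return(0L)
  pt <- table(predNg)
  rt <- table(refNg)
  shared <- intersect(names(pt), names(rt))
  sum(pmin(pt[shared], rt[shared]))
}

# BLEU over token vectors: geometric mean of clipped n-gram precisions up
# to maxN (capped by the hypothesis length so identical short pairs score
# 1), with the standard brevity penalty. smooth = "floor" replaces a zero
# precision by 0.5 / (number of hypothesis n-grams), the usual small-text
# smoothing; smooth = "none" lets any zero precision zero the score.
.bleu <- function(pred, ref, maxN = 4L, smooth = c("floor", "none")) {
  smooth <- match.arg(smooth)
  c_len <- length(pred)
  r_len <- length(ref)
  if (c_len == 0L || r_len == 0L) return(0)
  effN <- max(1L, min(maxN, c_len, r_len))
  logp <- numeric(effN)
  for (n in seq_len(effN)) {
    png <- .ngrams(pred, n)
    m <- .clippedMatches(png, .ngrams(ref, n))
    p <- if (m > 0L) m / length(png)
      else if (smooth == "floor") 0.5 / length(png)
      else return(0)
    logp[n] <- log(p)
  }
  bp <- if (c_len < r_len) exp(1 - r_len / c_len) else 1
  bp * exp(mean(logp))
}

.rougeN <- function(pred, ref, n) {
  png <- .ngrams(pred, n)
  rng <- .ngrams(ref, n)
  if (!length(png) || !length(rng)) return(0)
  m <- .clippedMatches(png, rng)
  p <- m / length(png)
  r <- m / length(rng)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

.lcsLength <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (!la || !lb) return(0L)
  prev <- integer(lb + 1L)
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    for (j in seq_len(lb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
        else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[lb + 1L]
}

.rougeL <- function(pred, ref) {
  if (!length(pred) || !length(ref)) return(0)
  l <- .lcsLength(pred, ref)
  p <- l / length(pred)
  r <- l / length(ref)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# METEOR, exact-matching variant (no synonym resource): one-to-one unigram
# alignment, harmonic mean weighted toward recall (alpha = 0.9), and a
# fragmentation penalty 0.5 * ((chunks - 1) / matches)^3. Counting breaks
# (chunks - 1) rather than chunks keeps a verbatim match at exactly 1.
.meteor <- function(pred, ref) {
  if (!length(pred) || !length(ref)) return(0)
  refAvail <- seq_along(ref)
  align <- integer(0)  # ref position matched by each matched pred position
  predPos <- integer(0)
  for (i in seq_along(pred)) {
    hit <- refAvail[ref[refAvail] == pred[i]]
    if (length(hit)) {
      align <- c(align, hit[1])
      predPos <- c(predPos, i)
      refAvail <- setdiff(refAvail, hit[1])
    }
  }
  m <- length(align)
  if (m == 0L) return(0)
  p <- m / length(pred)
  r <- m / length(ref)
  fmean <- p * r / (0.9 * p + 0.1 * r)
  chunks <- 1L + sum(diff(predPos) != 1L | diff(align) != 1L)
  penalty <- 0.5 * ((chunks - 1L) / m)^3
  fmean * (1 - penalty)
}

# ---- public pairwise metrics ------------------------------------------------

#' Levenshtein distance between two strings
#'
#' Minimal number of unit-cost insertions, deletions and substitutions,
#' computed on the raw strings.
#'
#' @param pred,gold Character strings.
#' @return Non-negative integer distance.
#' @export
levenshtein <- function(pred, gold) {
  as.integer(utils::adist(pred, gold)[1, 1])
}

#' Character-level BLEU between two SMILES strings
#'
#' BLEU up to 4-grams over characters with the standard brevity penalty; no
#' smoothing, so disjoint strings score 0 and identical strings score 1.
#'
#' @param pred,gold SMILES strings (any strings are accepted).
#' @return Score in [0, 1].
#' @export
smilesBleu <- function(pred, gold) {
  .bleu(strsplit(pred, "")[[1]], strsplit(gold, "")[[1]], maxN = 4L,
        smooth = "none")
}

#' Exact-match and hit@3 for a ranked molecule prediction
#'
#' Matches are on canonical SMILES; unparseable predictions never match.
#'
#' @param top3 Ordered character vector of up to 3 predicted SMILES.
#' @param gold Gold SMILES (must parse).
#' @return Named integer vector c(em = 0/1, hit3 = 0/1).
#' @examples
#' exactMatch(c("OCC", "C", "CC"), "CCO")  # em 1 (OCC is ethanol too)
#' @export
exactMatch <- function(top3, gold) {
  stopifnot(length(top3) >= 1L)
  goldCan <- canonicalSmiles(gold)
  predCan <- canonicalSmilesOrNA(utils::head(top3, 3L))
  hits <- !is.na(predCan) & predCan == goldCan
  c(em = as.integer(hits[1]), hit3 = as.integer(any(hits)))
}

#' Fingerprint Tanimoto similarity between predicted and gold molecules
#'
#' @param pred Predicted SMILES; unparseable predictions score 0.
#' @param gold Gold SMILES (must parse).
#' @param scheme "path", "maccs" or "morgan".
#' @return Similarity in [0, 1].
#' @export
fts <- function(pred, gold, scheme = c("path", "maccs", "morgan")) {
  scheme <- match.arg(scheme)
  if (!isValidSmiles(gold)) .invalidSmiles(gold, "gold molecule")
  if (!isValidSmiles(pred)) return(0)
  tanimoto(molFingerprint(pred, scheme), molFingerprint(gold, scheme))
}

#' Text-generation metrics for molecule understanding
#'
#' Word-tokenized (lowercased) BLEU-2 and BLEU-4 with small-text smoothing,
#' ROUGE-1/2 and ROUGE-L F-scores, and METEOR in its exact-matching variant
#' (no synonym dictionary; recorded in the result as
#' \code{attr(,"meteorMatching")}).
#'
#' @param pred,gold Text strings.
#' @return Named numeric vector bleu2/bleu4/rouge1/rouge2/rougeL/meteor,
#'   all in [0, 1].
#' @export
textMetrics <- function(pred, gold) {
  p <- wordTokens(pred)
  g <- wordTokens(gold)
  out <- c(
    bleu2 = .bleu(p, g, maxN = 2L, smooth = "floor"),
    bleu4 = .bleu(p, g, maxN = 4L, smooth = "floor"),
    rouge1 = .rougeN(p, g, 1L),
    rouge2 = .rougeN(p, g, 2L),
    rougeL = .rougeL(p, g),
    meteor = .meteor(p, g)
  )
  attr(out, "meteorMatching") <- "exact"
  out
}

# ---- aggregation ------------------------------------------------------------

.GEN_COLS <- c(em = "EM", hit3 = "hit@3", bleu = "BL", leven = "Leven",
               rdk = "RDK", mac = "MAC", morgan = "Morgan")
.UND_COLS <- c(bleu2 = "BL-2", bleu4 = "BL-4", rouge1 = "RG-1",
               rouge2 = "RG-2", rougeL = "RG-L", meteor = "MET")

#' Score a set of predictions
#'
#' Generation items need \code{itemId}, \code{top3} (ordered SMILES) and
#' \code{gold}; BLEU, Levenshtein and the three fingerprint similarities
#' are computed on the rank-1 prediction. Understanding items need
#' \code{itemId}, \code{text} and \code{gold}.
#'
#' @param predictions List of per-item lists (see above).
#' @param task "generation" or "understanding".
#' @return An \linkS4class{EvalReport}; aggregates are per-item means.
#' @export
evaluatePredictions <- function(predictions,
                                task = c("generation", "understanding")) {
  task <- match.arg(task)
  stopifnot(length(predictions) >= 1L)
  rows <- lapply(predictions, function(p) {
    if (is.null(p$itemId) || is.null(p$gold)) {
      stop("prediction item missing itemId or gold")
    }
    if (task == "generation") {
      if (is.null(p$top3) || !length(p$top3)) stop("generation item missing top3")
      top1 <- p$top3[1]
      m <- exactMatch(p$top3, p$gold)
      data.frame(
        itemId = p$itemId, em = m[["em"]], hit3 = m[["hit3"]],
        bleu = smilesBleu(top1, p$gold),
        leven = levenshtein(top1, p$gold),
        rdk = fts(top1, p$gold, "path"),
        mac = fts(top1, p$gold, "maccs"),
        morgan = fts(top1, p$gold, "morgan"),
        stringsAsFactors = FALSE
      )
    } else {
      if (is.null(p$text)) stop("understanding item missing text")
      tm <- textMetrics(p$text, p$gold)
      cbind(data.frame(itemId = p$itemId, stringsAsFactors = FALSE),
            as.data.frame(as.list(tm)))
    }
  })
  perItem <- do.call(rbind, rows)
  metricCols <- setdiff(names(perItem), "itemId")
  new("EvalReport", task = task, perItem = perItem,
      aggregate = vapply(perItem[metricCols], mean, 0),
      nItems = nrow(perItem))
}

#' @rdname EvalReport-class
#' @export
setMethod("aggregateMetrics", "EvalReport", function(x) x@aggregate)

#' @rdname EvalReport-class
#' @export
setMethod("perItemMetrics", "EvalReport", function(x) x@perItem)

setMethod("show", "EvalReport", function(object) {
  cols <- if (object@task == "generation") .GEN_COLS else .UND_COLS
  cat("EvalReport (", object@task, ", n = ", object@nItems, ")\n", sep = "")
  agg <- object@aggregate[names(cols)]
  names(agg) <- unname(cols)
  print(round(agg, 4))
})

#' Write an evaluation report as TSV and JSON
#'
#' Aggregate columns use the conventional short names (BL-2/BL-4/RG-1/RG-2/
#' RG-L/MET for understanding; EM/hit@3/BL/Leven/RDK/MAC/Morgan for
#' generation).
#'
#' @param report An \linkS4class{EvalReport}.
#' @param prefix Output path prefix; writes \code{<prefix>.tsv} (per item)
#'   and \code{<prefix>.json} (aggregate).
#' @return \code{prefix}, invisibly.
#' @export
writeEvalReport <- function(report, prefix) {
  cols <- if (report@task == "generation") .GEN_COLS else .UND_COLS
  per <- report@perItem
  names(per) <- c("itemId", unname(cols[names(per)[-1]]))
  .writeTsv(per, paste0(prefix, ".tsv"))
  agg <- as.list(report@aggregate)
  names(agg) <- unname(cols[names(agg)])
  jsonlite::write_json(c(list(task = report@task, n_items = report@nItems),
                         agg),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
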