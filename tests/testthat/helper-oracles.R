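# Independent oracles kept deliberately separate from the implementation
# paths they check.

# Quadratic dynamic-programming edit distance.
oracleLevenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1L, length(y) + 1L)
  d[, 1] <- 0:length(x)
  d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[length(x) + 1L, length(y) + 1L]
}

# Brute-force bit-set Tanimoto over 0/1 vectors.
oracleTanimoto <- function(bitsA, bitsB, nBits) {
  va <- rep(0L, nBits); va[bitsA + 1L] <- 1L
  vb <- rep(0L, nBits); vb[bitsB + 1L] <- 1L
  un <- sum(va | vb)
  if (un == 0) return(0)
  sum(va & vb) / un
}

# Shortest cycle through an atom by BFS over each incident edge; NULL-safe
# independent check on ring membership for small molecules.
oracleSmallestCycle <- function(mol, atomIndex) {
  b <- bonds(mol)
  n <- nrow(atoms(mol))
  adj <- lapply(seq_len(n) - 1L, function(v) {
    sort(c(b$j[b$i == v], b$i[b$j == v]))
  })
  best <- Inf
  for (w in adj[[atomIndex + 1L]]) {
    # shortest path atomIndex -> w avoiding the direct edge
    dist <- rep(Inf, n)
    dist[atomIndex + 1L] <- 0
    queue <- atomIndex
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v + 1L]]) {
        if (v == atomIndex && u == w) next
        if (v == w && u == atomIndex) next
        if (is.infinite(dist[u + 1L])) {
          dist[u + 1L] <- dist[v + 1L] + 1
          queue <- c(queue, u)
        }
      }
    }
    if (is.finite(dist[w + 1L])) best <- min(best, dist[w + 1L] + 1)
  }
  if (is.finite(best)) best else NA_integer_
}

# Maximal non-overlapping longest-match entity spans by exhaustive
# enumeration (oracle for the lexicon scanner).
oracleEntitySpans <- function(text, lexicon) {
  lower <- tolower(text)
  all <- list()
  for (nm in names(lexicon)) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                              tolower(nm)), "\\b")
    m <- gregexpr(pat, lower, perl = TRUE)[[1]]
    for (k in seq_along(m)) {
      if (m[k] > 0) {
        all[[length(all) + 1L]] <- list(name = nm, start = as.integer(m[k]),
                                        end = as.integer(m[k]) +
                                          attr(m, "match.length")[k] - 1L)
      }
    }
  }
  if (!length(all)) return(all)
  ord <- order(vapply(all, function(h) -(h$end - h$start), 0),
               vapply(all, function(h) h$start, 0))
  taken <- logical(nchar(text))
  keep <- list()
  for (h in all[ord]) {
    if (!any(taken[h$start:h$end])) {
      taken[h$start:h$end] <- TRUE
      keep[[length(keep) + 1L]] <- h
    }
  }
  keep[order(vapply(keep, function(h) h$start, 0))]
}
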