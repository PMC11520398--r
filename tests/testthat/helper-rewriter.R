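# Randomized SMILES re-writer: emits an alternative SMILES for a Molecule
# by depth-first traversal from a random start atom with shuffled neighbour
# order. Used to check canonicalization invariance; consumes only the
# public graph accessors. Ring-closure bonds are written without bond
# symbols, which is exact for the synthetic grammar (ring bonds are either
# aromatic-implicit or single); molecules outside that regime fall back to
# their original writing.

randomSmilesRewrite <- function(mol, seed = 1L) {
  a <- atoms(mol)
  b <- bonds(mol)
  n <- nrow(a)
  set.seed(seed)
  adj <- lapply(seq_len(n) - 1L, function(v) {
    nb <- c(b$j[b$i == v], b$i[b$j == v])
    idx <- sample(seq_along(nb))
    nb[idx]
  })
  bkey <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  edgeKey <- function(u, v) paste(min(u, v), max(u, v))
  orderOf <- function(u, v) b$order[match(edgeKey(u, v), bkey)]

  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  seen <- integer(0)
  treeEdges <- character(0)
  backEdges <- character(0)
  stack <- integer(0)
  dfs <- function(v) {
    visited[v + 1L] <<- TRUE
    for (w in adj[[v + 1L]]) {
      key <- edgeKey(v, w)
      if (!visited[w + 1L]) {
        parent[w + 1L] <<- v
        treeEdges <<- c(treeEdges, key)
        dfs(w)
      } else if (!key %in% c(treeEdges, backEdges)) {
        backEdges <<- c(backEdges, key)
      }
    }
  }
  start <- sample.int(n, 1L) - 1L
  dfs(start)
  if (any(!visited)) return(smiles(mol))  # disconnected: keep original
  for (key in backEdges) {
    uv <- as.integer(strsplit(key, " ")[[1]])
    if (!orderOf(uv[1], uv[2]) %in% c("single", "aromatic")) {
      return(smiles(mol))
    }
  }
  digitOf <- stats::setNames(as.character(seq_along(backEdges)), backEdges)

  atomTok <- function(v) {
    el <- a$element[v + 1L]
    tok <- if (a$aromatic[v + 1L]) tolower(el) else el
    if (nchar(tok) == 2L && !a$aromatic[v + 1L] && !el %in% c("Cl", "Br")) {
      tok <- paste0("[", tok, "]")
    }
    if (a$charge[v + 1L] != 0L) {
      sgn <- if (a$charge[v + 1L] > 0L) "+" else "-"
      tok <- paste0("[", el, strrep(sgn, abs(a$charge[v + 1L])), "]")
    }
    tok
  }
  bondChar <- function(u, v) {
    switch(orderOf(u, v), single = "", double = "=", triple = "#",
           aromatic = if (a$aromatic[u + 1L] && a$aromatic[v + 1L]) "" else ":")
  }
  write <- function(v) {
    tok <- atomTok(v)
    for (key in names(digitOf)) {
      uv <- as.integer(strsplit(key, " ")[[1]])
      if (v %in% uv) tok <- paste0(tok, digitOf[[key]])
    }
    kids <- Filter(function(w) identical(parent[w + 1L], v), adj[[v + 1L]])
    parts <- vapply(kids, function(w) paste0(bondChar(v, w), write(w)), "")
    if (length(parts) <= 1L) {
      paste0(tok, paste(parts, collapse = ""))
    } else {
      paste0(tok,
             paste(vapply(parts[-length(parts)],
                          function(p) paste0("(", p, ")"), ""),
                   collapse = ""),
             parts[length(parts)])
    }
  }
  write(start)
}
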