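# Strict SMILES reader producing an explicit molecular graph.
#
# OpenBabel (used for canonicalization and fingerprints) silently repairs
# malformed input, so validity checking and the atom/bond/ring graph with
# parse-order indexing live here. Covers the organic subset, bracket atoms,
# branches, ring-bond closures (incl. %nn), charges, explicit bond orders and
# aromatic (lowercase) notation. Stereo marks (/ \ @) are read and discarded;
# hydrogens are implicit throughout.

.SMILES_ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.SMILES_AROMATIC <- c("b", "c", "n", "o", "p", "s")
.SMILES_ELEMENTS <- c(
  .SMILES_ORGANIC, "H", "Si", "Se", "As", "Li", "Na", "K", "Mg", "Ca", "Fe",
  "Zn", "Cu", "Mn", "Co", "Ni", "Al", "Sn", "Te"
)

.invalidSmiles <- function(smiles, why) {
  stop(structure(
    class = c("invalidSmilesError", "error", "condition"),
    list(
      message = sprintf("invalid SMILES %s: %s", deparse(smiles), why),
      call = NULL, smiles = smiles
    )
  ))
}

# Tokenizes and walks a SMILES string, returning atoms/bonds in parse order.
# Atom indices are 0-based over heavy atoms. Errors are signalled as
# 'invalidSmilesError' conditions carrying the offending string.
.smilesToGraph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    .invalidSmiles(smiles, "not a non-empty string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  elem <- character(0)
  arom <- logical(0)
  charge <- integer(0)

  bond_i <- integer(0)
  bond_j <- integer(0)
  bond_o <- character(0)

  addBond <- function(i, j, order) {
    bond_i[[length(bond_i) + 1L]] <<- i
    bond_j[[length(bond_j) + 1L]] <<- j
    bond_o[[length(bond_o) + 1L]] <<- order
  }

  stack <- integer(0)      # open branch points
  prev <- NA_integer_      # previous atom index (0-based)
  pending_bond <- NA_character_
  ring_open <- list()      # closure digit -> list(atom, bond)

  newAtom <- function(symbol, aromatic, chg = 0L) {
    elem[[length(elem) + 1L]] <<- symbol
    arom[[length(arom) + 1L]] <<- aromatic
    charge[[length(charge) + 1L]] <<- chg
    idx <- length(elem) - 1L
    if (!is.na(prev)) {
      order <- pending_bond
      if (is.na(order)) {
        order <- if (aromatic && arom[[prev + 1L]]) "aromatic" else "single"
      }
      addBond(prev, idx, order)
    }
    prev <<- idx
    pending_bond <<- NA_character_
    idx
  }

  closeRing <- function(key) {
    if (is.na(prev)) .invalidSmiles(smiles, "ring bond before any atom")
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      if (op$atom == prev) .invalidSmiles(smiles, "ring bond to the same atom")
      order <- pending_bond
      if (is.na(order)) order <- op$bond
      if (is.na(order)) {
        order <- if (arom[[op$atom + 1L]] && arom[[prev + 1L]])
          "aromatic" else "single"
      }
      addBond(op$atom, prev, order)
      ring_open[[key]] <<- NULL
      pending_bond <<- NA_character_
    } else {
      ring_open[[key]] <<- list(atom = prev, bond = pending_bond)
      pending_bond <<- NA_character_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""

    if (ch == "(") {
      if (is.na(prev)) .invalidSmiles(smiles, "branch before any atom")
      stack[[length(stack) + 1L]] <- prev
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) .invalidSmiles(smiles, "unbalanced ')'")
      prev <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.na(pending_bond)) .invalidSmiles(smiles, "two bond symbols in a row")
      pending_bond <- switch(ch,
        "-" = "single", "/" = "single", "\\" = "single",
        "=" = "double", "#" = "triple", ":" = "aromatic"
      )
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NA_character_
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      closeRing(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L]))) {
        .invalidSmiles(smiles, "'%' not followed by two digits")
      }
      closeRing(paste0("%", chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == "[") {
      close_at <- NA_integer_
      for (k in seq(i + 1L, length.out = n - i)) {
        if (chars[k] == "]") { close_at <- k; break }
      }
      if (is.na(close_at)) .invalidSmiles(smiles, "unclosed '['")
      body <- paste0(chars[(i + 1L):(close_at - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2}H?[0-9]*)((?:\\+{1,3}|-{1,3}|[+-][0-9])?)$",
        body))[[1]]
      if (length(m) == 0L) .invalidSmiles(smiles, sprintf("bad bracket atom [%s]", body))
      sym <- m[3]
      aromatic <- sym %in% .SMILES_AROMATIC || sym == "se"
      symbol <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      } else sym
      if (!symbol %in% .SMILES_ELEMENTS) {
        .invalidSmiles(smiles, sprintf("unknown element '%s'", sym))
      }
      chg_txt <- m[5]
      chg <- if (!nzchar(chg_txt)) 0L
        else if (grepl("^[+-][0-9]$", chg_txt)) {
          as.integer(substr(chg_txt, 2, 2)) * (if (substr(chg_txt, 1, 1) == "+") 1L else -1L)
        } else nchar(chg_txt) * (if (substr(chg_txt, 1, 1) == "+") 1L else -1L)
      if (symbol == "H") {
        # bare bracket hydrogen (e.g. [H+]): no heavy atom; drop it
        prev_keep <- prev
        pending_bond <- NA_character_
        prev <- prev_keep
      } else {
        newAtom(symbol, aromatic, chg)
      }
      i <- close_at + 1L
    } else if (two %in% c("Cl", "Br")) {
      newAtom(two, FALSE)
      i <- i + 2L
    } else if (ch %in% .SMILES_ORGANIC) {
      newAtom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% .SMILES_AROMATIC) {
      newAtom(toupper(ch), TRUE)
      i <- i + 1L
    } else {
      .invalidSmiles(smiles, sprintf("unexpected character '%s' at position %d", ch, i))
    }
  }

  if (length(stack) > 0L) .invalidSmiles(smiles, "unbalanced '('")
  if (!is.na(pending_bond)) .invalidSmiles(smiles, "dangling bond symbol")
  if (length(ring_open) > 0L) {
    .invalidSmiles(smiles, sprintf("unclosed ring bond(s): %s",
                                   paste(names(ring_open), collapse = ",")))
  }
  if (length(elem) == 0L) .invalidSmiles(smiles, "no atoms")
  dup <- duplicated(cbind(pmin(bond_i, bond_j), pmax(bond_i, bond_j)))
  if (any(dup)) .invalidSmiles(smiles, "duplicate bond")

  list(
    atoms = data.frame(
      index = seq_along(elem) - 1L, element = elem, aromatic = arom,
      charge = charge, stringsAsFactors = FALSE
    ),
    bonds = if (length(bond_i)) data.frame(
      i = bond_i, j = bond_j, order = bond_o, stringsAsFactors = FALSE
    ) else data.frame(i = integer(0), j = integer(0), order = character(0),
                      stringsAsFactors = FALSE)
  )
}

# Smallest set of smallest rings by per-edge shortest-cycle search with a
# GF(2) independence filter over edge incidence vectors. Intended for the
# small-molecule regime (tens of atoms); returns 0-based atom-index vectors.
.sssr <- function(natoms, bonds) {
  nb <- nrow(bonds)
  n_comp_edges <- nb - natoms + .nComponents(natoms, bonds)
  if (n_comp_edges <= 0L) return(list())

  adj <- vector("list", natoms)
  for (b in seq_len(nb)) {
    i <- bonds$i[b] + 1L; j <- bonds$j[b] + 1L
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  edgeId <- function(i, j) paste(pmin(i, j), pmax(i, j))
  eid <- structure(seq_len(nb), names = edgeId(bonds$i + 1L, bonds$j + 1L))

  shortestPathAvoiding <- function(from, to, banned_edge) {
    # BFS over 1-based vertex ids skipping one edge
    parent <- rep(NA_integer_, natoms)
    seen <- rep(FALSE, natoms)
    seen[from] <- TRUE
    queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == to) break
      for (w in adj[[v]]) {
        if (identical(sort(c(v, w)), banned_edge)) next
        if (!seen[w]) {
          seen[w] <- TRUE
          parent[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (!seen[to]) return(NULL)
    path <- to
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    path
  }

  cycles <- list()
  for (b in seq_len(nb)) {
    u <- bonds$i[b] + 1L; v <- bonds$j[b] + 1L
    p <- shortestPathAvoiding(u, v, sort(c(u, v)))
    if (is.null(p)) next
    cycles[[length(cycles) + 1L]] <- p
  }
  if (!length(cycles)) return(list())

  key <- vapply(cycles, function(cy) paste(sort(cy), collapse = ","), "")
  cycles <- cycles[!duplicated(key)]
  cycles <- cycles[order(lengths(cycles))]

  cycleEdgeVec <- function(cy) {
    v <- rep(0L, nb)
    m <- length(cy)
    for (k in seq_len(m)) {
      a <- cy[k]; bnd <- cy[if (k == m) 1L else k + 1L]
      v[eid[[edgeId(a, bnd)]]] <- 1L
    }
    v
  }

  basis <- matrix(integer(0), nrow = 0, ncol = nb)
  chosen <- list()
  for (cy in cycles) {
    if (length(chosen) == n_comp_edges) break
    vec <- cycleEdgeVec(cy)
    red <- vec
    if (nrow(basis) > 0) {
      for (r in seq_len(nrow(basis))) {
        pivot <- which(basis[r, ] == 1L)[1]
        if (red[pivot] == 1L) red <- (red + basis[r, ]) %% 2L
      }
    }
    if (any(red == 1L)) {
      basis <- rbind(basis, red)
      chosen[[length(chosen) + 1L]] <- sort(cy - 1L)
    }
  }
  chosen
}

.nComponents <- function(natoms, bonds) {
  parent <- seq_len(natoms)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(bonds)) for (b in seq_len(nrow(bonds))) {
    ri <- find(bonds$i[b] + 1L); rj <- find(bonds$j[b] + 1L)
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_len(natoms), find, 1L)))
}

# Marks kekulized aromatic rings: a 6-ring of C/N atoms whose ring bonds
# alternate single/double is flagged aromatic (covers benzene/pyridine
# written in Kekule form). Lowercase-notated aromaticity is kept as parsed.
.perceiveAromaticity <- function(atoms, bonds, rings) {
  if (!length(rings)) return(list(atoms = atoms, bonds = bonds))
  bkey <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  for (ring in rings) {
    m <- length(ring)
    idx1 <- ring + 1L
    if (all(atoms$aromatic[idx1])) next
    if (m != 6L || !all(atoms$element[idx1] %in% c("C", "N"))) next
    # walk the ring in cyclic order
    ordered <- .orderRing(ring, bonds)
    if (is.null(ordered)) next
    orders <- character(m)
    for (k in seq_len(m)) {
      a <- ordered[k]; b <- ordered[if (k == m) 1L else k + 1L]
      orders[k] <- bonds$order[match(paste(min(a, b), max(a, b)), bkey)]
    }
    alt <- all(orders[seq(1, m, 2)] == "single") && all(orders[seq(2, m, 2)] == "double")
    alt2 <- all(orders[seq(1, m, 2)] == "double") && all(orders[seq(2, m, 2)] == "single")
    if (alt || alt2) {
      atoms$aromatic[idx1] <- TRUE
      for (k in seq_len(m)) {
        a <- ordered[k]; b <- ordered[if (k == m) 1L else k + 1L]
        bonds$order[match(paste(min(a, b), max(a, b)), bkey)] <- "aromatic"
      }
    }
  }
  list(atoms = atoms, bonds = bonds)
}

# Returns ring atoms in cyclic adjacency order (0-based), or NULL if the
# atom set does not form a single cycle in the bond graph.
.orderRing <- function(ring, bonds) {
  m <- length(ring)
  in_ring <- bonds$i %in% ring & bonds$j %in% ring
  sub <- bonds[in_ring, , drop = FALSE]
  nbr <- lapply(ring, function(a) {
    c(sub$j[sub$i == a], sub$i[sub$j == a])
  })
  names(nbr) <- as.character(ring)
  if (!all(lengths(nbr) == 2L)) return(NULL)
  ordered <- ring[1]
  prev <- NA_integer_
  for (k in seq_len(m - 1L)) {
    cur <- ordered[length(ordered)]
    nxt <- setdiff(nbr[[as.character(cur)]], prev)
    if (!length(nxt)) return(NULL)
    prev <- cur
    ordered <- c(ordered, nxt[1])
  }
  if (length(unique(ordered)) != m) return(NULL)
  ordered
}
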