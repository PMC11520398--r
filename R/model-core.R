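# Numerical core of the twin sequence-to-sequence model: a batched GRU
# encoder-decoder with dot-product attention, hand-derived backward pass and
# Adam updates, in plain matrix arithmetic. Correctness of the gradients is
# pinned by a finite-difference check in the test suite.
#
# Conventions: batches are B x H matrices; the encoder is left-padded (all
# sequences end at the same column) and padded positions are masked out of
# the attention; the decoder is right-padded with a loss mask. Decoder
# hidden states are initialized from the encoder's final state per layer.

.sigm <- function(x) 1 / (1 + exp(-x))

.addBias <- function(m, b) m + rep(b, each = nrow(m))

.initMatrix <- function(nr, nc, scale = 0.08) {
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

.initGruCell <- function(h) {
  list(Wz = .initMatrix(h, h), Uz = .initMatrix(h, h), bz = numeric(h),
       Wr = .initMatrix(h, h), Ur = .initMatrix(h, h), br = numeric(h),
       Wn = .initMatrix(h, h), Un = .initMatrix(h, h), bn = numeric(h))
}

# One encoder-decoder parameter set ("route"). Embeddings are H-dim; all
# recurrent inputs are H-dim, so every weight is H x H.
.initRoute <- function(vocabSize, hidden, layers) {
  list(
    Esrc = .initMatrix(vocabSize, hidden),
    Etgt = .initMatrix(vocabSize, hidden),
    enc = lapply(seq_len(layers), function(l) .initGruCell(hidden)),
    dec = lapply(seq_len(layers), function(l) .initGruCell(hidden)),
    Wout = .initMatrix(2L * hidden, vocabSize),
    bout = numeric(vocabSize)
  )
}

.zerosLike <- function(p) {
  if (is.list(p)) lapply(p, .zerosLike) else p * 0
}

.gruForward <- function(cell, x, h) {
  z <- .sigm(.addBias(x %*% cell$Wz + h %*% cell$Uz, cell$bz))
  r <- .sigm(.addBias(x %*% cell$Wr + h %*% cell$Ur, cell$br))
  n <- tanh(.addBias(x %*% cell$Wn + (r * h) %*% cell$Un, cell$bn))
  list(z = z, r = r, n = n, h = z * h + (1 - z) * n)
}

# Backward through one GRU step. `cache` is the forward record plus x and
# hprev; returns dx and dhprev and accumulates parameter gradients in g.
.gruBackward <- function(cell, g, cache, dh) {
  z <- cache$z; r <- cache$r; n <- cache$n
  x <- cache$x; hprev <- cache$hprev
  dz <- dh * (hprev - n)
  dn <- dh * (1 - z)
  dhprev <- dh * z
  dnpre <- dn * (1 - n * n)
  dx <- dnpre %*% t(cell$Wn)
  drh <- dnpre %*% t(cell$Un)
  dr <- drh * hprev
  dhprev <- dhprev + drh * r
  dzpre <- dz * z * (1 - z)
  drpre <- dr * r * (1 - r)
  dx <- dx + dzpre %*% t(cell$Wz) + drpre %*% t(cell$Wr)
  dhprev <- dhprev + dzpre %*% t(cell$Uz) + drpre %*% t(cell$Ur)
  g$Wn <- g$Wn + crossprod(x, dnpre)
  g$Un <- g$Un + crossprod(r * hprev, dnpre)
  g$bn <- g$bn + colSums(dnpre)
  g$Wz <- g$Wz + crossprod(x, dzpre)
  g$Uz <- g$Uz + crossprod(hprev, dzpre)
  g$bz <- g$bz + colSums(dzpre)
  g$Wr <- g$Wr + crossprod(x, drpre)
  g$Ur <- g$Ur + crossprod(hprev, drpre)
  g$br <- g$br + colSums(drpre)
  list(dx = dx, dhprev = dhprev, g = g)
}

.accumEmbed <- function(dE, ids, dx) {
  s <- rowsum(dx, group = ids)
  rows <- as.integer(rownames(s))
  dE[rows, ] <- dE[rows, , drop = FALSE] + s
  dE
}

# Full forward + backward for one batch on one route.
#
# src: B x S integer id matrix, left-padded with padId.
# tgtIn / tgtOut: B x T shifted target ids (tgtIn starts with BOS), right-
# padded; lossMask: B x T 0/1.
# Returns mean token cross-entropy and, unless lossOnly, gradients shaped
# like the route.
.routeBatch <- function(route, src, tgtIn, tgtOut, lossMask, padId,
                        lossOnly = FALSE) {
  B <- nrow(src); S <- ncol(src); Tn <- ncol(tgtIn)
  L <- length(route$enc)
  H <- ncol(route$Esrc)
  V <- nrow(route$Esrc)

  # ---- encoder ----
  # States are hard-reset to zero at (left-)pad positions so that a padded
  # batch computes exactly the states an unpadded single sequence would:
  # training and inference see identical encoders.
  hs <- lapply(seq_len(L), function(l) matrix(0, B, H))
  encCache <- vector("list", S)
  Hbig <- matrix(0, S * B, H)   # row (t-1)*B + b = top state at time t
  for (t in seq_len(S)) {
    padRow <- src[, t] == padId
    x <- route$Esrc[src[, t], , drop = FALSE]
    inp <- x
    layerCache <- vector("list", L)
    for (l in seq_len(L)) {
      st <- .gruForward(route$enc[[l]], inp, hs[[l]])
      layerCache[[l]] <- list(z = st$z, r = st$r, n = st$n, x = inp,
                              hprev = hs[[l]])
      h <- st$h
      if (any(padRow)) h[padRow, ] <- 0
      hs[[l]] <- h
      inp <- h
    }
    encCache[[t]] <- layerCache
    Hbig[(t - 1L) * B + seq_len(B), ] <- hs[[L]]
  }
  encFinal <- hs

  attMask <- src == padId            # B x S, TRUE = masked out
  bIdx <- rep(seq_len(B), times = S) # group vector for rowsum over s

  # ---- decoder ----
  # Input feeding: the previous step's attention context is added to the
  # token embedding, which lets the decoder track its position in a copied
  # source span (essential for copy-and-edit behaviour on SMILES).
  gs <- encFinal
  decCache <- vector("list", Tn)
  nValid <- sum(lossMask)
  if (nValid == 0) stop("empty loss mask")
  totalNll <- 0
  dlogitsAll <- vector("list", Tn)
  ctxPrev <- matrix(0, B, H)
  for (t in seq_len(Tn)) {
    x <- route$Etgt[tgtIn[, t], , drop = FALSE] + ctxPrev
    inp <- x
    layerCache <- vector("list", L)
    for (l in seq_len(L)) {
      st <- .gruForward(route$dec[[l]], inp, gs[[l]])
      layerCache[[l]] <- list(z = st$z, r = st$r, n = st$n, x = inp,
                              hprev = gs[[l]])
      gs[[l]] <- st$h
      inp <- st$h
    }
    h <- gs[[L]]
    # attention over encoder top states
    hrep <- h[bIdx, , drop = FALSE]
    e <- matrix(rowSums(Hbig * hrep), B, S)
    e[attMask] <- -Inf
    emax <- do.call(pmax, as.data.frame(e))
    a <- exp(e - emax)
    a <- a / rowSums(a)
    aFlat <- as.vector(a)
    ctx <- rowsum(Hbig * aFlat, group = bIdx)
    ctxPrev <- ctx
    o <- cbind(h, ctx)
    logits <- .addBias(o %*% route$Wout, route$bout)
    mx <- do.call(pmax, as.data.frame(logits))
    P <- exp(logits - mx)
    Z <- rowSums(P)
    tgtCol <- tgtOut[, t]
    lp <- logits[cbind(seq_len(B), tgtCol)] - mx - log(Z)
    totalNll <- totalNll - sum(lp * lossMask[, t])
    if (!lossOnly) {
      dlog <- P / Z
      dlog[cbind(seq_len(B), tgtCol)] <- dlog[cbind(seq_len(B), tgtCol)] - 1
      dlog <- dlog * (lossMask[, t] / nValid)
      dlogitsAll[[t]] <- dlog
      layerCache[[L]]$att <- list(a = a, h = h, ctx = ctx, o = o)
    }
    decCache[[t]] <- layerCache
  }
  loss <- totalNll / nValid
  if (lossOnly) return(list(loss = loss))

  # ---- backward ----
  g <- .zerosLike(route)
  dHbig <- matrix(0, S * B, H)
  dgs <- lapply(seq_len(L), function(l) matrix(0, B, H))
  dctxFeed <- matrix(0, B, H)  # input-feeding gradient from step t+1
  for (t in rev(seq_len(Tn))) {
    att <- decCache[[t]][[length(decCache[[t]])]]$att
    dlog <- dlogitsAll[[t]]
    g$Wout <- g$Wout + crossprod(att$o, dlog)
    g$bout <- g$bout + colSums(dlog)
    do_ <- dlog %*% t(route$Wout)
    dh <- do_[, seq_len(H), drop = FALSE]
    dctx <- do_[, H + seq_len(H), drop = FALSE] + dctxFeed
    # attention backward
    aFlat <- as.vector(att$a)
    dctxRep <- dctx[bIdx, , drop = FALSE]
    dHbig <- dHbig + aFlat * dctxRep
    daFlat <- rowSums(Hbig * dctxRep)
    da <- matrix(daFlat, B, S)
    de <- att$a * (da - rowSums(att$a * da))
    deFlat <- as.vector(de)
    hrep <- att$h[bIdx, , drop = FALSE]
    dHbig <- dHbig + deFlat * hrep
    dh <- dh + rowsum(Hbig * deFlat, group = bIdx)
    # recurrent chain
    dgs[[L]] <- dgs[[L]] + dh
    for (l in rev(seq_len(L))) {
      bk <- .gruBackward(route$dec[[l]], g$dec[[l]], decCache[[t]][[l]],
                         dgs[[l]])
      g$dec[[l]] <- bk$g
      dgs[[l]] <- bk$dhprev
      if (l > 1L) {
        dgs[[l - 1L]] <- dgs[[l - 1L]] + bk$dx
      } else {
        g$Etgt <- .accumEmbed(g$Etgt, tgtIn[, t], bk$dx)
        dctxFeed <- bk$dx  # x_t = Etgt[..] + ctx_{t-1}
      }
    }
  }
  # decoder initial state came from the encoder's final state
  dhs <- dgs
  for (t in rev(seq_len(S))) {
    padRow <- src[, t] == padId
    dhs[[L]] <- dhs[[L]] + dHbig[(t - 1L) * B + seq_len(B), , drop = FALSE]
    for (l in rev(seq_len(L))) {
      if (any(padRow)) dhs[[l]][padRow, ] <- 0  # forward states were reset
      bk <- .gruBackward(route$enc[[l]], g$enc[[l]], encCache[[t]][[l]],
                         dhs[[l]])
      g$enc[[l]] <- bk$g
      dhs[[l]] <- bk$dhprev
      if (l > 1L) {
        dhs[[l - 1L]] <- dhs[[l - 1L]] + bk$dx
      } else {
        g$Esrc <- .accumEmbed(g$Esrc, src[, t], bk$dx)
      }
    }
  }
  list(loss = loss, grads = g)
}

# ---- flat parameter views for the optimizer --------------------------------

.flattenParams <- function(p, prefix = "") {
  if (is.list(p)) {
    out <- list()
    nms <- names(p)
    if (is.null(nms)) nms <- as.character(seq_along(p))
    for (i in seq_along(p)) {
      out <- c(out, .flattenParams(p[[i]], paste0(prefix, "/", nms[i])))
    }
    out
  } else {
    stats::setNames(list(p), prefix)
  }
}

.applyFlat <- function(p, flat, prefix = "") {
  if (is.list(p)) {
    nms <- names(p)
    if (is.null(nms)) nms <- as.character(seq_along(p))
    for (i in seq_along(p)) {
      p[[i]] <- .applyFlat(p[[i]], flat, paste0(prefix, "/", nms[i]))
    }
    p
  } else {
    flat[[prefix]]
  }
}

# Adam with global-norm gradient clipping. state holds m/v/t; returns the
# updated route and state.
.adamStep <- function(route, grads, state, lr = 3e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 5) {
  fp <- .flattenParams(route)
  fg <- .flattenParams(grads)
  gnorm <- sqrt(sum(vapply(fg, function(g) sum(g * g), 0)))
  scale <- if (gnorm > clip) clip / gnorm else 1
  if (is.null(state$m)) {
    state$m <- lapply(fg, function(g) g * 0)
    state$v <- lapply(fg, function(g) g * 0)
    state$t <- 0L
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(fp)) {
    gk <- fg[[k]] * scale
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk * gk
    fp[[k]] <- fp[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(route = .applyFlat(route, fp), state = state)
}

# ---- single-sequence decoding ----------------------------------------------

# Encoder forward for one sequence (no padding); returns top states matrix
# (S x H) and per-layer final states.
.encodeOne <- function(route, srcIds) {
  L <- length(route$enc); H <- ncol(route$Esrc)
  hs <- lapply(seq_len(L), function(l) matrix(0, 1, H))
  Htop <- matrix(0, length(srcIds), H)
  for (t in seq_along(srcIds)) {
    inp <- route$Esrc[srcIds[t], , drop = FALSE]
    for (l in seq_len(L)) {
      st <- .gruForward(route$enc[[l]], inp, hs[[l]])
      hs[[l]] <- st$h
      inp <- st$h
    }
    Htop[t, ] <- hs[[L]]
  }
  list(Htop = Htop, final = hs)
}

# One decoder step for one hypothesis; state holds the per-layer hidden
# list ($h) and the previous attention context ($ctx, input feeding).
# Returns the log-probability vector over the vocabulary and the new state.
.decodeStep <- function(route, state, prevId, Htop) {
  L <- length(route$dec); H <- ncol(route$Etgt)
  inp <- route$Etgt[prevId, , drop = FALSE] + state$ctx
  for (l in seq_len(L)) {
    st <- .gruForward(route$dec[[l]], inp, state$h[[l]])
    state$h[[l]] <- st$h
    inp <- st$h
  }
  h <- state$h[[L]]
  e <- as.vector(Htop %*% t(h))
  a <- exp(e - max(e))
  a <- a / sum(a)
  ctx <- matrix(colSums(Htop * a), 1)
  state$ctx <- ctx
  logits <- as.vector(cbind(h, ctx) %*% route$Wout) + route$bout
  lp <- logits - (max(logits) + log(sum(exp(logits - max(logits)))))
  list(logprobs = lp, state = state)
}

# Beam search decoding over one route. Returns up to k distinct token-id
# sequences (without BOS/EOS) in descending score order.
.beamDecode <- function(route, srcIds, bosId, eosId, k = 3L, maxLen = 60L,
                        beamWidth = max(3L * k, 8L)) {
  enc <- .encodeOne(route, srcIds)
  H <- ncol(route$Esrc)
  beams <- list(list(ids = integer(0), lp = 0,
                     state = list(h = enc$final, ctx = matrix(0, 1, H)),
                     prev = bosId, done = FALSE))
  finished <- list()
  for (step in seq_len(maxLen)) {
    cand <- list()
    for (b in beams) {
      if (b$done) next
      st <- .decodeStep(route, b$state, b$prev, enc$Htop)
      top <- order(st$logprobs, decreasing = TRUE)[seq_len(beamWidth)]
      for (id in top) {
        cand[[length(cand) + 1L]] <- list(
          ids = c(b$ids, id), lp = b$lp + st$logprobs[id], state = st$state,
          prev = id, done = id == eosId
        )
      }
    }
    if (!length(cand)) break
    ord <- order(vapply(cand, function(c) c$lp, 0), decreasing = TRUE)
    cand <- cand[ord[seq_len(min(beamWidth, length(cand)))]]
    beams <- list()
    for (c in cand) {
      if (c$done) {
        c$ids <- c$ids[-length(c$ids)]  # strip EOS
        finished[[length(finished) + 1L]] <- c
      } else {
        beams[[length(beams) + 1L]] <- c
      }
    }
    if (length(finished) >= beamWidth) break
  }
  for (b in beams) finished[[length(finished) + 1L]] <- b
  if (!length(finished)) return(list())
  # length-normalized final ranking counters the bias toward early EOS
  ord <- order(vapply(finished, function(c) c$lp / max(1L, length(c$ids)), 0),
               decreasing = TRUE)
  finished[ord]
}
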