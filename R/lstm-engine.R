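# Batched LSTM engine: forward pass, backpropagation through time, Adam.
#
# Weights layout:
#   layers[[l]] = list(Wx = D x 4H, Wh = H x 4H, b = 4H)
#     gate column blocks, in order: input (i), forget (f), cell (g), output (o)
#   dense = list(w = H x 1, b = scalar)
# The cell/candidate activation is configurable (relu per the published
# setting, or tanh); gate activations and the output neuron are sigmoid.
# All forward/backward steps operate on a whole batch at once (B x * matrices)
# so the heavy lifting is BLAS matrix products.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.act <- function(x, kind) if (kind == "relu") pmax(x, 0) else tanh(x)
# derivative expressed through the *activated* value (valid for both kinds)
.dact <- function(a, kind) if (kind == "relu") (a > 0) + 0 else 1 - a * a

# Standard LSTM initialisation: Glorot-uniform input kernels, orthogonal
# recurrent kernels (one orthogonal block per gate), forget-gate bias 1
# (keeps early memory open).
.lstmInit <- function(m, units, nLayers) {
  glorot <- function(nin, nout)
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
  orthogonal <- function(n) {
    qrd <- qr(matrix(stats::rnorm(n * n), n, n))
    q <- qr.Q(qrd)
    # fix the sign ambiguity so the draw is uniform over orthogonal matrices
    q * rep(sign(diag(qr.R(qrd))), each = n)
  }
  H <- units
  layers <- vector("list", nLayers)
  D <- m
  for (l in seq_len(nLayers)) {
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1
    Wh <- do.call(cbind, lapply(1:4, function(g) orthogonal(H)))
    layers[[l]] <- list(Wx = glorot(D, 4L * H), Wh = Wh, b = b)
    D <- H
  }
  list(layers = layers, dense = list(w = glorot(H, 1L), b = 0))
}

# Scale gradients so their global L2 norm does not exceed `maxNorm`.
.clipGrads <- function(grads, maxNorm) {
  if (!is.finite(maxNorm)) return(grads)
  total <- sqrt(sum(vapply(.flattenW(grads), function(g) sum(g * g),
                           numeric(1L))))
  if (total <= maxNorm) return(grads)
  sc <- maxNorm / total
  grads$layers <- lapply(grads$layers, function(l) lapply(l, function(p) p * sc))
  grads$dense <- lapply(grads$dense, function(p) p * sc)
  grads
}

# X: B x T x D array -> list of T (B x D) matrices
.sliceTime <- function(X) {
  B <- dim(X)[1L]; T <- dim(X)[2L]; D <- dim(X)[3L]
  lapply(seq_len(T), function(t) matrix(X[, t, ], B, D))
}

# Forward pass. Returns sigmoid scores; with cache = TRUE also everything
# the backward pass needs. `mask` is an inverted-dropout mask (B x H,
# already scaled by 1/(1-p)) applied to the last hidden state; NULL at
# inference.
.lstmForward <- function(weights, X, actKind, mask = NULL, cache = FALSE) {
  xs <- .sliceTime(X)
  B <- nrow(xs[[1L]]); T <- length(xs)
  H <- nrow(weights$dense$w)
  gi <- seq_len(H); gf <- H + gi; gg <- 2L * H + gi; go <- 3L * H + gi
  caches <- if (cache) vector("list", length(weights$layers))
  inp <- xs
  for (l in seq_along(weights$layers)) {
    W <- weights$layers[[l]]
    bMat <- matrix(W$b, B, 4L * H, byrow = TRUE)
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    hs <- vector("list", T)
    if (cache) st <- vector("list", T)
    for (t in seq_len(T)) {
      z <- inp[[t]] %*% W$Wx + h %*% W$Wh + bMat
      i <- .sigmoid(z[, gi, drop = FALSE])
      f <- .sigmoid(z[, gf, drop = FALSE])
      g <- .act(z[, gg, drop = FALSE], actKind)
      o <- .sigmoid(z[, go, drop = FALSE])
      cPrev <- cc
      cc <- f * cPrev + i * g
      ac <- .act(cc, actKind)
      hPrev <- if (t == 1L) matrix(0, B, H) else hs[[t - 1L]]
      h <- o * ac
      hs[[t]] <- h
      if (cache)
        st[[t]] <- list(x = inp[[t]], hPrev = hPrev, cPrev = cPrev,
                        i = i, f = f, g = g, o = o, c = cc, ac = ac)
    }
    if (cache) caches[[l]] <- st
    inp <- hs
  }
  hFinal <- inp[[T]]
  hDrop <- if (is.null(mask)) hFinal else hFinal * mask
  score <- .sigmoid(hDrop %*% weights$dense$w + weights$dense$b)
  out <- list(scores = as.vector(score))
  if (cache) {
    out$caches <- caches
    out$hDrop <- hDrop
    out$mask <- mask
    out$seqOut <- inp  # hidden states of the top layer (unused downstream)
  }
  out
}

# Mean natural-log binary cross entropy, scores clipped away from {0, 1}.
.bceLoss <- function(scores, y, eps = 1e-12) {
  p <- pmin(pmax(scores, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Backward pass for mean-BCE loss. Returns gradients in the weights layout.
.lstmBackward <- function(weights, fwd, X, y, actKind) {
  B <- length(y)
  H <- nrow(weights$dense$w)
  gi <- seq_len(H); gf <- H + gi; gg <- 2L * H + gi; go <- 3L * H + gi
  dLogit <- matrix((fwd$scores - y) / B, B, 1L)
  grads <- list(layers = vector("list", length(weights$layers)),
                dense = list(w = crossprod(fwd$hDrop, dLogit),
                             b = sum(dLogit)))
  dh <- dLogit %*% t(weights$dense$w)
  if (!is.null(fwd$mask)) dh <- dh * fwd$mask
  # dhTop[[t]]: gradient flowing into hidden state t of the current layer
  # from the layer above (top layer: only the final step receives one).
  T <- length(fwd$caches[[1L]])
  dhTop <- c(rep(list(NULL), T - 1L), list(dh))
  for (l in rev(seq_along(weights$layers))) {
    W <- weights$layers[[l]]
    st <- fwd$caches[[l]]
    dWx <- matrix(0, nrow(W$Wx), ncol(W$Wx))
    dWh <- matrix(0, H, 4L * H)
    db <- numeric(4L * H)
    dxList <- vector("list", T)
    dhNext <- matrix(0, B, H); dcNext <- matrix(0, B, H)
    for (t in rev(seq_len(T))) {
      s <- st[[t]]
      dht <- dhNext
      if (!is.null(dhTop[[t]])) dht <- dht + dhTop[[t]]
      do <- dht * s$ac
      dc <- dht * s$o * .dact(s$ac, actKind) + dcNext
      df <- dc * s$cPrev
      di <- dc * s$g
      dg <- dc * s$i
      dz <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * .dact(s$g, actKind),
                  do * s$o * (1 - s$o))
      dWx <- dWx + crossprod(s$x, dz)
      dWh <- dWh + crossprod(s$hPrev, dz)
      db <- db + colSums(dz)
      dxList[[t]] <- dz %*% t(W$Wx)
      dhNext <- dz %*% t(W$Wh)
      dcNext <- dc * s$f
    }
    grads$layers[[l]] <- list(Wx = dWx, Wh = dWh, b = db)
    dhTop <- dxList  # becomes the per-step gradient for the layer below
  }
  grads
}

# --- Adam ------------------------------------------------------------------

.flattenW <- function(w) c(unlist(lapply(w$layers, function(l) l[c("Wx", "Wh", "b")]),
                                  recursive = FALSE),
                           list(dense.w = w$dense$w, dense.b = w$dense$b))

.adamInit <- function(weights) {
  zeros <- lapply(.flattenW(weights), function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

.adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  wFlat <- .flattenW(weights)
  gFlat <- .flattenW(grads)
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (k in seq_along(wFlat)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gFlat[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gFlat[[k]]^2
    wFlat[[k]] <- wFlat[[k]] -
      lr * (state$m[[k]] / corr1) / (sqrt(state$v[[k]] / corr2) + eps)
  }
  # fold flat params back into the structured layout
  nL <- length(weights$layers)
  for (l in seq_len(nL)) {
    weights$layers[[l]]$Wx <- wFlat[[(l - 1L) * 3L + 1L]]
    weights$layers[[l]]$Wh <- wFlat[[(l - 1L) * 3L + 2L]]
    weights$layers[[l]]$b <- as.numeric(wFlat[[(l - 1L) * 3L + 3L]])
  }
  weights$dense$w <- wFlat[[nL * 3L + 1L]]
  weights$dense$b <- as.numeric(wFlat[[nL * 3L + 2L]])
  list(weights = weights, state = state)
}

.countParams <- function(weights)
  sum(vapply(.flattenW(weights), length, integer(1L)))
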