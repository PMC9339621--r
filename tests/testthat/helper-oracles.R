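# Independent pure-loop re-implementations of every network stage, written
# directly from the layer definitions. These never share code with the
# package internals; tests compare the two routes.

oracleTemporalConv <- function(f, kernel, bias, s) {
  n <- dim(f)[1]; tl <- dim(f)[2]; cIn <- dim(f)[3]
  w <- dim(kernel)[1]; cOut <- dim(kernel)[3]
  tc <- tl - w + 1
  a <- array(0, c(n, tc, cOut))
  for (x in 1:n) for (t in 1:tc) for (j in 1:cOut) {
    acc <- bias[j]
    for (d in 1:w) for (i in 1:cIn)
      acc <- acc + f[x, t + d - 1, i] * kernel[d, i, j]
    a[x, t, j] <- max(acc, 0)
  }
  tp <- tc %/% s
  out <- array(0, c(n, tp, cOut))
  for (x in 1:n) for (u in 1:tp) for (j in 1:cOut)
    out[x, u, j] <- mean(a[x, ((u - 1) * s + 1):(u * s), j])
  out
}

oracleGraphConv <- function(f, S, W, bias) {
  n <- dim(f)[1]; tp <- dim(f)[2]; cIn <- dim(f)[3]; cOut <- ncol(W)
  out <- array(0, c(n, tp, cOut))
  for (t in 1:tp) for (x in 1:n) for (j in 1:cOut) {
    acc <- bias[j]
    for (m in 1:n) for (i in 1:cIn)
      acc <- acc + S[x, m] * f[m, t, i] * W[i, j]
    out[x, t, j] <- max(acc, 0)
  }
  out
}

oracleAttention <- function(fhat, ha, ba, W1, b1, W2, b2) {
  n <- dim(fhat)[1]; tp <- dim(fhat)[2]; cc <- dim(fhat)[3]
  Ma <- matrix(0, n, cc)
  for (x in 1:n) for (j in 1:cc) {
    acc <- ba[j]
    for (t in 1:tp) acc <- acc + fhat[x, t, j] * ha[t, j]
    Ma[x, j] <- max(acc, 0)
  }
  v <- numeric(n)
  for (x in 1:n) v[x] <- sum(Ma[x, ]) / cc
  q <- nrow(W1)
  d <- numeric(q)
  for (k in 1:q) d[k] <- max(sum(W1[k, ] * v) + b1[k], 0)
  u <- numeric(n)
  for (x in 1:n) u[x] <- max(sum(W2[x, ] * d) + b2[x], 0)
  1 / (1 + exp(-u))
}

oracleApplyAttention <- function(Z, fhat) {
  out <- fhat
  for (x in seq_along(Z)) out[x, , ] <- Z[x] * fhat[x, , ]
  out
}

oracleFuse <- function(a, b) {
  out <- a
  for (k in seq_along(a)) out[k] <- a[k] + b[k]
  out
}

oracleCompressHead <- function(h, U, bu, Wfc, bfc) {
  cL <- dim(h)[3]
  Sc <- numeric(cL)
  for (j in 1:cL) Sc[j] <- sum(h[, , j] * U[, , j]) + bu[j]
  out <- numeric(nrow(Wfc))
  for (k in seq_len(nrow(Wfc))) out[k] <- sum(Wfc[k, ] * Sc) + bfc[k]
  out
}

# full forward chain built only from the oracle stages (default routing:
# fuse temporal features with the attended spatial features)
oracleForward <- function(xmat, S, model) {
  cfg <- model@config
  f <- array(t(xmat), c(cfg$nNodes, cfg$tIn, 1))
  for (l in seq_along(cfg$channels)) {
    pb <- model@params[[l]]
    P <- oracleTemporalConv(f, pb$Kt, pb$bt, cfg$s)
    G2 <- oracleGraphConv(P, S, pb$Wg, pb$bg)
    Z <- oracleAttention(G2, pb$ha, pb$ba, pb$W1, pb$b1, pb$W2, pb$b2)
    f <- oracleFuse(P, oracleApplyAttention(Z, G2))
  }
  ph <- model@params$head
  oracleCompressHead(f, ph$U, ph$bu, ph$Wfc, ph$bfc)
}

oracleAttentionLoss <- function(Z) {
  s <- 0
  for (z in Z) s <- s + z
  m <- s / length(Z)
  v <- 0
  for (z in Z) v <- v + (z - m)^2
  m - v / length(Z)
}

oracleCrossEntropy <- function(scores, y) {
  p <- exp(scores) / sum(exp(scores))
  -log(p[y + 1])
}

# small helpers shared across test files
randomAdjacency <- function(n, lambda = 0.5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(60 * n), 60, n)
  normalizeAdjacency(sparsifyConnectivity(computePearson(x), lambda))
}

tinyLabeledSet <- function(nNodes = 6, T0 = 16, perClass = 4, seed = 5) {
  cfg <- syntheticConfig(nNodes = nNodes, nTimepoints = T0,
                         nSubjectsPerClass = perClass, plantedNodes = 1:2,
                         baseCorrelation = 0.1, effectDelta = 0.5,
                         arCoefficient = 0, noiseSd = 1, seed = seed)
  generateDataset(cfg)
}
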