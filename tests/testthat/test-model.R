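test_that("shape contract follows the floor((T-w+1)/s) recursion", {
  m <- dstanModel(nNodes = 90, tIn = 80, channels = c(8, 16, 32),
                  w = 5, s = 2, attentionRatio = 16, seed = 1)
  expect_equal(m@config$timeLengths, c(80L, 38L, 17L, 6L))
  expect_equal(m@config$bottleneck, 5L)

  # invalid (w, s) rejected at construction, not at run time
  expect_error(dstanModel(nNodes = 10, tIn = 12, channels = c(2, 2, 2),
                          w = 5, s = 2, attentionRatio = 2),
               "shorter than kernel width")
  expect_error(dstanModel(nNodes = 10, tIn = 6, channels = 2, w = 5, s = 3,
                          attentionRatio = 2), "pooling window")
  expect_error(dstanModel(nNodes = 10, tIn = 20, channels = 2, w = 5, s = 2,
                          attentionRatio = 11), "attentionRatio")
})

test_that("temporal convolution matches shapes, constants and the oracle", {
  # shape: 90 x 80 x 1 with w=5, s=2 -> 90 x 38 x 8
  f <- array(rnorm(90 * 80), c(90, 80, 1))
  K <- array(rnorm(5 * 1 * 8, sd = 0.3), c(5, 1, 8))
  out <- temporalConv(f, K, s = 2)
  expect_equal(dim(out), c(90L, 38L, 8L))

  # constant input, identity activation, kernel summing to k -> constant k*c
  fc <- array(2, c(3, 10, 1))
  Kc <- array(0.5, c(4, 1, 2))      # each kernel sums to 2
  outc <- temporalConv(fc, Kc, s = 2, activation = "identity")
  expect_equal(unname(as.vector(outc)), rep(4, length(outc)))

  # random instance vs pure-loop oracle
  set.seed(8)
  f2 <- array(rnorm(4 * 10 * 2), c(4, 10, 2))
  K2 <- array(rnorm(3 * 2 * 5), c(3, 2, 5))
  b2 <- rnorm(5)
  expect_lt(max(abs(temporalConv(f2, K2, b2, s = 2) -
                    oracleTemporalConv(f2, K2, b2, 2))), 1e-6)

  expect_error(temporalConv(array(0, c(3, 2, 1)), K2), "channels")
  expect_error(temporalConv(array(0, c(3, 2, 2)), K2), "shorter")
})

test_that("graph convolution matches identity case, zero case and oracle", {
  set.seed(9)
  f <- array(rnorm(5 * 6 * 3), c(5, 6, 3))
  W <- matrix(rnorm(3 * 4), 3, 4)
  b <- rnorm(4)

  # S = I, identity activation -> per-timepoint channel mixing f_t W
  outI <- graphConv(f, diag(5), W, b, activation = "identity")
  manual <- array(0, c(5, 6, 4))
  for (t in 1:6) manual[, t, ] <- f[, t, ] %*% W + rep(b, each = 5)
  expect_lt(max(abs(outI - manual)), 1e-12)

  # W = 0, zero bias -> ReLU(0) = 0
  expect_equal(graphConv(f, diag(5), matrix(0, 3, 4), numeric(4)),
               array(0, c(5, 6, 4)))

  # random instance vs dense pure-loop oracle
  S <- as.matrix(randomAdjacency(5, lambda = 0.4, seed = 2))
  expect_lt(max(abs(graphConv(f, S, W, b) - oracleGraphConv(f, S, W, b))),
            1e-6)

  expect_error(graphConv(f, diag(4), W), "nodes")
  expect_error(graphConv(f, diag(5), matrix(0, 2, 4)), "channels")
})

test_that("node attention respects its bottleneck and degenerate cases", {
  # zero input, zero biases -> Z = sigmoid(0) = 0.5 everywhere
  n <- 6; tp <- 4; cc <- 3; q <- 3
  Z0 <- nodeAttention(array(0, c(n, tp, cc)), matrix(1, tp, cc), numeric(cc),
                      matrix(1, q, n), numeric(q), matrix(1, n, q),
                      numeric(n))
  expect_equal(Z0, rep(0.5, n))

  # identical node rows -> identical attention values
  set.seed(10)
  row <- matrix(rnorm(tp * cc), tp, cc)
  fh <- array(0, c(n, tp, cc))
  for (x in 1:n) fh[x, , ] <- row
  ha <- matrix(rnorm(tp * cc), tp, cc); ba <- rnorm(cc)
  W1 <- matrix(rnorm(q * n), q, n); b1 <- rnorm(q)
  W2 <- matrix(rnorm(n * q), n, q); b2 <- rnorm(n)
  # equal per-node scalars enter the FC maps; Z then varies only through
  # node-specific FC weights, so re-running with equal weights gives equal Z
  W1c <- matrix(1, q, n); W2c <- matrix(1, n, q)
  Zc <- nodeAttention(fh, ha, ba, W1c, numeric(q), W2c, numeric(n))
  expect_equal(max(Zc) - min(Zc), 0)

  # random instance vs pure-loop oracle, bounds strict
  fh2 <- array(rnorm(n * tp * cc), c(n, tp, cc))
  Z <- nodeAttention(fh2, ha, ba, W1, b1, W2, b2)
  expect_lt(max(abs(Z - oracleAttention(fh2, ha, ba, W1, b1, W2, b2))), 1e-12)
  expect_true(all(Z > 0 & Z < 1))
})

test_that("attention application and fusion match their element-wise forms", {
  set.seed(12)
  fh <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  expect_equal(applyAttention(rep(1, 4), fh), fh)
  expect_equal(applyAttention(rep(0, 4), fh), fh * 0)
  Z <- c(0.999, 0.001, 0.001, 0.001)
  expect_lt(max(abs(applyAttention(Z, fh) - oracleApplyAttention(Z, fh))),
            1e-15)
  a <- array(rnorm(60), c(4, 5, 3)); b <- array(rnorm(60), c(4, 5, 3))
  expect_equal(fuseFeatures(a, b), fuseFeatures(b, a))
  expect_equal(fuseFeatures(a, b * 0), a)
  expect_equal(fuseFeatures(a, b), oracleFuse(a, b))
  expect_error(fuseFeatures(a, array(0, c(4, 5, 2))), "identical shapes")
})

test_that("compression head reduces channels to scalars then class scores", {
  set.seed(13)
  h <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  # uniform averaging kernels + identity-like FC -> global channel means
  U <- array(1 / 15, c(5, 3, 4))
  Wfc <- matrix(0, 2, 4); Wfc[1, 2] <- 1; Wfc[2, 4] <- 1
  sc <- compressHead(h, U, numeric(4), Wfc, numeric(2))
  expect_equal(sc, c(mean(h[, , 2]), mean(h[, , 4])))

  # random instance vs flatten-and-dot oracle
  U2 <- array(rnorm(60), c(5, 3, 4)); bu <- rnorm(4)
  W2 <- matrix(rnorm(8), 2, 4); b2 <- rnorm(2)
  expect_lt(max(abs(compressHead(h, U2, bu, W2, b2) -
                    oracleCompressHead(h, U2, bu, W2, b2))), 1e-6)

  # channels (8,16,32): 32 scalars before the FC layer
  m <- dstanModel(nNodes = 10, tIn = 80, channels = c(8, 16, 32), w = 5,
                  s = 2, attentionRatio = 2, seed = 1)
  expect_equal(dim(m@params$head$U)[3], 32L)
})

test_that("full forward pass agrees with the independent loop implementation", {
  m <- dstanModel(nNodes = 4, tIn = 10, channels = c(2, 3), w = 3, s = 2,
                  attentionRatio = 2, seed = 21)
  S <- as.matrix(randomAdjacency(4, lambda = 0.3, seed = 4))
  set.seed(22)
  x <- matrix(rnorm(40), 10, 4)
  fw <- dstanForward(x, S, m)
  expect_lt(max(abs(fw$scores[1, ] - oracleForward(x, S, m))), 1e-5)
  expect_true(all(fw$attention > 0 & fw$attention < 1))
})

test_that("forward pass has no cross-subject coupling and is deterministic", {
  d <- tinyLabeledSet(nNodes = 6, T0 = 16, perClass = 4, seed = 7)
  S <- buildFbn(d, 0.5)$adjacency
  m <- dstanModel(nNodes = 6, tIn = 16, channels = c(2, 2), w = 3, s = 2,
                  attentionRatio = 2, seed = 2)
  full <- dstanForward(d, S, m)
  single <- dstanForward(subjectSeries(d, 3), S, m)
  expect_equal(single$scores[1, ], full$scores[3, ], tolerance = 1e-15)
  again <- dstanForward(d, S, m)
  expect_identical(full$scores, again$scores)
  expect_identical(full$attention, again$attention)

  # paper-scale settings construct and run
  mBig <- dstanModel(nNodes = 90, tIn = 80, channels = c(8, 16, 32), w = 5,
                     s = 2, attentionRatio = 16, seed = 1)
  set.seed(1)
  xBig <- matrix(rnorm(80 * 90), 80, 90)
  sc <- dstanForward(xBig, diag(90), mBig)$scores
  expect_equal(dim(sc), c(1L, 2L))
  expect_true(all(is.finite(sc)))
})

test_that("analytic gradients match central finite differences", {
  m <- dstanModel(nNodes = 4, tIn = 10, channels = c(2, 2), w = 3, s = 2,
                  attentionRatio = 2, seed = 31)
  S <- as.matrix(randomAdjacency(4, lambda = 0.3, seed = 5))
  set.seed(32)
  x <- matrix(rnorm(40), 10, 4)
  fw <- dstan:::forwardSubject(x, S, m)
  bk <- dstan:::subjectBackward(fw, 1L, S, m, attWeight = 1)
  lossAt <- function(mod) {
    f <- dstan:::forwardSubject(x, S, mod)
    ce <- dstan:::crossEntropy(f$scores, 1L)
    ce + attentionLoss(f$Zmat)
  }
  eps <- 1e-6
  set.seed(33)
  for (nm in names(m@params)) {
    for (pn in names(m@params[[nm]])) {
      p <- m@params[[nm]][[pn]]
      for (k in sample(length(p), min(4, length(p)))) {
        mp <- m; mp@params[[nm]][[pn]][k] <- p[k] + eps
        mm <- m; mm@params[[nm]][[pn]][k] <- p[k] - eps
        num <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
        expect_equal(bk$grads[[nm]][[pn]][k], num, tolerance = 1e-4,
                     label = paste("grad", nm, pn, k))
      }
    }
  }
})

test_that("every parameter tensor receives gradient from the loss on a batch", {
  # wiring check: no stage is disconnected from the loss. Individual scalar
  # weights feeding ReLU units that are inactive across the whole batch
  # legitimately get zero gradient, so the assertion is per tensor.
  d <- tinyLabeledSet(nNodes = 6, T0 = 16, perClass = 4, seed = 8)
  S <- as.matrix(buildFbn(d, 0.5)$adjacency)
  m <- dstanModel(nNodes = 6, tIn = 16, channels = c(2, 2), w = 3, s = 2,
                  attentionRatio = 2, seed = 3)
  total <- dstan:::zeroGrads(m)
  for (i in seq_len(nSubjects(d))) {
    fw <- dstan:::forwardSubject(subjectSeries(d, i), S, m)
    bk <- dstan:::subjectBackward(fw, subjectLabels(d)[i], S, m, 1)
    total <- dstan:::addGrads(total, bk$grads)
  }
  for (nm in names(total)) {
    for (pn in names(total[[nm]])) {
      expect_true(any(total[[nm]][[pn]] != 0),
                  label = paste("gradient reaches", nm, pn))
    }
  }
})

test_that("the No-Att variant pins Z to one and bypasses the attention path", {
  d <- tinyLabeledSet(nNodes = 6, T0 = 16, perClass = 2, seed = 9)
  S <- buildFbn(d, 0.5)$adjacency
  m <- dstanModel(nNodes = 6, tIn = 16, channels = c(2, 2), w = 3, s = 2,
                  attentionRatio = 2, seed = 4, noAttention = TRUE)
  fw <- dstanForward(d, S, m)
  expect_true(all(fw$attention == 1))
})
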