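#' Construct a deep spatiotemporal attention network
#'
#' Builds the network configuration and initializes its parameters. The
#' architecture stacks one block per entry of \code{channels}; each block
#' applies (i) per-node temporal convolution (kernel width \code{w}, valid
#' padding, summed over input channels) with ReLU and non-overlapping
#' average pooling of window \code{s}, giving the temporal features; (ii)
#' graph convolution over the functional brain network (shared across
#' timepoints) with ReLU, giving the spatial features; (iii) a node
#' attention module that collapses time and channels to one scalar per
#' node and passes it through a bottleneck of width
#' \code{max(1, floor(nNodes / attentionRatio))}, returning a per-node
#' attention map Z in (0,1); and (iv) fusion of the temporal features with
#' the attended spatial features by element-wise sum. After the last block
#' a per-channel kernel spanning the whole node-by-time extent compresses
#' each channel to a scalar, and a fully connected layer maps those
#' scalars to the class scores.
#'
#' The time dimension shrinks as \code{T_{l+1} = floor((T_l - w + 1) / s)};
#' a configuration for which any block's input is shorter than \code{w},
#' or whose final time length is zero, is rejected at construction.
#'
#' All parameters (weights and biases) are initialized from a
#' fan-in-scaled uniform distribution (bounds \code{1/sqrt(fan_in)}),
#' deterministically from \code{seed}.
#'
#' @param nNodes number of brain nodes n.
#' @param tIn number of input timepoints T.
#' @param channels integer vector of output channels per block
#'   (default \code{c(8, 16, 32)}).
#' @param w temporal convolution kernel width (default 5).
#' @param s average pooling window / stride (default 2).
#' @param attentionRatio bottleneck down-sampling ratio r (default 16).
#' @param nClasses number of classes (default 2).
#' @param seed integer seed for parameter initialization.
#' @param noAttention if TRUE the attention map is pinned to the constant
#'   1 vector and the attention loss is dropped (the ablation arm).
#' @param fuseRaw if TRUE fusion sums the temporal and raw (un-attended)
#'   spatial features; the default routes the attended spatial features
#'   into the fusion.
#' @return A \linkS4class{DstanModel}.
#' @export
dstanModel <- function(nNodes, tIn, channels = c(8L, 16L, 32L), w = 5L,
                       s = 2L, attentionRatio = 16L, nClasses = 2L,
                       seed = 1L, noAttention = FALSE, fuseRaw = FALSE) {
  nNodes <- as.integer(nNodes); tIn <- as.integer(tIn)
  channels <- as.integer(channels); w <- as.integer(w); s <- as.integer(s)
  attentionRatio <- as.integer(attentionRatio)
  stopifnot(length(channels) >= 1L, all(channels >= 1L), w >= 1L, s >= 1L,
            nNodes >= 2L, nClasses >= 2L)
  if (attentionRatio < 1L || attentionRatio > nNodes)
    stop("attentionRatio must lie in 1..nNodes")
  # shape contract: reject invalid (w, s) at construction, not at run time
  timeLengths <- integer(length(channels) + 1L)
  timeLengths[1L] <- tIn
  for (l in seq_along(channels)) {
    tl <- timeLengths[l]
    if (tl < w)
      stop(sprintf("block %d: input time length %d is shorter than kernel width %d",
                   l, tl, w))
    if (s > tl - w + 1L)
      stop(sprintf("block %d: pooling window %d exceeds convolved length %d",
                   l, s, tl - w + 1L))
    timeLengths[l + 1L] <- (tl - w + 1L) %/% s
  }
  if (timeLengths[length(timeLengths)] < 1L)
    stop("configuration collapses the time dimension to zero")
  q <- max(1L, nNodes %/% attentionRatio)
  cfg <- list(nNodes = nNodes, tIn = tIn, channels = channels, w = w, s = s,
              attentionRatio = attentionRatio, bottleneck = q,
              nClasses = as.integer(nClasses), seed = as.integer(seed),
              noAttention = isTRUE(noAttention), fuseRaw = isTRUE(fuseRaw),
              timeLengths = timeLengths)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(cfg$seed)
  params <- vector("list", length(channels) + 1L)
  cIn <- 1L
  for (l in seq_along(channels)) {
    cOut <- channels[l]
    tp <- timeLengths[l + 1L]
    params[[l]] <- list(
      Kt = initUniform(c(w, cIn, cOut), fanIn = w * cIn),
      bt = initUniform(cOut, fanIn = w * cIn),
      Wg = initUniform(c(cOut, cOut), fanIn = cOut),
      bg = initUniform(cOut, fanIn = cOut),
      ha = initUniform(c(tp, cOut), fanIn = tp),
      ba = initUniform(cOut, fanIn = tp),
      W1 = initUniform(c(q, nNodes), fanIn = nNodes),
      b1 = initUniform(q, fanIn = nNodes),
      W2 = initUniform(c(nNodes, q), fanIn = q),
      b2 = initUniform(nNodes, fanIn = q)
    )
    cIn <- cOut
  }
  cL <- channels[length(channels)]
  tL <- timeLengths[length(timeLengths)]
  params[[length(params)]] <- list(
    U = initUniform(c(nNodes, tL, cL), fanIn = nNodes * tL),
    bu = initUniform(cL, fanIn = nNodes * tL),
    Wfc = initUniform(c(nClasses, cL), fanIn = cL),
    bfc = initUniform(nClasses, fanIn = cL)
  )
  names(params) <- c(sprintf("block%d", seq_along(channels)), "head")
  new("DstanModel", config = cfg, params = params)
}

initUniform <- function(dims, fanIn) {
  a <- 1 / sqrt(fanIn)
  vals <- stats::runif(prod(dims), min = -a, max = a)
  if (length(dims) == 1L && dims == length(vals)) vals else array(vals, dim = dims)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Temporal convolution with average pooling
#'
#' Per node, 1-D valid convolution along time (kernels of width w, summed
#' over input channels), activation, then non-overlapping average pooling
#' with window and stride \code{s}. The output time length is
#' \code{floor((T - w + 1) / s)}.
#'
#' @param f input feature block, array n x T x c_in.
#' @param kernel array w x c_in x c_out of convolution kernels.
#' @param bias numeric vector of length c_out (default zeros).
#' @param s average pooling window (default 1 = no pooling).
#' @param activation \code{"relu"} (default) or \code{"identity"}.
#' @return Feature block n x floor((T-w+1)/s) x c_out.
#' @export
temporalConv <- function(f, kernel, bias = NULL, s = 1L,
                         activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  d <- dim(f); n <- d[1L]; tl <- d[2L]; cIn <- d[3L]
  kd <- dim(kernel); w <- kd[1L]
  if (kd[2L] != cIn)
    stop(sprintf("kernel expects %d input channels, feature block has %d",
                 kd[2L], cIn))
  if (tl < w)
    stop(sprintf("time length %d is shorter than kernel width %d", tl, w))
  cOut <- kd[3L]
  if (is.null(bias)) bias <- numeric(cOut)
  cache <- tconvForward(f, kernel, bias, s, n, tl, w, cIn, cOut,
                        linear = (activation == "identity"))
  cache$P
}

# internal forward with cache for backprop
tconvForward <- function(f, kernel, bias, s, n, tl, w, cIn, cOut,
                         linear = FALSE) {
  tc <- tl - w + 1L
  unf <- matrix(0, n * tc, w * cIn)
  for (i in seq_len(cIn)) {
    fi <- f[, , i, drop = FALSE]
    dim(fi) <- c(n, tl)
    for (d in seq_len(w))
      unf[, (i - 1L) * w + d] <- fi[, d:(d + tc - 1L)]
  }
  kmat <- matrix(0, w * cIn, cOut)
  for (i in seq_len(cIn)) kmat[(i - 1L) * w + seq_len(w), ] <- kernel[, i, ]
  a1 <- unf %*% kmat
  a1 <- sweep(a1, 2L, bias, `+`)
  a2 <- if (linear) a1 else relu(a1)
  a2arr <- array(a2, dim = c(n, tc, cOut))
  tp <- tc %/% s
  if (s == 1L) {
    P <- a2arr
  } else {
    P <- array(0, dim = c(n, tp, cOut))
    for (v in seq_len(s))
      P <- P + a2arr[, seq(v, tp * s, by = s), , drop = FALSE]
    P <- P / s
  }
  list(P = P, unf = unf, kmat = kmat, a1pos = (a1 > 0), tc = tc, tp = tp)
}

#' Graph convolution over the functional brain network
#'
#' For every timepoint t, computes \eqn{\sigma(S f_t W)} where S is the
#' normalized adjacency, \eqn{f_t} the n x c feature slice and W the
#' channel-mixing weight. The time dimension is preserved.
#'
#' @param f input feature block, array n x T x c_in.
#' @param S an n x n matrix or \linkS4class{NormalizedAdjacency}.
#' @param W weight matrix c_in x c_out.
#' @param bias numeric vector of length c_out (default zeros).
#' @param activation \code{"relu"} (default) or \code{"identity"}.
#' @return Feature block n x T x c_out.
#' @export
graphConv <- function(f, S, W, bias = NULL,
                      activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (is(S, "NormalizedAdjacency")) S <- S@values
  d <- dim(f); n <- d[1L]; tp <- d[2L]; cIn <- d[3L]
  if (nrow(S) != n)
    stop(sprintf("adjacency has %d nodes but feature block has %d", nrow(S), n))
  if (nrow(W) != cIn)
    stop(sprintf("weight expects %d input channels, feature block has %d",
                 nrow(W), cIn))
  cOut <- ncol(W)
  if (is.null(bias)) bias <- numeric(cOut)
  gconvForward(f, S, W, bias, n, tp, cIn, cOut,
               linear = (activation == "identity"))$G2
}

gconvForward <- function(f, S, W, bias, n, tp, cIn, cOut, linear = FALSE) {
  sp <- S %*% matrix(f, n, tp * cIn)          # n x (tp*cIn)
  spmat <- matrix(array(sp, c(n, tp, cIn)), n * tp, cIn)
  g1 <- spmat %*% W
  g1 <- sweep(g1, 2L, bias, `+`)
  g2 <- if (linear) g1 else relu(g1)
  list(G2 = array(g2, c(n, tp, cOut)), g1pos = (g1 > 0), spmat = spmat)
}

#' Node attention map
#'
#' Integrates the time and channel information of each node into a scalar
#' and maps it through a squeeze-and-excitation style bottleneck: (i) per
#' channel, a learned kernel spanning the whole time axis collapses time,
#' with ReLU; (ii) channel-wise mean; (iii) fully connected down-map to
#' \code{max(1, floor(n/r))} units with ReLU; (iv) fully connected up-map
#' back to n units with ReLU; (v) sigmoid, giving one attention weight in
#' (0, 1) per node.
#'
#' @param fhat feature block n x T' x c (the graph-convolution output).
#' @param ha time-collapse kernels, matrix T' x c.
#' @param ba bias vector of length c.
#' @param W1,b1 down-map weight (q x n) and bias (length q).
#' @param W2,b2 up-map weight (n x q) and bias (length n).
#' @return Numeric attention map Z of length n with entries in (0, 1).
#' @export
nodeAttention <- function(fhat, ha, ba, W1, b1, W2, b2) {
  attForward(fhat, ha, ba, W1, b1, W2, b2)$Z
}

attForward <- function(fhat, ha, ba, W1, b1, W2, b2) {
  d <- dim(fhat); n <- d[1L]; tp <- d[2L]; cc <- d[3L]
  if (nrow(ha) != tp || ncol(ha) != cc)
    stop("attention time-collapse kernel does not match the feature block")
  pre <- matrix(0, n, cc)
  for (j in seq_len(cc)) {
    fj <- fhat[, , j, drop = FALSE]; dim(fj) <- c(n, tp)
    pre[, j] <- fj %*% ha[, j] + ba[j]
  }
  Ma <- relu(pre)
  vbar <- rowMeans(Ma)
  d1 <- as.numeric(W1 %*% vbar + b1)
  d2 <- relu(d1)
  u1 <- as.numeric(W2 %*% d2 + b2)
  u2 <- relu(u1)
  Z <- sigmoid(u2)
  list(Z = Z, prepos = (pre > 0), vbar = vbar, d1pos = (d1 > 0), d2 = d2,
       u1pos = (u1 > 0))
}

#' Apply a node attention map to a feature block
#'
#' Multiplies every node's features by its attention weight:
#' \code{out[x, t, c] = Z[x] * fhat[x, t, c]}.
#'
#' @param Z attention map of length n.
#' @param fhat feature block n x T' x c.
#' @return Attended feature block of the same shape.
#' @export
applyAttention <- function(Z, fhat) {
  if (length(Z) != dim(fhat)[1L])
    stop("attention map length does not match the node dimension")
  fhat * as.numeric(Z)
}

#' Fuse temporal and spatial features
#'
#' Element-wise sum of two feature blocks of identical shape.
#'
#' @param fTemp,fSpat feature blocks n x T' x c.
#' @return Their element-wise sum.
#' @export
fuseFeatures <- function(fTemp, fSpat) {
  if (!identical(dim(fTemp), dim(fSpat)))
    stop("feature blocks to fuse must have identical shapes")
  fTemp + fSpat
}

#' Compression head and classifier
#'
#' Per channel j, a learned kernel spanning the full node-by-time extent
#' compresses the block to a scalar S_j; a fully connected layer then maps
#' the c_L scalars to unnormalized class scores.
#'
#' @param h final feature block n x T_L x c_L.
#' @param U kernel array n x T_L x c_L.
#' @param bu per-channel bias of length c_L.
#' @param Wfc fully connected weight, nClasses x c_L.
#' @param bfc fully connected bias of length nClasses.
#' @return Numeric vector of class scores.
#' @export
compressHead <- function(h, U, bu, Wfc, bfc) {
  if (!identical(dim(h), dim(U)))
    stop("head kernel does not match the feature block shape")
  cL <- dim(h)[3L]
  Sc <- colSums(matrix(h * U, ncol = cL)) + bu
  as.numeric(Wfc %*% Sc + bfc)
}

# full forward pass for one subject (T x n input matrix), with caches
forwardSubject <- function(xmat, S, model) {
  cfg <- model@config
  pp <- model@params
  L <- length(cfg$channels)
  f <- array(t(xmat), dim = c(cfg$nNodes, cfg$tIn, 1L))
  blocks <- vector("list", L)
  Zmat <- matrix(0, cfg$nNodes, L)
  cIn <- 1L
  for (l in seq_len(L)) {
    pb <- pp[[l]]
    cOut <- cfg$channels[l]
    tl <- cfg$timeLengths[l]
    tcache <- tconvForward(f, pb$Kt, pb$bt, cfg$s, cfg$nNodes, tl, cfg$w,
                           cIn, cOut)
    P <- tcache$P
    tp <- tcache$tp
    gcache <- gconvForward(P, S, pb$Wg, pb$bg, cfg$nNodes, tp, cOut, cOut)
    G2 <- gcache$G2
    if (cfg$noAttention) {
      acache <- NULL
      Z <- rep(1, cfg$nNodes)
      ftil <- G2
    } else {
      acache <- attForward(G2, pb$ha, pb$ba, pb$W1, pb$b1, pb$W2, pb$b2)
      Z <- acache$Z
      ftil <- if (cfg$fuseRaw) G2 else applyAttention(Z, G2)
    }
    h <- P + ftil
    Zmat[, l] <- Z
    blocks[[l]] <- list(fin = f, tcache = tcache, P = P, gcache = gcache,
                        G2 = G2, acache = acache, Z = Z)
    f <- h
    cIn <- cOut
  }
  ph <- pp$head
  Sc <- colSums(matrix(f * ph$U, ncol = dim(f)[3L])) + ph$bu
  scores <- as.numeric(ph$Wfc %*% Sc + ph$bfc)
  list(scores = scores, Zmat = Zmat, blocks = blocks, hL = f, Sc = Sc)
}

#' Forward pass of the network
#'
#' Runs every subject through the stacked spatiotemporal attention blocks
#' and the compression head. Subjects are processed independently (no
#' cross-subject coupling), so batch composition never changes a
#' subject's scores.
#'
#' @param x a \linkS4class{RoiTimeSeriesSet} or a single T x n matrix.
#' @param S a \linkS4class{NormalizedAdjacency} (or plain n x n matrix)
#'   shared by all subjects, or a list of per-subject adjacencies (the
#'   subject-level network option).
#' @param model a \linkS4class{DstanModel}.
#' @return list with \code{scores} (N x nClasses matrix) and
#'   \code{attention} (array n x L x N of per-block node attention maps).
#' @export
dstanForward <- function(x, S, model) {
  cfg <- model@config
  mats <- if (is(x, "RoiTimeSeriesSet")) {
    lapply(seq_len(nSubjects(x)), function(i) subjectSeries(x, i))
  } else list(as.matrix(x))
  for (i in seq_along(mats)) {
    d <- dim(mats[[i]])
    if (d[1L] != cfg$tIn || d[2L] != cfg$nNodes)
      stop(sprintf("subject %d is %d x %d but the model expects %d x %d",
                   i, d[1L], d[2L], cfg$tIn, cfg$nNodes))
  }
  N <- length(mats)
  Ss <- resolveAdjacency(S, N)
  L <- length(cfg$channels)
  scores <- matrix(0, N, cfg$nClasses)
  attention <- array(0, dim = c(cfg$nNodes, L, N))
  for (i in seq_len(N)) {
    fw <- forwardSubject(mats[[i]], Ss[[i]], model)
    scores[i, ] <- fw$scores
    attention[, , i] <- fw$Zmat
  }
  list(scores = scores, attention = attention)
}

# one shared adjacency or a per-subject list -> list of plain matrices
resolveAdjacency <- function(S, N) {
  if (is.list(S)) {
    if (length(S) != N)
      stop(sprintf("got %d per-subject adjacencies for %d subjects",
                   length(S), N))
    lapply(S, function(s) if (is(s, "NormalizedAdjacency")) s@values else s)
  } else {
    if (is(S, "NormalizedAdjacency")) S <- S@values
    rep(list(S), N)
  }
}
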