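# Hand-derived reverse-mode gradients for the network. Every forward
# stage in model.R caches exactly what its adjoint needs; the analytic
# gradients are validated against central finite differences in the test
# suite.

# zero-filled parameter structure matching model@params
zeroGrads <- function(model) {
  rapply(model@params, function(p) {
    z <- p; z[] <- 0; z
  }, how = "replace")
}

addGrads <- function(a, b) {
  for (nm in names(a)) {
    for (pn in names(a[[nm]])) a[[nm]][[pn]] <- a[[nm]][[pn]] + b[[nm]][[pn]]
  }
  a
}

scaleGrads <- function(g, f) {
  rapply(g, function(p) p * f, how = "replace")
}

# Per-subject loss and gradients. y in {0,1}; attWeight scales the
# attention term; returns the gradient of
#   ce(scores, y) + attWeight * mean_l (mean(Z_l) - varp(Z_l))
# with respect to every parameter.
subjectBackward <- function(fw, y, S, model, attWeight = 1) {
  cfg <- model@config
  pp <- model@params
  L <- length(cfg$channels)
  n <- cfg$nNodes
  grads <- zeroGrads(model)

  # softmax cross-entropy
  sc <- fw$scores
  p <- exp(sc - max(sc))
  p <- p / sum(p)
  ce <- -log(p[y + 1L])
  dscores <- p
  dscores[y + 1L] <- dscores[y + 1L] - 1

  # head
  ph <- pp$head
  cL <- length(fw$Sc)
  grads$head$Wfc <- outer(dscores, fw$Sc)
  grads$head$bfc <- dscores
  dSc <- as.numeric(t(ph$Wfc) %*% dscores)
  hL <- fw$hL
  dU <- hL
  for (j in seq_len(cL)) dU[, , j] <- dSc[j] * hL[, , j]
  grads$head$U <- dU
  grads$head$bu <- dSc
  dh <- hL
  for (j in seq_len(cL)) dh[, , j] <- dSc[j] * ph$U[, , j]

  attLossVal <- 0
  for (l in rev(seq_len(L))) {
    bl <- fw$blocks[[l]]
    pb <- pp[[l]]
    cOut <- cfg$channels[l]
    tp <- bl$tcache$tp
    cIn <- if (l == 1L) 1L else cfg$channels[l - 1L]

    # fuse: h = P + ftil
    dP <- dh
    Z <- bl$Z
    G2 <- bl$G2
    if (cfg$noAttention) {
      dG2 <- dh
      dZ <- NULL
    } else {
      if (cfg$fuseRaw) {
        dG2 <- dh
        dZ <- numeric(n)
      } else {
        # ftil = Z * G2 (broadcast over time and channels)
        dZ <- as.numeric(rowSums(matrix(dh * G2, nrow = n)))
        dG2 <- dh * as.numeric(Z)
      }
      # attention loss: mean over blocks of mean(Z) - varp(Z)
      zbar <- mean(Z)
      attLossVal <- attLossVal + (zbar - mean((Z - zbar)^2)) / L
      dZ <- dZ + attWeight * (1 / n - 2 * (Z - zbar) / n) / L
    }

    if (!cfg$noAttention) {
      ac <- bl$acache
      du2 <- dZ * Z * (1 - Z)
      du1 <- du2 * ac$u1pos
      grads[[l]]$W2 <- outer(du1, ac$d2)
      grads[[l]]$b2 <- du1
      dd2 <- as.numeric(t(pb$W2) %*% du1)
      dd1 <- dd2 * ac$d1pos
      grads[[l]]$W1 <- outer(dd1, ac$vbar)
      grads[[l]]$b1 <- dd1
      dv <- as.numeric(t(pb$W1) %*% dd1)
      dMa <- matrix(dv / cOut, n, cOut)
      dpre <- dMa * ac$prepos
      dha <- pb$ha; dha[] <- 0
      for (j in seq_len(cOut)) {
        g2j <- G2[, , j, drop = FALSE]; dim(g2j) <- c(n, tp)
        dha[, j] <- as.numeric(crossprod(g2j, dpre[, j]))
        dG2[, , j] <- dG2[, , j] + outer(dpre[, j], pb$ha[, j])
      }
      grads[[l]]$ha <- dha
      grads[[l]]$ba <- colSums(dpre)
    }

    # graph conv backward
    gc <- bl$gcache
    dG1 <- dG2 * array(gc$g1pos, dim = dim(dG2))
    dG1mat <- matrix(dG1, n * tp, cOut)
    grads[[l]]$Wg <- crossprod(gc$spmat, dG1mat)
    grads[[l]]$bg <- colSums(dG1mat)
    B <- dG1mat %*% t(pb$Wg)                       # (n*tp) x cOut
    dPg <- S %*% matrix(array(B, c(n, tp, cOut)), n, tp * cOut)
    dP <- dP + array(dPg, c(n, tp, cOut))

    # pooling backward
    tcc <- bl$tcache$tc
    dA2 <- array(0, dim = c(n, tcc, cOut))
    if (cfg$s == 1L) {
      dA2[, seq_len(tp), ] <- dP
    } else {
      for (v in seq_len(cfg$s))
        dA2[, seq(v, tp * cfg$s, by = cfg$s), ] <- dP / cfg$s
    }

    # temporal conv backward
    dA1 <- dA2 * array(bl$tcache$a1pos, dim = c(n, tcc, cOut))
    dA1mat <- matrix(dA1, n * tcc, cOut)
    dKmat <- crossprod(bl$tcache$unf, dA1mat)
    dKt <- pb$Kt; dKt[] <- 0
    for (i in seq_len(cIn))
      dKt[, i, ] <- dKmat[(i - 1L) * cfg$w + seq_len(cfg$w), ]
    grads[[l]]$Kt <- dKt
    grads[[l]]$bt <- colSums(dA1mat)

    if (l > 1L) {
      dunf <- dA1mat %*% t(bl$tcache$kmat)
      tl <- cfg$timeLengths[l]
      df <- array(0, dim = c(n, tl, cIn))
      for (i in seq_len(cIn)) {
        for (d in seq_len(cfg$w)) {
          df[, d:(d + tcc - 1L), i] <- df[, d:(d + tcc - 1L), i] +
            matrix(dunf[, (i - 1L) * cfg$w + d], n, tcc)
        }
      }
      dh <- df
    }
  }

  list(grads = grads, ce = ce, att = attLossVal,
       pred = which.max2(fw$scores))
}

# argmax with ties broken toward class 0
which.max2 <- function(sc) {
  if (sc[2L] > sc[1L]) 1L else 0L
}
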