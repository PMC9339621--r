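#' Training configuration
#'
#' Defaults follow the study recipe: SGD with momentum 0.1 and weight
#' decay 1e-4, 90 epochs, initial learning rate 0.1 halved every 30
#' epochs, batch size 32.
#'
#' @param epochs number of passes over the training set (default 90).
#' @param batchSize mini-batch size (default 32).
#' @param learningRate initial learning rate (default 0.1).
#' @param lrDecayFactor multiplicative decay (default 0.5).
#' @param lrDecayEvery decay period in epochs (default 30).
#' @param momentum SGD momentum (default 0.1).
#' @param weightDecay L2 weight decay coefficient (default 1e-4).
#' @param attentionWeight weight of the attention loss term (default 1).
#' @param seed integer seed governing batch shuffling.
#' @return A validated list of class \code{TrainConfig}.
#' @export
trainConfig <- function(epochs = 90L, batchSize = 32L, learningRate = 0.1,
                        lrDecayFactor = 0.5, lrDecayEvery = 30L,
                        momentum = 0.1, weightDecay = 1e-4,
                        attentionWeight = 1, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
              learningRate = learningRate, lrDecayFactor = lrDecayFactor,
              lrDecayEvery = as.integer(lrDecayEvery), momentum = momentum,
              weightDecay = weightDecay, attentionWeight = attentionWeight,
              seed = as.integer(seed))
  stopifnot(cfg$epochs >= 1L, cfg$batchSize >= 1L, cfg$learningRate >= 0,
            cfg$lrDecayFactor > 0, cfg$lrDecayFactor <= 1,
            cfg$lrDecayEvery >= 1L, cfg$momentum >= 0, cfg$momentum < 1,
            cfg$weightDecay >= 0)
  class(cfg) <- "TrainConfig"
  cfg
}

#' Learning rate at a given epoch
#'
#' \code{learningRate * lrDecayFactor^floor((epoch - 1) / lrDecayEvery)}:
#' with the defaults, epochs 1-30 run at 0.1, 31-60 at 0.05, 61-90 at
#' 0.025.
#'
#' @param tcfg a \code{\link{trainConfig}}.
#' @param epoch epoch number (1-based).
#' @return The learning rate.
#' @export
learningRateAt <- function(tcfg, epoch) {
  tcfg$learningRate * tcfg$lrDecayFactor^((epoch - 1L) %/% tcfg$lrDecayEvery)
}

#' Train the network with mini-batch SGD
#'
#' Momentum SGD with L2 weight decay on every parameter and a stepwise
#' learning-rate schedule. Gradients are batch means of the per-subject
#' gradients of cross-entropy plus the attention loss. The run is fully
#' deterministic given the model seed and \code{tcfg$seed}; batch order is
#' reshuffled each epoch from a seed derived from the epoch index.
#'
#' @param data a labeled \linkS4class{RoiTimeSeriesSet} (training set).
#' @param S a \linkS4class{NormalizedAdjacency} (or plain matrix), or a
#'   list of per-subject adjacencies aligned with \code{data}.
#' @param model an initialized \linkS4class{DstanModel}.
#' @param tcfg a \code{\link{trainConfig}}.
#' @param verbose print one line per \code{verbose} epochs (0 = silent).
#' @return A \linkS4class{DstanFit} holding the trained model and the
#'   per-epoch history (lr, ce, att, total, train_acc).
#' @export
trainDstan <- function(data, S, model, tcfg = trainConfig(), verbose = 0L) {
  stopifnot(is(data, "RoiTimeSeriesSet"))
  if (is.null(subjectLabels(data)))
    stop("training data must carry labels")
  if (nSubjects(data) < 1L) stop("training data is empty")
  Ss <- resolveAdjacency(S, nSubjects(data))
  cfg <- model@config
  if (nTimepoints(data) != cfg$tIn || nNodes(data) != cfg$nNodes)
    stop("data dimensions do not match the model configuration")
  N <- nSubjects(data)
  labels <- subjectLabels(data)
  mats <- lapply(seq_len(N), function(i) subjectSeries(data, i))
  attW <- if (cfg$noAttention) 0 else tcfg$attentionWeight

  params <- model@params
  velocity <- zeroGrads(model)
  hist <- data.frame(epoch = seq_len(tcfg$epochs), lr = NA_real_,
                     ce = NA_real_, att = NA_real_, total = NA_real_,
                     train_acc = NA_real_)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))

  for (epoch in seq_len(tcfg$epochs)) {
    lr <- learningRateAt(tcfg, epoch)
    set.seed(tcfg$seed + 7919L * epoch)
    ord <- sample.int(N)
    starts <- seq(1L, N, by = tcfg$batchSize)
    epCe <- 0; epAtt <- 0; epCorrect <- 0L
    for (b in starts) {
      idx <- ord[b:min(b + tcfg$batchSize - 1L, N)]
      bs <- length(idx)
      gsum <- NULL
      for (i in idx) {
        fw <- forwardSubject(mats[[i]], Ss[[i]], modelWith(model, params))
        bk <- subjectBackward(fw, labels[i], Ss[[i]], modelWith(model, params),
                              attWeight = attW)
        gsum <- if (is.null(gsum)) bk$grads else addGrads(gsum, bk$grads)
        epCe <- epCe + bk$ce
        epAtt <- epAtt + bk$att
        if (bk$pred == labels[i]) epCorrect <- epCorrect + 1L
      }
      g <- scaleGrads(gsum, 1 / bs)
      for (nm in names(params)) {
        for (pn in names(params[[nm]])) {
          gr <- g[[nm]][[pn]] + tcfg$weightDecay * params[[nm]][[pn]]
          velocity[[nm]][[pn]] <- tcfg$momentum * velocity[[nm]][[pn]] + gr
          params[[nm]][[pn]] <- params[[nm]][[pn]] - lr * velocity[[nm]][[pn]]
        }
      }
    }
    epCe <- epCe / N
    epAtt <- attW * epAtt / N
    total <- epCe + epAtt
    if (!is.finite(total))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    hist[epoch, c("lr", "ce", "att", "total", "train_acc")] <-
      c(lr, epCe, epAtt, total, epCorrect / N)
    if (verbose > 0L && (epoch %% verbose == 0L || epoch == 1L))
      message(sprintf("epoch %3d  lr %.4g  ce %.4f  att %.4f  total %.4f  acc %.1f%%",
                      epoch, lr, epCe, epAtt, total, 100 * epCorrect / N))
  }
  fitted <- modelWith(model, params)
  new("DstanFit", model = fitted, history = hist, trainConfig = unclass(tcfg))
}

# model with replaced parameters
modelWith <- function(model, params) {
  model@params <- params
  model
}
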