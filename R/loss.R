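#' Attention loss of one node attention map
#'
#' \code{mean(Z) - var(Z)} over the n nodes, with the population variance
#' (denominator n). Minimizing it drives the map toward low overall
#' attention with high spread, i.e. a few strongly attended nodes.
#' When a model returns one map per block (a matrix with one column per
#' block), the per-sample loss is the mean over blocks.
#'
#' @param Z numeric attention map of length n with entries in (0, 1), or
#'   an n x L matrix of per-block maps.
#' @return The attention loss (a scalar).
#' @export
attentionLoss <- function(Z) {
  if (is.matrix(Z))
    return(mean(apply(Z, 2L, attentionLoss)))
  zbar <- mean(Z)
  zbar - mean((Z - zbar)^2)
}

# numerically stable per-sample softmax cross-entropy
crossEntropy <- function(scores, y) {
  m <- max(scores)
  lse <- m + log(sum(exp(scores - m)))
  lse - scores[y + 1L]
}

#' Total training objective
#'
#' Sum of the mean softmax cross-entropy over the batch and the mean
#' per-sample attention loss (weighted by \code{attWeight}).
#'
#' @param scores N x nClasses matrix of unnormalized class scores.
#' @param labels integer vector in \{0, 1\} of length N.
#' @param Zs list of length N of attention maps (vector or n x L matrix
#'   per subject), or NULL to drop the attention term (the ablation arm).
#' @param attWeight weight of the attention term (default 1).
#' @return list with components \code{ce}, \code{att} and \code{total}
#'   (\code{total = ce + att} where \code{att} already includes the
#'   weight).
#' @export
totalLoss <- function(scores, labels, Zs = NULL, attWeight = 1) {
  scores <- rbind(scores)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  if (nrow(scores) != length(labels))
    stop("scores and labels are not batch-aligned")
  ce <- mean(vapply(seq_len(nrow(scores)),
                    function(i) crossEntropy(scores[i, ], labels[i]),
                    numeric(1)))
  att <- if (is.null(Zs)) 0 else
    attWeight * mean(vapply(Zs, attentionLoss, numeric(1)))
  list(ce = ce, att = att, total = ce + att)
}
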