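#' @import methods
#' @importFrom stats cor rnorm var sd filter quantile
#' @importFrom utils head read.table write.table
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Labeled set of ROI time series
#'
#' Container for a cohort of subjects, each observed as a T x n matrix of
#' BOLD signal (rows = timepoints, columns = ROIs / brain nodes), with an
#' optional binary diagnosis label per subject (0 = normal control,
#' 1 = mild cognitive impairment).
#'
#' @slot series numeric array of dimension T x n x N (timepoints, nodes,
#'   subjects).
#' @slot labels integer vector of length N with values in \{0, 1\}, or
#'   \code{NULL} when labels are unknown.
#' @slot subjectIds character vector of length N.
#' @slot nodeNames character vector of length n (e.g. AAL region labels).
#'
#' @export
setClass("RoiTimeSeriesSet",
  representation(
    series = "array",
    labels = "integerOrNULL",
    subjectIds = "character",
    nodeNames = "character"
  )
)

setValidity("RoiTimeSeriesSet", function(object) {
  d <- dim(object@series)
  if (length(d) != 3L)
    return("'series' must be a 3-d array: timepoints x nodes x subjects")
  if (!is.numeric(object@series) || any(!is.finite(object@series)))
    return("'series' must be finite numeric")
  if (!is.null(object@labels)) {
    if (length(object@labels) != d[3L])
      return("length(labels) must equal the number of subjects")
    if (!all(object@labels %in% c(0L, 1L)))
      return("labels must be 0 (normal) or 1 (MCI)")
  }
  if (length(object@subjectIds) != d[3L])
    return("length(subjectIds) must equal the number of subjects")
  if (anyDuplicated(object@subjectIds))
    return("subjectIds must be unique")
  if (length(object@nodeNames) != d[2L])
    return("length(nodeNames) must equal the number of nodes")
  TRUE
})

#' Construct a RoiTimeSeriesSet
#'
#' @param series T x n x N numeric array (timepoints x nodes x subjects).
#' @param labels integer vector in \{0,1\} of length N, or NULL.
#' @param subjectIds character vector of subject identifiers; generated as
#'   \code{sub-<k>} when missing.
#' @param nodeNames character vector of node names; generated as
#'   \code{ROI<j>} when missing.
#' @return A \linkS4class{RoiTimeSeriesSet}.
#' @export
RoiTimeSeriesSet <- function(series, labels = NULL, subjectIds = NULL,
                             nodeNames = NULL) {
  if (is.matrix(series)) series <- array(series, dim = c(dim(series), 1L))
  d <- dim(series)
  if (is.null(subjectIds))
    subjectIds <- sprintf("sub-%03d", seq_len(d[3L]))
  if (is.null(nodeNames))
    nodeNames <- sprintf("ROI%03d", seq_len(d[2L]))
  if (!is.null(labels)) labels <- as.integer(labels)
  new("RoiTimeSeriesSet", series = series, labels = labels,
      subjectIds = as.character(subjectIds), nodeNames = as.character(nodeNames))
}

#' @describeIn RoiTimeSeriesSet-class number of subjects
#' @param x a \code{RoiTimeSeriesSet}
#' @export
nSubjects <- function(x) dim(x@series)[3L]

#' @describeIn RoiTimeSeriesSet-class number of nodes (ROIs)
#' @export
nNodes <- function(x) dim(x@series)[2L]

#' @describeIn RoiTimeSeriesSet-class number of timepoints
#' @export
nTimepoints <- function(x) dim(x@series)[1L]

#' @describeIn RoiTimeSeriesSet-class integer 0/1 label vector (or NULL)
#' @export
subjectLabels <- function(x) x@labels

#' @describeIn RoiTimeSeriesSet-class subject identifiers
#' @export
subjectIds <- function(x) x@subjectIds

#' @describeIn RoiTimeSeriesSet-class node (ROI) names
#' @export
nodeNames <- function(x) x@nodeNames

#' Extract one subject's T x n matrix
#'
#' @param x a \code{RoiTimeSeriesSet}
#' @param i subject index or id
#' @return T x n numeric matrix.
#' @export
subjectSeries <- function(x, i) {
  if (is.character(i)) i <- match(i, x@subjectIds)
  m <- x@series[, , i, drop = FALSE]
  dim(m) <- dim(x@series)[1:2]
  colnames(m) <- x@nodeNames
  m
}

#' Subset a RoiTimeSeriesSet by subject
#'
#' @param x a \code{RoiTimeSeriesSet}
#' @param i,j,... subject indices (only \code{i} is used)
#' @param drop ignored
#' @export
setMethod("[", "RoiTimeSeriesSet", function(x, i, j, ..., drop = FALSE) {
  new("RoiTimeSeriesSet",
      series = x@series[, , i, drop = FALSE],
      labels = if (is.null(x@labels)) NULL else x@labels[i],
      subjectIds = x@subjectIds[i],
      nodeNames = x@nodeNames)
})

setMethod("show", "RoiTimeSeriesSet", function(object) {
  d <- dim(object@series)
  cat(sprintf("RoiTimeSeriesSet: %d subjects, %d nodes, %d timepoints\n",
              d[3L], d[2L], d[1L]))
  if (!is.null(object@labels)) {
    tab <- table(factor(object@labels, levels = c(0L, 1L)))
    cat(sprintf("  labels: %d normal (0), %d MCI (1)\n", tab[["0"]], tab[["1"]]))
  } else cat("  labels: none\n")
  invisible(NULL)
})

#' Functional connectivity matrix
#'
#' An n x n matrix of (optionally sparsified) pairwise Pearson correlations
#' between ROI time series. A dense matrix has \code{sparsity = 0} and unit
#' diagonal; a sparsified matrix has zero diagonal, a fraction
#' \code{sparsity} of the weakest undirected edges removed, and
#' \code{edgeCount} retained pairs.
#'
#' @slot values n x n symmetric numeric matrix with entries in [-1, 1].
#' @slot sparsity the sparsity level lambda in [0, 1] (0 = dense).
#' @slot edgeCount number of retained undirected off-diagonal edges
#'   (NA for a dense matrix).
#' @slot nodeNames character vector of node names.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", sparsity = "numeric",
                 edgeCount = "integer", nodeNames = "character")
)

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("'values' must be square")
  if (any(!is.finite(v))) return("'values' must be finite")
  if (!isSymmetric(unname(v), tol = 1e-8)) return("'values' must be symmetric")
  if (max(abs(v)) > 1 + 1e-8) return("correlations must lie in [-1, 1]")
  if (length(object@sparsity) != 1L || object@sparsity < 0 || object@sparsity > 1)
    return("'sparsity' must be a single value in [0, 1]")
  dense <- object@sparsity == 0 && is.na(object@edgeCount)
  dg <- diag(v)
  if (dense && any(abs(dg - 1) > 1e-8))
    return("dense connectivity must have unit diagonal")
  if (!dense && any(dg != 0))
    return("sparsified connectivity must have zero diagonal")
  if (length(object@nodeNames) != nrow(v))
    return("length(nodeNames) must equal the matrix order")
  TRUE
})

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- nrow(object@values)
  if (is.na(object@edgeCount)) {
    cat(sprintf("ConnectivityMatrix: %d nodes, dense (Pearson)\n", n))
  } else {
    cat(sprintf("ConnectivityMatrix: %d nodes, sparsity lambda = %g, %d edges retained\n",
                n, object@sparsity, object@edgeCount))
  }
  invisible(NULL)
})

#' @describeIn ConnectivityMatrix-class the underlying numeric matrix
#' @param x a \code{ConnectivityMatrix}
#' @param ... ignored
#' @export
setMethod("as.matrix", "ConnectivityMatrix", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@nodeNames, x@nodeNames)
  m
})

#' @describeIn ConnectivityMatrix-class the sparsity level lambda
#' @export
sparsity <- function(x) x@sparsity

#' Number of retained undirected edges
#'
#' @param x a \code{ConnectivityMatrix} or \code{NormalizedAdjacency}
#' @return integer edge count (NA for a dense connectivity matrix).
#' @export
edgeCount <- function(x) x@edgeCount

#' Symmetrically normalized adjacency operator
#'
#' The graph-convolution propagation operator
#' \eqn{\hat{D}^{-1/2} \hat{A} \hat{D}^{-1/2}} with
#' \eqn{\hat{A} = I + |V|} (absolute sparsified edge weights plus
#' self-loops) and \eqn{\hat{D}_{nn} = \sum_m \hat{A}_{nm}}. All
#' eigenvalues lie in [-1, 1] and \eqn{\hat{D}^{1/2} \mathbf{1}} is an
#' eigenvector with eigenvalue 1.
#'
#' @slot values n x n symmetric numeric matrix.
#' @slot edgeCount number of underlying undirected edges.
#' @slot nodeNames character vector of node names.
#' @export
setClass("NormalizedAdjacency",
  representation(values = "matrix", edgeCount = "integer",
                 nodeNames = "character")
)

setValidity("NormalizedAdjacency", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("'values' must be square")
  if (any(!is.finite(v))) return("'values' must be finite")
  if (!isSymmetric(unname(v), tol = 1e-8)) return("'values' must be symmetric")
  if (length(object@nodeNames) != nrow(v))
    return("length(nodeNames) must equal the matrix order")
  TRUE
})

setMethod("show", "NormalizedAdjacency", function(object) {
  cat(sprintf("NormalizedAdjacency: %d nodes, %d edges (+ self-loops)\n",
              nrow(object@values), object@edgeCount))
  invisible(NULL)
})

#' @describeIn NormalizedAdjacency-class the underlying numeric matrix
#' @param x a \code{NormalizedAdjacency}
#' @param ... ignored
#' @export
setMethod("as.matrix", "NormalizedAdjacency", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@nodeNames, x@nodeNames)
  m
})

#' Deep spatiotemporal attention network
#'
#' Holds the architecture configuration and the (possibly trained)
#' parameters of the network: L spatiotemporal convolution blocks
#' (temporal convolution + average pooling, graph convolution, node
#' attention, fusion) followed by a per-channel compression head and a
#' fully connected classifier.
#'
#' @slot config list of architecture settings (see \code{\link{dstanModel}}).
#' @slot params list of parameter arrays, one entry per block plus the head.
#' @export
setClass("DstanModel",
  representation(config = "list", params = "list")
)

setMethod("show", "DstanModel", function(object) {
  cfg <- object@config
  cat("DstanModel\n")
  cat(sprintf("  nodes: %d, input timepoints: %d\n", cfg$nNodes, cfg$tIn))
  cat(sprintf("  blocks: %d, channels: (%s), kernel w = %d, pool s = %d\n",
              length(cfg$channels), paste(cfg$channels, collapse = ","),
              cfg$w, cfg$s))
  cat(sprintf("  attention ratio r = %d (bottleneck width %d)%s\n",
              cfg$attentionRatio, max(1L, cfg$nNodes %/% cfg$attentionRatio),
              if (isTRUE(cfg$noAttention)) " [attention disabled]" else ""))
  cat(sprintf("  time lengths per block: %s\n",
              paste(cfg$timeLengths, collapse = " -> ")))
  cat(sprintf("  parameters: %d\n", nParameters(object)))
  invisible(NULL)
})

#' Total number of learnable parameters
#'
#' @param model a \code{DstanModel}
#' @return integer count.
#' @export
nParameters <- function(model) {
  sum(vapply(unlist(model@params, recursive = FALSE), length, integer(1)))
}

#' A trained model with its optimization history
#'
#' @slot model the trained \linkS4class{DstanModel}.
#' @slot history data.frame with one row per epoch: learning rate,
#'   cross-entropy, attention loss, total loss and training accuracy.
#' @slot trainConfig the training configuration used.
#' @export
setClass("DstanFit",
  representation(model = "DstanModel", history = "data.frame",
                 trainConfig = "list")
)

setMethod("show", "DstanFit", function(object) {
  h <- object@history
  cat(sprintf("DstanFit: %d epochs\n", nrow(h)))
  if (nrow(h) > 0) {
    last <- h[nrow(h), ]
    cat(sprintf("  final: lr = %g, ce = %.4f, att = %.4f, total = %.4f, train acc = %.1f%%\n",
                last$lr, last$ce, last$att, last$total, 100 * last$train_acc))
  }
  invisible(NULL)
})

#' @describeIn DstanFit-class the trained model
#' @param x a \code{DstanFit}
#' @export
fittedModel <- function(x) x@model

#' @describeIn DstanFit-class the per-epoch training history
#' @export
trainingHistory <- function(x) x@history
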