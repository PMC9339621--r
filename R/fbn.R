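#' Pearson functional connectivity
#'
#' Computes the sample Pearson correlation between every pair of ROI
#' columns of one subject's time-series matrix (or the element-wise mean
#' of per-subject matrices for a whole cohort, the group-level network).
#'
#' @param x a T x n matrix, or a \linkS4class{RoiTimeSeriesSet} (in which
#'   case per-subject connectivity matrices are averaged).
#' @param subjects optional subject indices to restrict a set to (e.g. the
#'   training fold, so the network never sees test subjects).
#' @return A dense \linkS4class{ConnectivityMatrix} (sparsity 0, unit
#'   diagonal).
#' @export
computePearson <- function(x, subjects = NULL) {
  if (is(x, "RoiTimeSeriesSet")) {
    idx <- if (is.null(subjects)) seq_len(nSubjects(x)) else subjects
    mats <- lapply(idx, function(i) pearsonMatrix(subjectSeries(x, i)))
    P <- Reduce(`+`, mats) / length(mats)
    P <- (P + t(P)) / 2
    diag(P) <- 1
    names <- nodeNames(x)
  } else {
    P <- pearsonMatrix(as.matrix(x))
    names <- colnames(x)
    if (is.null(names)) names <- sprintf("ROI%03d", seq_len(ncol(P)))
  }
  new("ConnectivityMatrix", values = P, sparsity = 0,
      edgeCount = NA_integer_, nodeNames = names)
}

pearsonMatrix <- function(m) {
  if (nrow(m) < 3L)
    stop("at least 3 timepoints are required for a Pearson connectivity matrix")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant (zero-variance) ROI column(s): ",
         paste(which(sds == 0), collapse = ", "))
  P <- stats::cor(m)
  P <- (P + t(P)) / 2
  P[P > 1] <- 1
  P[P < -1] <- -1
  diag(P) <- 1
  unname(P)
}

#' Sparsify a connectivity matrix
#'
#' Proportional thresholding: of the m = n(n-1)/2 undirected off-diagonal
#' pairs, the \code{ceiling((1 - lambda) * m)} with largest \code{|P_ij|}
#' are retained with their signed values and all others (and the diagonal)
#' are set to zero. Ties at the cut magnitude are broken by retaining the
#' lexicographically smallest (i, j) pairs, so the result is deterministic.
#' \code{lambda = 0} keeps every edge; \code{lambda = 1} removes all.
#'
#' @param P a dense \linkS4class{ConnectivityMatrix}.
#' @param lambda sparsity level in [0, 1]: the fraction of weakest
#'   connections removed.
#' @return A sparsified \linkS4class{ConnectivityMatrix} with
#'   \code{edgeCount} filled in.
#' @export
sparsifyConnectivity <- function(P, lambda) {
  stopifnot(is(P, "ConnectivityMatrix"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  if (P@sparsity != 0 || !is.na(P@edgeCount))
    stop("sparsifyConnectivity expects a dense connectivity matrix")
  v <- P@values
  n <- nrow(v)
  ij <- which(upper.tri(v), arr.ind = TRUE)
  m <- nrow(ij)
  keep <- ceiling((1 - lambda) * m)
  out <- matrix(0, n, n)
  if (keep > 0L) {
    w <- abs(v[ij])
    ord <- order(-w, ij[, 1L], ij[, 2L])
    sel <- ij[ord[seq_len(keep)], , drop = FALSE]
    out[sel] <- v[sel]
    out[sel[, c(2L, 1L), drop = FALSE]] <- v[sel]
  }
  new("ConnectivityMatrix", values = out, sparsity = lambda,
      edgeCount = as.integer(keep), nodeNames = P@nodeNames)
}

#' Symmetric normalized adjacency for graph convolution
#'
#' Builds the propagation operator
#' \eqn{\hat{D}^{-1/2} \hat{A} \hat{D}^{-1/2}} from a sparsified
#' connectivity matrix, with \eqn{\hat{A} = I + |V|}: absolute edge
#' weights (so degrees stay positive under negative correlations) plus
#' self-loops, and \eqn{\hat{D}_{nn} = \sum_m \hat{A}_{nm}}. Isolated
#' nodes get degree 1 from their self-loop. The operator is symmetric
#' with spectral radius at most 1.
#'
#' @param Ps a sparsified \linkS4class{ConnectivityMatrix} (zero diagonal).
#' @return A \linkS4class{NormalizedAdjacency}.
#' @export
normalizeAdjacency <- function(Ps) {
  stopifnot(is(Ps, "ConnectivityMatrix"))
  if (is.na(Ps@edgeCount))
    stop("normalizeAdjacency expects a sparsified connectivity matrix")
  A <- abs(Ps@values)
  diag(A) <- diag(A) + 1
  dInvSqrt <- 1 / sqrt(rowSums(A))
  S <- A * tcrossprod(dInvSqrt)
  S <- (S + t(S)) / 2
  new("NormalizedAdjacency", values = S, edgeCount = Ps@edgeCount,
      nodeNames = Ps@nodeNames)
}

#' Build the functional brain network in one step
#'
#' Convenience wrapper: group-level Pearson connectivity (mean over the
#' given subjects), proportional sparsification at \code{lambda}, and
#' symmetric normalization. One shared network per experiment; pass a
#' single subject's matrix for a subject-level network.
#'
#' @param x a \linkS4class{RoiTimeSeriesSet} or a T x n matrix.
#' @param lambda sparsity level in [0, 1].
#' @param subjects optional subject indices (typically the training fold).
#' @param level \code{"group"} (default; one shared network from the mean
#'   connectivity) or \code{"subject"} (one network per subject, each
#'   element of the returned lists).
#' @return For \code{level = "group"}, a list with elements
#'   \code{connectivity} (dense), \code{sparsified} and \code{adjacency};
#'   for \code{level = "subject"}, the same names but each a list with one
#'   entry per subject.
#' @export
buildFbn <- function(x, lambda = 0.9, subjects = NULL,
                     level = c("group", "subject")) {
  level <- match.arg(level)
  if (level == "subject") {
    if (!is(x, "RoiTimeSeriesSet"))
      stop("subject-level networks require a RoiTimeSeriesSet")
    idx <- if (is.null(subjects)) seq_len(nSubjects(x)) else subjects
    per <- lapply(idx, function(i) buildFbn(subjectSeries(x, i), lambda))
    return(list(connectivity = lapply(per, `[[`, "connectivity"),
                sparsified = lapply(per, `[[`, "sparsified"),
                adjacency = lapply(per, `[[`, "adjacency")))
  }
  P <- computePearson(x, subjects = subjects)
  Ps <- sparsifyConnectivity(P, lambda)
  list(connectivity = P, sparsified = Ps, adjacency = normalizeAdjacency(Ps))
}

#' Edge-count sweep over sparsity levels
#'
#' Tabulates retained edge counts over a grid of lambda values, the
#' harness behind sparsity-sensitivity experiments.
#'
#' @param P a dense \linkS4class{ConnectivityMatrix}.
#' @param lambdas numeric vector of sparsity levels (default
#'   \code{seq(0.1, 0.9, by = 0.1)}).
#' @return data.frame with columns \code{lambda} and \code{edge_count}.
#' @export
sparsitySweep <- function(P, lambdas = seq(0.1, 0.9, by = 0.1)) {
  counts <- vapply(lambdas, function(l)
    sparsifyConnectivity(P, l)@edgeCount, integer(1))
  data.frame(lambda = lambdas, edge_count = counts)
}
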