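#' Configuration for the synthetic BOLD generator
#'
#' Describes a two-class cohort of ROI time series in which the classes
#' differ only in the pairwise correlations among a planted subset of
#' nodes: controls (label 0) share a compound-symmetric baseline
#' correlation, while the MCI class (label 1) has \code{effectDelta}
#' added to every correlation between two planted nodes. Defaults mirror
#' a 90-ROI, 80-timepoint resting-state acquisition with a 46/45
#' control/patient cohort.
#'
#' @param nNodes number of ROIs (default 90).
#' @param nTimepoints number of timepoints per subject (default 80).
#' @param nSubjectsPerClass subjects per class; either a single count or a
#'   length-2 vector \code{c(n_control, n_mci)} (default \code{c(46, 45)}).
#' @param plantedNodes integer indices (1-based) of the nodes whose mutual
#'   correlations differ between classes (default \code{1:6}).
#' @param baseCorrelation baseline pairwise correlation shared by all node
#'   pairs in the control class, in [0, 1) (default 0.1).
#' @param effectDelta additive shift applied to planted-pair correlations in
#'   the MCI class; the shifted values are clipped to (-0.99, 0.99)
#'   (default 0.4).
#' @param arCoefficient AR(1) coefficient for temporal smoothing in [0, 1)
#'   (default 0.3; BOLD series are autocorrelated).
#' @param noiseSd marginal standard deviation of the signal (default 1).
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @return A validated list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(nNodes = 90L, nTimepoints = 80L,
                            nSubjectsPerClass = c(46L, 45L),
                            plantedNodes = 1:6,
                            baseCorrelation = 0.1, effectDelta = 0.4,
                            arCoefficient = 0.3, noiseSd = 1, seed = 1L) {
  cfg <- list(
    nNodes = as.integer(nNodes),
    nTimepoints = as.integer(nTimepoints),
    nSubjectsPerClass = as.integer(rep_len(nSubjectsPerClass,
                                           if (length(nSubjectsPerClass) >= 2) 2L else 1L)),
    plantedNodes = sort(unique(as.integer(plantedNodes))),
    baseCorrelation = baseCorrelation,
    effectDelta = effectDelta,
    arCoefficient = arCoefficient,
    noiseSd = noiseSd,
    seed = as.integer(seed)
  )
  if (length(cfg$nSubjectsPerClass) == 1L)
    cfg$nSubjectsPerClass <- rep(cfg$nSubjectsPerClass, 2L)
  validateSyntheticConfig(cfg)
  class(cfg) <- "SyntheticConfig"
  cfg
}

validateSyntheticConfig <- function(cfg) {
  stopifnot(cfg$nNodes >= 2L, cfg$nTimepoints >= 2L,
            all(cfg$nSubjectsPerClass >= 1L))
  if (length(cfg$plantedNodes) == 0L)
    stop("plantedNodes must be non-empty")
  if (any(cfg$plantedNodes < 1L) || any(cfg$plantedNodes > cfg$nNodes))
    stop("plantedNodes must lie in 1..nNodes")
  if (cfg$baseCorrelation < 0 || cfg$baseCorrelation >= 1)
    stop("baseCorrelation must lie in [0, 1)")
  if (cfg$arCoefficient < 0 || cfg$arCoefficient >= 1)
    stop("arCoefficient must lie in [0, 1)")
  if (cfg$noiseSd < 0) stop("noiseSd must be non-negative")
  # both class correlation matrices must be positive definite before sampling
  for (cl in c(0L, 1L)) buildClassCorrelation(cfg, cl)
  invisible(TRUE)
}

#' Per-class population correlation matrix
#'
#' Class 0 is compound-symmetric at \code{baseCorrelation}; class 1 differs
#' only on entries between two planted nodes, shifted by \code{effectDelta}
#' and clipped to (-0.99, 0.99). If the shifted matrix is not positive
#' definite it is repaired by eigenvalue clipping at 1e-6 followed by
#' re-normalization to unit diagonal (with a message); a non-repairable
#' matrix is a configuration error.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param classLabel 0 (control) or 1 (MCI).
#' @return n x n correlation matrix.
#' @export
buildClassCorrelation <- function(cfg, classLabel) {
  stopifnot(classLabel %in% c(0L, 1L))
  n <- cfg$nNodes
  C <- matrix(cfg$baseCorrelation, n, n)
  diag(C) <- 1
  if (classLabel == 1L && cfg$effectDelta != 0) {
    p <- cfg$plantedNodes
    if (length(p) >= 2L) {
      shifted <- pmin(pmax(C[p, p] + cfg$effectDelta, -0.99), 0.99)
      C[p, p] <- shifted
      diag(C) <- 1
    }
  }
  if (!isPositiveDefinite(C)) {
    message("class ", classLabel,
            " correlation matrix not positive definite; applying nearest-PD repair")
    C <- nearestPD(C)
    if (!isPositiveDefinite(C))
      stop("non-repairable non-positive-definite correlation matrix ",
           sprintf("(baseCorrelation = %g, effectDelta = %g, %d planted nodes)",
                   cfg$baseCorrelation, cfg$effectDelta, length(cfg$plantedNodes)))
  }
  C
}

isPositiveDefinite <- function(C, tol = 1e-10) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol)
}

# eigenvalue clipping at 1e-6, then rescale back to unit diagonal
nearestPD <- function(C, eps = 1e-6) {
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, eps)
  M <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  (M + t(M)) / 2
}

#' Sample one subject's ROI time series
#'
#' Rows are drawn as multivariate normal with covariance
#' \code{sd^2 * corr} (via the Cholesky factor), then each column is
#' passed through the same recursive AR(1) filter
#' \eqn{y_t = ar\, y_{t-1} + x_t}. Applying one common linear filter to
#' all columns leaves the zero-lag cross-correlation structure intact, so
#' the target correlation matrix is preserved while adding the temporal
#' autocorrelation characteristic of BOLD signal.
#'
#' @param corr n x n positive definite correlation matrix.
#' @param nTimepoints number of timepoints T (must be >= 2).
#' @param ar AR(1) coefficient in [0, 1).
#' @param sd marginal standard deviation (\code{sd = 0} gives a zero matrix).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return T x n numeric matrix.
#' @export
sampleSubject <- function(corr, nTimepoints, ar = 0, sd = 1, seed = 1L) {
  if (nTimepoints < 2L)
    stop("nTimepoints must be at least 2 (correlation undefined otherwise)")
  n <- nrow(corr)
  R <- chol(corr)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  Z <- matrix(rnorm(nTimepoints * n), nTimepoints, n)
  X <- sd * (Z %*% R)
  if (ar > 0 && sd > 0) {
    X <- apply(X, 2L, function(col)
      as.numeric(stats::filter(col, ar, method = "recursive")))
  }
  X
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# deterministic per-subject seed below 2^31, derived from (master, class, index)
subjectSeed <- function(masterSeed, classLabel, index) {
  m <- 2147483647
  h <- (as.numeric(masterSeed) %% m)
  h <- (h * 1000003 + (classLabel + 1) * 97003) %% m
  h <- (h * 69069 + index * 10007) %% m
  as.integer(h %% (m - 1)) + 1L
}

#' Generate a labeled two-class dataset
#'
#' Draws \code{nSubjectsPerClass[1]} control subjects (label 0) and
#' \code{nSubjectsPerClass[2]} MCI subjects (label 1) from the two class
#' correlation matrices. Per-subject seeds are derived deterministically
#' from \code{cfg$seed}, the class and the subject index, so two calls
#' with the same configuration return identical datasets.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return A \linkS4class{RoiTimeSeriesSet} with labels attached.
#' @export
generateDataset <- function(cfg) {
  validateSyntheticConfig(cfg)
  corr0 <- buildClassCorrelation(cfg, 0L)
  corr1 <- buildClassCorrelation(cfg, 1L)
  nTotal <- sum(cfg$nSubjectsPerClass)
  series <- array(0, dim = c(cfg$nTimepoints, cfg$nNodes, nTotal))
  labels <- integer(nTotal)
  k <- 0L
  for (cl in c(0L, 1L)) {
    corr <- if (cl == 0L) corr0 else corr1
    for (i in seq_len(cfg$nSubjectsPerClass[cl + 1L])) {
      k <- k + 1L
      series[, , k] <- sampleSubject(corr, cfg$nTimepoints,
                                     ar = cfg$arCoefficient,
                                     sd = cfg$noiseSd,
                                     seed = subjectSeed(cfg$seed, cl, i))
      labels[k] <- cl
    }
  }
  RoiTimeSeriesSet(series, labels = labels,
                   subjectIds = sprintf("sub-%03d", seq_len(nTotal)))
}
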