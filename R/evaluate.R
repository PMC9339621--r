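#' Stratified train/test split
#'
#' Randomly splits subjects into a training and a test set, by default
#' stratified by label so both classes appear on both sides. The test
#' fraction is \code{1 - ratio}, rounded up within each class (so a 91
#' subject cohort at ratio 0.8 yields a 19-subject test set). The split is
#' a partition (no overlap, union = all) and is deterministic given the
#' seed.
#'
#' @param data a labeled \linkS4class{RoiTimeSeriesSet}.
#' @param ratio training fraction in (0, 1) (default 0.8).
#' @param seed integer seed.
#' @param stratified stratify by label (default TRUE).
#' @return list with \code{train} and \code{test}
#'   \linkS4class{RoiTimeSeriesSet}s.
#' @export
splitDataset <- function(data, ratio = 0.8, seed = 1L, stratified = TRUE) {
  stopifnot(is(data, "RoiTimeSeriesSet"))
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("ratio must lie strictly between 0 and 1")
  labels <- subjectLabels(data)
  if (is.null(labels)) stop("splitDataset requires labels")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  testIdx <- integer(0)
  if (stratified) {
    for (cl in c(0L, 1L)) {
      members <- which(labels == cl)
      if (length(members) == 0L)
        stop("class ", cl, " has no subjects; cannot stratify")
      nTest <- ceiling((1 - ratio) * length(members))
      testIdx <- c(testIdx, sort(sample(members, nTest)))
    }
  } else {
    nTest <- ceiling((1 - ratio) * length(labels))
    testIdx <- sort(sample(seq_along(labels), nTest))
  }
  trainIdx <- setdiff(seq_along(labels), testIdx)
  list(train = data[trainIdx], test = data[sort(testIdx)],
       trainIdx = trainIdx, testIdx = sort(testIdx))
}

#' Confusion counts with MCI as the positive class
#'
#' The predicted class is the argmax of the scores, ties broken toward
#' class 0 (normal). Label 1 (MCI) is the positive class.
#'
#' @param scores N x 2 matrix of class scores.
#' @param labels integer vector in \{0, 1\}.
#' @return list with integer components \code{tp}, \code{fp}, \code{tn},
#'   \code{fn}.
#' @export
confusionCounts <- function(scores, labels) {
  scores <- rbind(scores)
  labels <- as.integer(labels)
  if (nrow(scores) != length(labels))
    stop("scores and labels are not aligned")
  pred <- as.integer(scores[, 2L] > scores[, 1L])
  list(tp = sum(pred == 1L & labels == 1L),
       fp = sum(pred == 1L & labels == 0L),
       tn = sum(pred == 0L & labels == 0L),
       fn = sum(pred == 0L & labels == 1L))
}

#' Accuracy, sensitivity and specificity
#'
#' \code{accuracy = 100 (tp + tn) / (tp + fp + tn + fn)},
#' \code{sensitivity = 100 tp / (tp + fn)} (true-positive rate among MCI),
#' \code{specificity = 100 tn / (tn + fp)} (true-negative rate among
#' controls), as percentages. A zero denominator yields NaN with a
#' warning, never a silent 0. Values are exact; see
#' \code{\link{formatMetrics}} for 2-decimal display truncation.
#'
#' @param cc confusion counts (a list with tp, fp, tn, fn), e.g. from
#'   \code{\link{confusionCounts}}; alternatively pass the four counts.
#' @param fp,tn,fn individual counts when \code{cc} is given as tp.
#' @return list with \code{accuracy}, \code{sensitivity},
#'   \code{specificity} (percent).
#' @export
classificationMetrics <- function(cc, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.list(cc)) cc <- list(tp = cc, fp = fp, tn = tn, fn = fn)
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(cc)))
  tot <- cc$tp + cc$fp + cc$tn + cc$fn
  if (tot < 1L) stop("at least one evaluated subject is required")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    100 * num / den
  }
  list(accuracy = ratio(cc$tp + cc$tn, tot, "accuracy"),
       sensitivity = ratio(cc$tp, cc$tp + cc$fn, "sensitivity"),
       specificity = ratio(cc$tn, cc$tn + cc$fp, "specificity"))
}

#' Truncate metrics to two decimals for display
#'
#' Report tables print percentages truncated (not rounded) at two
#' decimals, e.g. 9/11 = 81.8181... prints as 81.81.
#'
#' @param m a metrics list from \code{\link{classificationMetrics}}.
#' @return list of the same metrics truncated at 2 decimals.
#' @export
formatMetrics <- function(m) {
  lapply(m, function(v) if (is.nan(v)) v else floor(v * 100) / 100)
}

#' Evaluate a trained model on a dataset
#'
#' Runs the forward pass, tabulates confusion counts (MCI positive) and
#' computes the metrics; per-block node attention maps are returned for
#' inspection.
#'
#' @param model a trained \linkS4class{DstanModel}.
#' @param data a labeled \linkS4class{RoiTimeSeriesSet}.
#' @param S the \linkS4class{NormalizedAdjacency} used at training time.
#' @return list with \code{scores}, \code{predicted}, \code{confusion},
#'   \code{metrics} and \code{attention} (n x L x N array).
#' @export
evaluateModel <- function(model, data, S) {
  fw <- dstanForward(data, S, model)
  labels <- subjectLabels(data)
  cc <- confusionCounts(fw$scores, labels)
  list(scores = fw$scores,
       predicted = as.integer(fw$scores[, 2L] > fw$scores[, 1L]),
       confusion = cc,
       metrics = classificationMetrics(cc),
       attention = fw$attention)
}

#' Mean node attention map of a cohort
#'
#' Averages the per-block attention maps over blocks and subjects to one
#' scalar per node, the quantity visualized when ranking regions by their
#' relevance to the MCI label.
#'
#' @param attention n x L x N attention array from
#'   \code{\link{dstanForward}} or \code{\link{evaluateModel}}.
#' @param nodeNames optional node names.
#' @return data.frame with columns \code{node_index}, \code{node_name},
#'   \code{Z}.
#' @export
meanAttentionMap <- function(attention, nodeNames = NULL) {
  n <- dim(attention)[1L]
  z <- apply(attention, 1L, mean)
  if (is.null(nodeNames)) nodeNames <- sprintf("ROI%03d", seq_len(n))
  data.frame(node_index = seq_len(n), node_name = nodeNames, Z = z)
}

#' Attention ablation harness
#'
#' Trains and evaluates the full model and the No-Att variant (attention
#' map pinned to 1, attention loss dropped) under identical seeds, data
#' split and functional brain network, and reports both rows in one
#' table.
#'
#' @param train,test labeled \linkS4class{RoiTimeSeriesSet}s.
#' @param S the shared \linkS4class{NormalizedAdjacency}.
#' @param modelArgs list of arguments to \code{\link{dstanModel}} (nNodes
#'   and tIn are filled from the data if absent).
#' @param tcfg a \code{\link{trainConfig}}.
#' @param verbose passed to \code{\link{trainDstan}}.
#' @return list with \code{table} (data.frame: method, accuracy,
#'   sensitivity, specificity) and the two fitted/evaluated arms
#'   (\code{dstan}, \code{noAtt}).
#' @export
runAblation <- function(train, test, S, modelArgs = list(),
                        tcfg = trainConfig(), verbose = 0L) {
  modelArgs$nNodes <- modelArgs$nNodes %||% nNodes(train)
  modelArgs$tIn <- modelArgs$tIn %||% nTimepoints(train)
  arms <- list()
  rows <- list()
  for (arm in c("DSTAN", "No-Att")) {
    args <- modelArgs
    args$noAttention <- (arm == "No-Att")
    model <- do.call(dstanModel, args)
    fit <- trainDstan(train, S, model, tcfg, verbose = verbose)
    ev <- evaluateModel(fittedModel(fit), test, S)
    m <- formatMetrics(ev$metrics)
    rows[[arm]] <- data.frame(method = arm, accuracy = m$accuracy,
                              sensitivity = m$sensitivity,
                              specificity = m$specificity)
    arms[[arm]] <- list(fit = fit, evaluation = ev)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       dstan = arms[["DSTAN"]], noAtt = arms[["No-Att"]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
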