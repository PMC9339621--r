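#' Write a dataset as a directory of TSV files
#'
#' One \code{sub-<k>.tsv} per subject (T rows of n tab-separated values,
#' no header), a \code{participants.tsv} (columns subject_id, label) and,
#' when a generator configuration is supplied, a \code{dataset.yaml}
#' echoing it.
#'
#' @param x a \linkS4class{RoiTimeSeriesSet}.
#' @param dir output directory (created if needed).
#' @param config optional \code{\link{syntheticConfig}} to echo.
#' @return \code{dir}, invisibly.
#' @export
writeTimeSeriesDir <- function(x, dir, config = NULL) {
  stopifnot(is(x, "RoiTimeSeriesSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- subjectIds(x)
  for (i in seq_len(nSubjects(x))) {
    write.table(format(subjectSeries(x, i), digits = 17, trim = TRUE,
                       scientific = FALSE),
                file.path(dir, paste0(ids[i], ".tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  labels <- subjectLabels(x)
  part <- data.frame(subject_id = ids,
                     label = if (is.null(labels)) NA_integer_ else labels)
  write.table(part, file.path(dir, "participants.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(config))
    yaml::write_yaml(unclass(config), file.path(dir, "dataset.yaml"))
  invisible(dir)
}

#' Read a dataset from a directory of TSV files
#'
#' Reads \code{participants.tsv} and one \code{<subject_id>.tsv} per
#' listed subject, validating that every matrix is numeric, rectangular
#' and of the same T x n shape, and that no ROI column is constant
#' (a per-ROI variance check; constants would make the Pearson
#' connectivity undefined).
#'
#' @param dir dataset directory.
#' @param checkVariance warn about zero-variance ROI columns
#'   (default TRUE).
#' @return A \linkS4class{RoiTimeSeriesSet}.
#' @export
readTimeSeriesDir <- function(dir, checkVariance = TRUE) {
  pfile <- file.path(dir, "participants.tsv")
  if (!file.exists(pfile))
    stop("missing participants.tsv in ", dir)
  part <- read.table(pfile, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(part)))
    stop("participants.tsv must have columns subject_id and label")
  mats <- vector("list", nrow(part))
  for (i in seq_len(nrow(part))) {
    f <- file.path(dir, paste0(part$subject_id[i], ".tsv"))
    if (!file.exists(f)) stop("missing subject file: ", f)
    mats[[i]] <- readSubjectTsv(f)
  }
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("subjects do not share a common T x n shape: ",
         part$subject_id[which(dims[1, ] != dims[1, 1] |
                               dims[2, ] != dims[2, 1])[1]])
  series <- array(unlist(mats), dim = c(dims[1, 1], dims[2, 1], length(mats)))
  if (checkVariance) {
    for (i in seq_along(mats)) {
      sds <- apply(mats[[i]], 2L, stats::sd)
      if (any(sds == 0))
        warning(sprintf("subject %s: zero-variance ROI column(s) %s",
                        part$subject_id[i],
                        paste(which(sds == 0), collapse = ", ")))
    }
  }
  labels <- part$label
  if (all(is.na(labels))) labels <- NULL
  RoiTimeSeriesSet(series, labels = labels, subjectIds = part$subject_id)
}

readSubjectTsv <- function(f) {
  lines <- readLines(f)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(fields)
  if (any(width != width[1L]))
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 f, which(width != width[1L])[1L],
                 width[which(width != width[1L])[1L]], width[1L]))
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (any(is.na(vals))) {
    bad <- which(vapply(fields, function(r)
      any(is.na(suppressWarnings(as.numeric(r)))), logical(1)))[1L]
    stop(sprintf("%s: non-numeric cell at line %d", f, bad))
  }
  matrix(vals, nrow = length(lines), ncol = width[1L], byrow = TRUE)
}

#' Write a square matrix as TSV
#'
#' Tab-separated n x n values with an optional header row of ROI names.
#' Accepts a plain matrix, a \linkS4class{ConnectivityMatrix} or a
#' \linkS4class{NormalizedAdjacency}.
#'
#' @param m the matrix (or matrix-backed object).
#' @param path output file.
#' @param header write the ROI-name header row (default TRUE when names
#'   are available).
#' @return \code{path}, invisibly.
#' @export
writeMatrixTsv <- function(m, path, header = TRUE) {
  if (is(m, "ConnectivityMatrix") || is(m, "NormalizedAdjacency"))
    m <- as.matrix(m)
  cn <- colnames(m)
  write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", row.names = FALSE,
              col.names = if (header && !is.null(cn)) cn else FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a square matrix from TSV
#'
#' @param path input file (optionally with a header row of ROI names).
#' @param role one of \code{"matrix"} (any square matrix),
#'   \code{"connectivity"} or \code{"adjacency"}; the latter two
#'   additionally require symmetry.
#' @return numeric matrix (with dimnames when a header is present).
#' @export
readMatrixTsv <- function(path, role = c("matrix", "connectivity",
                                         "adjacency")) {
  role <- match.arg(role)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(first))))
  m <- as.matrix(read.table(path, header = hasHeader, sep = "\t",
                            check.names = FALSE))
  if (nrow(m) != ncol(m))
    stop(sprintf("%s: expected a square matrix, got %d x %d",
                 path, nrow(m), ncol(m)))
  if (role != "matrix" && !isSymmetric(unname(m), tol = 1e-8))
    stop(sprintf("%s: a %s matrix must be symmetric", path, role))
  if (hasHeader) rownames(m) <- colnames(m)
  m
}

#' Export per-node attention as TSV
#'
#' Writes the mean attention map (columns node_index, node_name, Z), the
#' data surface behind region-relevance rankings.
#'
#' @param attention n x L x N array from \code{\link{evaluateModel}}.
#' @param path output file.
#' @param nodeNames optional node names.
#' @return \code{path}, invisibly.
#' @export
writeAttentionTsv <- function(attention, path, nodeNames = NULL) {
  df <- meanAttentionMap(attention, nodeNames)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
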