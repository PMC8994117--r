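#' @include AllClasses.R
NULL

## numbers are written with 17 significant digits so that doubles round-trip
## through text bit-exactly
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.readTable <- function(path, what) {
  lines <- readLines(path)
  if (!length(lines)) stop(sprintf("%s: empty %s file", path, what))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- length(fields[[1L]])
  bad <- which(vapply(fields, length, 1L) != nc)
  if (length(bad))
    stop(sprintf("%s: ragged row at line %d (expected %d fields)", path,
                 bad[1L], nc))
  list(header = fields[[1L]], rows = fields[-1L])
}

#' Read / write a node-labelled time-series TSV
#'
#' The time-series format is a TSV whose header row holds the node ids and
#' whose subsequent rows hold one volume each. Nuisance-signal columns named
#' `wm`, `csf` and `global` are recognised and stored separately from the
#' node signals.
#'
#' @param path file path.
#' @param trSeconds repetition time to attach on read (default 2).
#' @param subject,timepoint identifiers to attach on read.
#' @return `readTimeseriesTSV`: a [SubjectTimeSeries-class].
#' @export
readTimeseriesTSV <- function(path, trSeconds = 2, subject = NA_character_,
                              timepoint = NA_character_) {
  tab <- .readTable(path, "time-series")
  if (anyDuplicated(tab$header))
    stop(sprintf("%s: duplicated column names in header", path))
  m <- matrix(as.numeric(unlist(tab$rows)), nrow = length(tab$rows),
              byrow = TRUE, dimnames = list(NULL, tab$header))
  nuisCols <- intersect(c("wm", "csf", "global"), tab$header)
  nuis <- if (length(nuisCols))
    as.data.frame(m[, nuisCols, drop = FALSE]) else data.frame()
  sig <- m[, setdiff(tab$header, nuisCols), drop = FALSE]
  SubjectTimeSeries(sig, trSeconds = trSeconds, nuisance = nuis,
                    subject = subject, timepoint = timepoint)
}

#' @rdname readTimeseriesTSV
#' @param ts a [SubjectTimeSeries-class] object.
#' @return `writeTimeseriesTSV`: `path`, invisibly.
#' @export
writeTimeseriesTSV <- function(ts, path) {
  m <- signalMatrix(ts)
  nuis <- nuisanceSignals(ts)
  if (nrow(nuis)) m <- cbind(m, as.matrix(nuis))
  lines <- c(paste(colnames(m), collapse = "\t"),
             apply(m, 1L, function(r) paste(.fmtNum(r), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a six-parameter motion trace TSV
#'
#' Columns `tx, ty, tz` (translations, mm) and `rx, ry, rz` (rotations,
#' radians), one row per volume.
#'
#' @param path file path.
#' @return `readMotionTSV`: volumes x 6 numeric matrix.
#' @export
readMotionTSV <- function(path) {
  tab <- .readTable(path, "motion")
  expect <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (!identical(tab$header, expect))
    stop(sprintf("%s: motion header must be %s", path,
                 paste(expect, collapse = ",")))
  matrix(as.numeric(unlist(tab$rows)), nrow = length(tab$rows),
         byrow = TRUE, dimnames = list(NULL, expect))
}

#' @rdname readMotionTSV
#' @param motion volumes x 6 motion matrix.
#' @export
writeMotionTSV <- function(motion, path) {
  motion <- as.matrix(motion)
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  lines <- c(paste(colnames(motion), collapse = "\t"),
             apply(motion, 1L, function(r) paste(.fmtNum(r), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a node-set definition JSON
#'
#' Format: `{"name": ..., "nodes": [{"id", "hemisphere", "region",
#' "mni": [x, y, z] (optional)}, ...]}`.
#'
#' @param path file path.
#' @return `readNodesetJSON`: a [NetworkDefinition-class].
#' @export
readNodesetJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$name) || is.null(obj$nodes))
    stop(sprintf("%s: node-set JSON must have 'name' and 'nodes'", path))
  nodes <- as.data.frame(obj$nodes)
  for (col in c("id", "hemisphere", "region"))
    if (is.null(nodes[[col]]))
      stop(sprintf("%s: every node needs a '%s' field", path, col))
  if (!is.null(nodes$mni) && is.list(nodes$mni)) {
    mni <- do.call(rbind, lapply(nodes$mni, function(v)
      if (is.null(v) || !length(v)) rep(NA_real_, 3) else as.numeric(v)))
    nodes$mni <- NULL
    nodes[c("mni_x", "mni_y", "mni_z")] <- mni
  }
  NetworkDefinition(obj$name, nodes)
}

#' @rdname readNodesetJSON
#' @param network a [NetworkDefinition-class].
#' @export
writeNodesetJSON <- function(network, path) {
  nd <- nodeTable(network)
  nodes <- lapply(seq_len(nrow(nd)), function(i) {
    node <- list(id = nd$id[i], hemisphere = nd$hemisphere[i],
                 region = nd$region[i])
    if (all(c("mni_x", "mni_y", "mni_z") %in% colnames(nd)) &&
        !is.na(nd$mni_x[i]))
      node$mni <- c(nd$mni_x[i], nd$mni_y[i], nd$mni_z[i])
    node
  })
  jsonlite::write_json(list(name = networkName(network), nodes = nodes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a per-subject language-score table
#'
#' TSV with one row per subject: identifiers and covariates (`subject, sex,
#' age, education, grade, location, resection`, optionally `group`) and the
#' AQ trajectory columns `aq_pre, aq_w2, aq_m1, aq_m3, aq_m6` (empty or `NA`
#' = not observed).
#'
#' @param path file path.
#' @return `readScoresTSV`: `data.frame` with the columns above.
#' @export
readScoresTSV <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"subject" %in% colnames(df))
    stop(sprintf("%s: scores table must have a 'subject' column", path))
  if (!"aq_pre" %in% colnames(df))
    stop(sprintf("%s: scores table must have an 'aq_pre' column", path))
  df
}

#' @rdname readScoresTSV
#' @param scores `data.frame` of scores.
#' @export
writeScoresTSV <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a connectivity matrix or edge list as TSV
#'
#' `writeMatrixTSV` writes a square matrix with a node-id header column and
#' row; `readMatrixTSV` reads it back bit-exactly. `writeEdgelistTSV` writes
#' the long-format edge list produced by [classifyEdges()].
#'
#' @param m square numeric matrix with dimnames.
#' @param path file path.
#' @export
writeMatrixTSV <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  lines <- c(paste(c("node", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = "\t"),
               ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  tab <- .readTable(path, "matrix")
  ids <- tab$header[-1L]
  rows <- lapply(tab$rows, function(f) f[-1L])
  rn <- vapply(tab$rows, `[[`, "", 1L)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE,
         dimnames = list(rn, ids))
}

#' @rdname writeMatrixTSV
#' @param edges edge-list `data.frame` from [classifyEdges()].
#' @export
writeEdgelistTSV <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
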