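setOldClass("data.frame")

## timepoint vocabulary used throughout: preoperative baseline, 2 weeks,
## 1 month (subacute phase), 3 months, 6 months (chronic phase)
.TIMEPOINTS <- c("pre", "w2", "m1", "m3", "m6")
.SUBACUTE <- c("w2", "m1")
.CHRONIC <- c("m3", "m6")

#' NetworkDefinition: a named node set with hemisphere labels
#'
#' Defines a network of interest as a table of nodes (regions of interest),
#' each with a unique identifier, a hemisphere label (`"L"`, `"R"` or
#' `"midline"`), a free-text region label and optional MNI coordinates.
#'
#' @slot name character(1), network name (e.g. `"language"`, `"co_fp"`).
#' @slot nodes `data.frame` with columns `id`, `hemisphere`, `region` and
#'   optionally `mni_x`, `mni_y`, `mni_z`.
#'
#' @section Validity:
#' Node ids must be unique; hemisphere labels must be `"L"`, `"R"` or
#' `"midline"`. A network named `"language"` must have equal left and right
#' node counts (it is defined as a hemispherically symmetric node set).
#'
#' @seealso [builtinNetwork()], [readNodesetJSON()]
#' @export
setClass("NetworkDefinition",
  representation(name = "character", nodes = "data.frame"),
  validity = function(object) {
    msg <- NULL
    nd <- object@nodes
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
      msg <- c(msg, "'name' must be a single non-empty string")
    req <- c("id", "hemisphere", "region")
    if (!all(req %in% colnames(nd)))
      msg <- c(msg, sprintf("node table must have columns %s",
                            paste(req, collapse = ", ")))
    else {
      if (anyDuplicated(nd$id))
        msg <- c(msg, "node ids must be unique")
      if (!all(nd$hemisphere %in% c("L", "R", "midline")))
        msg <- c(msg, "hemisphere labels must be 'L', 'R' or 'midline'")
      if (identical(object@name, "language") &&
          sum(nd$hemisphere == "L") != sum(nd$hemisphere == "R"))
        msg <- c(msg, "the language network must have equal L and R node counts")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a NetworkDefinition
#'
#' @param name network name.
#' @param nodes `data.frame` with columns `id`, `hemisphere`, `region` and
#'   optional `mni_x`, `mni_y`, `mni_z`.
#' @return A [NetworkDefinition-class] object.
#' @examples
#' net <- NetworkDefinition("toy", data.frame(
#'   id = c("A_L", "A_R"), hemisphere = c("L", "R"), region = "A"))
#' nodeIds(net)
#' @export
NetworkDefinition <- function(name, nodes) {
  nodes <- as.data.frame(nodes)
  nodes$id <- as.character(nodes$id)
  nodes$hemisphere <- as.character(nodes$hemisphere)
  nodes$region <- as.character(nodes$region)
  new("NetworkDefinition", name = as.character(name), nodes = nodes)
}

#' SubjectTimeSeries: node-labelled multivariate signal for one scan
#'
#' Holds a volumes-by-nodes matrix of BOLD-like signal for one subject at one
#' timepoint, together with the repetition time, the six-parameter rigid-body
#' motion trace (x/y/z translations in mm, three rotations in radians) and
#' optional node-level nuisance signals (white matter, CSF, global).
#'
#' @slot signals numeric matrix, volumes x nodes, column names = node ids.
#' @slot trSeconds numeric(1), repetition time in seconds.
#' @slot motion numeric matrix, volumes x 6 (`tx,ty,tz,rx,ry,rz`) or 0-row
#'   when no motion trace is attached.
#' @slot nuisance `data.frame` with 0 rows or one row per volume; recognised
#'   columns are `wm`, `csf`, `global`.
#' @slot subject character(1) subject identifier (may be `NA`).
#' @slot timepoint character(1), one of `pre, w2, m1, m3, m6`, `"control"`,
#'   or `NA`.
#' @slot processingLog list of character messages recording processing steps.
#' @export
setClass("SubjectTimeSeries",
  representation(signals = "matrix", trSeconds = "numeric",
                 motion = "matrix", nuisance = "data.frame",
                 subject = "character", timepoint = "character",
                 processingLog = "list"),
  prototype(trSeconds = 2, motion = matrix(numeric(0), 0, 6),
            nuisance = data.frame(), subject = NA_character_,
            timepoint = NA_character_, processingLog = list()),
  validity = function(object) {
    msg <- NULL
    n <- nrow(object@signals)
    if (is.null(colnames(object@signals)))
      msg <- c(msg, "signal matrix must have node ids as column names")
    if (!is.numeric(object@signals))
      msg <- c(msg, "signals must be numeric")
    if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
        object@trSeconds <= 0)
      msg <- c(msg, "trSeconds must be a single positive number")
    if (nrow(object@motion) > 0L) {
      if (ncol(object@motion) != 6L)
        msg <- c(msg, "motion trace must have 6 columns (tx,ty,tz,rx,ry,rz)")
      if (nrow(object@motion) != n)
        msg <- c(msg, "motion trace must have one row per volume")
    }
    if (nrow(object@nuisance) > 0L && nrow(object@nuisance) != n)
      msg <- c(msg, "nuisance signals must have one row per volume")
    if (!is.na(object@timepoint) &&
        !object@timepoint %in% c(.TIMEPOINTS, "control"))
      msg <- c(msg, "timepoint must be one of pre, w2, m1, m3, m6 or control")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SubjectTimeSeries
#'
#' @param signals volumes x nodes numeric matrix with node-id column names.
#' @param trSeconds repetition time in seconds (default 2).
#' @param motion optional volumes x 6 motion matrix.
#' @param nuisance optional `data.frame` of node-level nuisance signals with
#'   columns among `wm`, `csf`, `global`.
#' @param subject,timepoint optional identifiers.
#' @return A [SubjectTimeSeries-class] object.
#' @export
SubjectTimeSeries <- function(signals, trSeconds = 2, motion = NULL,
                              nuisance = NULL, subject = NA_character_,
                              timepoint = NA_character_) {
  signals <- as.matrix(signals)
  if (is.null(motion)) motion <- matrix(numeric(0), 0, 6,
    dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  motion <- as.matrix(motion)
  if (is.null(nuisance)) nuisance <- data.frame()
  new("SubjectTimeSeries", signals = signals, trSeconds = trSeconds,
      motion = motion, nuisance = as.data.frame(nuisance),
      subject = as.character(subject), timepoint = as.character(timepoint))
}

#' ConnectivityMatrix: symmetric functional-connectivity weights
#'
#' Stores the full Pearson correlation matrix of a node set together with the
#' active weight matrix (raw `r` or Fisher `z`), the weight semantics and, if
#' thresholding has been applied, the correlation threshold used. The
#' underlying `r` matrix is always retained so that thresholding is always
#' performed on correlations even when weights are Fisher-z values.
#'
#' @slot nodes character vector of node ids.
#' @slot r symmetric correlation matrix, zero diagonal.
#' @slot weights symmetric active weight matrix; entries of removed
#'   (subthreshold) edges are 0; zero diagonal.
#' @slot weightKind `"pearson_r"` or `"fisher_z"`.
#' @slot thresholdR numeric(1); `NA` when no threshold applied.
#'
#' @section Validity:
#' `r` and `weights` must be symmetric within 1e-12 with zero diagonal and
#' dimensions matching `nodes`; when a threshold is recorded, every surviving
#' (non-zero) weight must correspond to `r >` the threshold.
#' @export
setClass("ConnectivityMatrix",
  representation(nodes = "character", r = "matrix", weights = "matrix",
                 weightKind = "character", thresholdR = "numeric"),
  prototype(weightKind = "pearson_r", thresholdR = NA_real_),
  validity = function(object) {
    msg <- NULL
    n <- length(object@nodes)
    for (nm in c("r", "weights")) {
      m <- slot(object, nm)
      if (!all(dim(m) == c(n, n))) {
        msg <- c(msg, sprintf("'%s' must be %d x %d", nm, n, n))
        next
      }
      if (n > 0L && max(abs(m - t(m))) > 1e-12)
        msg <- c(msg, sprintf("'%s' must be symmetric within 1e-12", nm))
      if (n > 0L && any(diag(m) != 0))
        msg <- c(msg, sprintf("'%s' must have a zero diagonal", nm))
    }
    if (!object@weightKind %in% c("pearson_r", "fisher_z"))
      msg <- c(msg, "weightKind must be 'pearson_r' or 'fisher_z'")
    if (!is.na(object@thresholdR) && n > 0L &&
        all(dim(object@weights) == c(n, n)) && all(dim(object@r) == c(n, n))) {
      surviving <- object@weights != 0
      if (any(object@r[surviving] <= object@thresholdR))
        msg <- c(msg, "surviving weights must all have r above the threshold")
    }
    if (is.null(msg)) TRUE else msg
  })

.connectivityMatrix <- function(nodes, r, weights, weightKind, thresholdR) {
  dimnames(r) <- list(nodes, nodes)
  dimnames(weights) <- list(nodes, nodes)
  new("ConnectivityMatrix", nodes = nodes, r = r, weights = weights,
      weightKind = weightKind, thresholdR = thresholdR)
}

#' GlobalNetworkProperties: the three global graph metrics of one network
#'
#' @slot fcStrength sum of suprathreshold edge weights (each undirected edge
#'   counted once).
#' @slot globalEfficiency mean inverse weighted shortest-path length over
#'   unordered node pairs.
#' @slot localEfficiency mean over nodes of the global efficiency of each
#'   node's neighbourhood subgraph.
#' @slot nNodes,nEdges node and surviving-edge counts.
#' @seealso [globalNetworkProperties()]
#' @export
setClass("GlobalNetworkProperties",
  representation(fcStrength = "numeric", globalEfficiency = "numeric",
                 localEfficiency = "numeric", nNodes = "integer",
                 nEdges = "integer"))

## ---- show methods -----------------------------------------------------------

setMethod("show", "NetworkDefinition", function(object) {
  h <- table(factor(object@nodes$hemisphere, c("L", "R", "midline")))
  cat(sprintf("NetworkDefinition '%s': %d nodes (%d L, %d R, %d midline)\n",
              object@name, nrow(object@nodes), h[["L"]], h[["R"]],
              h[["midline"]]))
})

setMethod("show", "SubjectTimeSeries", function(object) {
  cat(sprintf(
    "SubjectTimeSeries: %d volumes x %d nodes, TR = %gs%s%s\n",
    nrow(object@signals), ncol(object@signals), object@trSeconds,
    if (!is.na(object@subject)) paste0(", subject ", object@subject) else "",
    if (!is.na(object@timepoint)) paste0(" [", object@timepoint, "]") else ""))
  if (nrow(object@motion)) cat("  motion trace attached\n")
  if (length(object@processingLog))
    cat("  processing:", paste(unlist(object@processingLog), collapse = "; "),
        "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  ne <- sum(object@weights[upper.tri(object@weights)] != 0)
  cat(sprintf("ConnectivityMatrix: %d nodes, %d non-zero edges, weights = %s%s\n",
              length(object@nodes), ne, object@weightKind,
              if (!is.na(object@thresholdR))
                sprintf(", thresholded at r > %g", object@thresholdR) else ""))
})

setMethod("show", "GlobalNetworkProperties", function(object) {
  cat(sprintf(
    "GlobalNetworkProperties: FC strength %.4f, gE %.4f, lE %.4f (%d nodes, %d edges)\n",
    object@fcStrength, object@globalEfficiency, object@localEfficiency,
    object@nNodes, object@nEdges))
})
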