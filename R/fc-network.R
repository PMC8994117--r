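#' @include AllClasses.R
NULL

#' Packaged networks of interest
#'
#' Returns one of the packaged node sets:
#' \describe{
#'   \item{`language`}{68 cortical regions, 34 per hemisphere, spanning the
#'     bilateral inferior/middle/superior frontal gyri, superior/middle/
#'     inferior temporal gyri, pre- and postcentral gyri and inferior
#'     parietal lobule.}
#'   \item{`co_fp`}{the combined cognitive-control set: 7 cingulo-opercular
#'     regions plus 11 fronto-parietal regions.}
#'   \item{`dmn`}{default-mode reference network (bilateral posterior
#'     cingulate, ventromedial prefrontal cortex, temporoparietal junction).}
#'   \item{`men`}{motor-execution reference network.}
#' }
#'
#' The packaged tables carry node ids, hemispheres and region labels only.
#' Region-level parcel identities and coordinates are schematic stand-ins
#' with the documented structure (node counts and hemispheric symmetry), not
#' a reproduction of any atlas parcellation; the fixture files are named
#' `*_schematic.json` accordingly. Supply your own node set via
#' [readNodesetJSON()] for real parcellations.
#'
#' @param name one of `"language"`, `"co_fp"`, `"dmn"`, `"men"`.
#' @return A [NetworkDefinition-class] object.
#' @examples
#' length(builtinNetwork("language"))  # 68
#' @export
builtinNetwork <- function(name = c("language", "co_fp", "dmn", "men")) {
  name <- match.arg(name)
  path <- system.file("extdata", "nodesets",
                      paste0(name, "_schematic.json"),
                      package = "fcRecovery", mustWork = TRUE)
  readNodesetJSON(path)
}

#' Pairwise Pearson correlation network of a scan
#'
#' Computes the Pearson correlation between every pair of node time courses
#' over the (surviving) volumes of a scan. Zero-variance nodes get zero
#' edges, with a warning. The diagonal is stored as 0.
#'
#' @param ts a [SubjectTimeSeries-class] object.
#' @param nodes optional character vector restricting/ordering the nodes; by
#'   default all nodes of the scan.
#' @return A [ConnectivityMatrix-class] with `weightKind = "pearson_r"`.
#' @export
correlationMatrix <- function(ts, nodes = NULL) {
  x <- signalMatrix(ts)
  if (nrow(x) < 3L)
    stop("at least 3 surviving volumes are required for correlation")
  if (!is.null(nodes)) {
    missing <- setdiff(nodes, colnames(x))
    if (length(missing))
      stop("requested nodes not present: ", paste(missing, collapse = ", "))
    x <- x[, nodes, drop = FALSE]
  }
  sds <- apply(x, 2L, stats::sd)
  zeroVar <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(stats::cor(x))
  if (any(zeroVar)) {
    warning("zero-variance node(s): ",
            paste(colnames(x)[zeroVar], collapse = ", "),
            "; their edges are set to 0")
    r[zeroVar, ] <- 0
    r[, zeroVar] <- 0
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  r <- (r + t(r)) / 2
  .connectivityMatrix(colnames(x), r, r, "pearson_r", NA_real_)
}

.fisherZ <- function(r, clamp = 1 - 1e-7) atanh(pmin(pmax(r, -clamp), clamp))

#' Fisher r-to-z transformation of a connectivity matrix
#'
#' Applies `z = atanh(r)` element-wise to the active weights. Correlations of
#' exactly +/-1 are clamped to +/-(1 - 1e-7) before transforming (with a
#' message), since `atanh(+/-1)` is infinite.
#'
#' @param cm a [ConnectivityMatrix-class] with `weightKind = "pearson_r"`.
#' @return A [ConnectivityMatrix-class] with `weightKind = "fisher_z"`; the
#'   underlying r matrix is retained, and any applied threshold is preserved.
#' @export
fisherZ <- function(cm) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  if (weightKind(cm) != "pearson_r")
    stop("fisherZ expects pearson_r weights")
  w <- edgeWeights(cm)
  if (any(abs(w) >= 1))
    message("correlations of magnitude 1 clamped to 1 - 1e-7 before atanh")
  z <- .fisherZ(w)
  z[w == 0] <- 0   # absent edges stay absent
  .connectivityMatrix(nodeIds(cm), corMatrix(cm), z, "fisher_z",
                      thresholdR(cm))
}

#' Remove weak connections by correlation thresholding
#'
#' Edges with `r <= rThreshold` are removed (strict inequality: only
#' `r > rThreshold` survives, so negative correlations never survive a
#' positive threshold). Thresholding is always applied to the Pearson
#' correlations, regardless of the weight semantics; surviving edges carry
#' Fisher-z weights by default, or raw correlations with
#' `weightKind = "pearson_r"`.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param rThreshold correlation threshold, strictly inside (-1, 1)
#'   (default 0.2).
#' @param weightKind weight semantics of the surviving edges, `"fisher_z"`
#'   (default) or `"pearson_r"`.
#' @return A thresholded [ConnectivityMatrix-class].
#' @export
thresholdNetwork <- function(cm, rThreshold = 0.2,
                             weightKind = c("fisher_z", "pearson_r")) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  weightKind <- match.arg(weightKind)
  if (rThreshold <= -1 || rThreshold >= 1)
    stop("rThreshold must lie strictly inside (-1, 1)")
  r <- corMatrix(cm)
  keep <- r > rThreshold
  diag(keep) <- FALSE
  w <- if (weightKind == "fisher_z") .fisherZ(r) else r
  w[!keep] <- 0
  .connectivityMatrix(nodeIds(cm), r, w, weightKind, rThreshold)
}

.FC_BINS <- c(fair = 0.2, moderate = 0.4, strong = 0.6)

.edgeClass <- function(h1, h2) {
  if (h1 == "midline" && h2 == "midline") return("midline")
  ## a midline node counts as ipsilateral to the other endpoint's side
  if (h1 == "midline") h1 <- h2
  if (h2 == "midline") h2 <- h1
  if (h1 != h2) "interhemispheric"
  else if (h1 == "L") "ipsi_left"
  else "ipsi_right"
}

.fcBin <- function(r, breaks = .FC_BINS) {
  cut(r, breaks = c(-Inf, breaks, Inf),
      labels = c("subthreshold", names(breaks)), right = FALSE)
}

#' Classify edges by hemisphere and connectivity-strength bin
#'
#' Each surviving edge is classified by its endpoint hemispheres
#' (`ipsi_left`, `ipsi_right`, `interhemispheric`; a midline endpoint counts
#' as ipsilateral to the other endpoint's side, and midline-midline edges
#' are reported separately as class `midline`) and binned by correlation
#' strength. The default bins, used for descriptive summaries, are
#' fair `[0.2, 0.4)`, moderate `[0.4, 0.6)` and strong `[0.6, 1]`.
#'
#' @param cm a (typically thresholded) [ConnectivityMatrix-class].
#' @param network a [NetworkDefinition-class] supplying hemisphere labels
#'   for every node of `cm`.
#' @param binBreaks named ascending numeric vector of lower bin edges
#'   (default `c(fair = 0.2, moderate = 0.4, strong = 0.6)`).
#' @return `data.frame` with columns `node_a`, `node_b`, `r`, `z`, `class`,
#'   `bin`, one row per surviving edge.
#' @export
classifyEdges <- function(cm, network, binBreaks = .FC_BINS) {
  stopifnot(is(cm, "ConnectivityMatrix"), is(network, "NetworkDefinition"))
  hemi <- hemisphere(network)
  missing <- setdiff(nodeIds(cm), names(hemi))
  if (length(missing))
    stop("nodes without hemisphere label: ", paste(missing, collapse = ", "))
  w <- edgeWeights(cm)
  r <- corMatrix(cm)
  ids <- nodeIds(cm)
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(node_a = character(0), node_b = character(0),
                      r = numeric(0), z = numeric(0), class = character(0),
                      bin = character(0)))
  a <- ids[idx[, 1L]]
  b <- ids[idx[, 2L]]
  rv <- r[idx]
  data.frame(
    node_a = a, node_b = b, r = rv, z = .fisherZ(rv),
    class = mapply(.edgeClass, hemi[a], hemi[b], USE.NAMES = FALSE),
    bin = as.character(.fcBin(rv, binBreaks)),
    row.names = NULL)
}
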