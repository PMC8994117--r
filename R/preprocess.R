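#' @include AllClasses.R
NULL

#' Preprocessing configuration
#'
#' Parameters of the ROI-level cleaning pipeline: framewise-displacement
#' scrubbing, nuisance regression, temporal band-pass filtering and the
#' minimum-volume exclusion guard.
#'
#' @param fdThresholdMm framewise displacement above which a volume counts as
#'   sudden head motion, in mm (default 0.5).
#' @param censorBefore,censorAfter volumes removed before / after each bad
#'   volume (defaults 1 and 2).
#' @param bandLowHz,bandHighHz band-pass edges in Hz (defaults 0.01, 0.1).
#' @param minVolumes minimum surviving volumes after scrubbing; fewer raises
#'   a `minimumVolumesError`, signalling the scan must be excluded
#'   (default 140).
#' @param useGlobalSignal include the global signal (plus derivative and
#'   square) among the nuisance regressors (default `TRUE`); the 36-parameter
#'   model becomes a 32-parameter model (8 + 8 + 16) when `FALSE`.
#' @param rotationSphereRadiusMm radius converting rotations to displacement
#'   at the head surface, in mm (default 50).
#' @param nDiscardInitial initial volumes discarded before any cleaning
#'   (default 10).
#' @return A classed list (`PreprocessConfig`).
#' @export
preprocessConfig <- function(fdThresholdMm = 0.5, censorBefore = 1L,
                             censorAfter = 2L, bandLowHz = 0.01,
                             bandHighHz = 0.1, minVolumes = 140L,
                             useGlobalSignal = TRUE,
                             rotationSphereRadiusMm = 50,
                             nDiscardInitial = 10L) {
  stopifnot(fdThresholdMm > 0, censorBefore >= 0, censorAfter >= 0,
            bandLowHz > 0, bandHighHz > bandLowHz, minVolumes >= 0,
            rotationSphereRadiusMm > 0, nDiscardInitial >= 0)
  structure(list(fdThresholdMm = fdThresholdMm,
                 censorBefore = as.integer(censorBefore),
                 censorAfter = as.integer(censorAfter),
                 bandLowHz = bandLowHz, bandHighHz = bandHighHz,
                 minVolumes = as.integer(minVolumes),
                 useGlobalSignal = isTRUE(useGlobalSignal),
                 rotationSphereRadiusMm = rotationSphereRadiusMm,
                 nDiscardInitial = as.integer(nDiscardInitial)),
            class = "PreprocessConfig")
}

#' Framewise displacement from a six-parameter motion trace
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the three translations (mm) plus `radius` times the sum of
#' absolute backward differences of the three rotations (radians), i.e.
#' rotations are converted to arc displacement on a sphere of the given
#' radius. The first volume has FD 0 by convention.
#'
#' @param motion volumes x 6 numeric matrix (`tx,ty,tz,rx,ry,rz`;
#'   translations in mm, rotations in radians).
#' @param radius sphere radius in mm (default 50).
#' @return Numeric vector of per-volume FD values.
#' @examples
#' m <- matrix(0, 10, 6)
#' m[5:10, 1] <- 0.3   # sustained 0.3 mm step in x at volume 5
#' computeFD(m)
#' @export
computeFD <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stop("motion trace must have at least 2 volumes")
  if (ncol(motion) != 6L) stop("motion trace must have 6 columns")
  if (!all(is.finite(motion))) stop("motion trace contains non-finite values")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' Flag high-motion volumes and return the surviving index set
#'
#' Every volume whose FD exceeds the threshold is removed together with
#' `censorBefore` preceding and `censorAfter` following volumes (windows may
#' overlap and are clipped at the series ends). If fewer than
#' `config$minVolumes` volumes survive, an error of class
#' `minimumVolumesError` is raised: the scan does not meet the
#' minimum-data guard and the subject must be excluded from analysis.
#'
#' @param fd per-volume FD series (see [computeFD()]).
#' @param config a [preprocessConfig()] object.
#' @return Integer vector of surviving volume indices, in increasing order.
#' @export
flagAndCensor <- function(fd, config = preprocessConfig()) {
  n <- length(fd)
  bad <- which(fd > config$fdThresholdMm)
  censored <- integer(0)
  if (length(bad)) {
    censored <- unique(unlist(lapply(bad, function(b)
      seq(b - config$censorBefore, b + config$censorAfter))))
    censored <- censored[censored >= 1L & censored <= n]
  }
  kept <- setdiff(seq_len(n), censored)
  if (length(kept) < config$minVolumes)
    stop(errorCondition(
      sprintf("only %d of %d volumes survive scrubbing (minimum %d): scan must be excluded",
              length(kept), n, config$minVolumes),
      class = c("minimumVolumesError", "error")))
  kept
}

#' Build the 36-parameter nuisance design
#'
#' Base signals are the six motion parameters plus the white-matter, CSF and
#' (optionally) global signals (9 columns); their temporal derivatives are
#' backward differences with 0 at the first volume (9 columns); the quadratic
#' terms are the element-wise squares of all 18 base-plus-derivative columns.
#' With the global signal omitted, its derivative and quadratic columns are
#' dropped too, leaving 8 + 8 + 16 = 32 columns.
#'
#' @param motion volumes x 6 motion matrix.
#' @param wm,csf,globalSignal per-volume nuisance signals; `globalSignal`
#'   may be `NULL` when `useGlobal = FALSE`.
#' @param useGlobal include the global-signal column family (default `TRUE`).
#' @return volumes x 36 (or 27) numeric design matrix with named columns.
#' @export
buildNuisanceDesign <- function(motion, wm, csf, globalSignal = NULL,
                                useGlobal = TRUE) {
  motion <- as.matrix(motion)
  n <- nrow(motion)
  if (length(wm) != n || length(csf) != n)
    stop("wm and csf signals must have one value per volume")
  base <- cbind(motion[, 1:6, drop = FALSE], wm = wm, csf = csf)
  colnames(base)[1:6] <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (useGlobal) {
    if (is.null(globalSignal)) stop("global signal required when useGlobal = TRUE")
    if (length(globalSignal) != n)
      stop("global signal must have one value per volume")
    base <- cbind(base, global = globalSignal)
  }
  deriv <- rbind(0, diff(base))
  colnames(deriv) <- paste0("d_", colnames(base))
  bd <- cbind(base, deriv)
  sq <- bd^2
  colnames(sq) <- paste0("sq_", colnames(bd))
  cbind(bd, sq)
}

## least-squares fit with least-norm (pseudo-inverse) fallback when the
## design is rank deficient
.lsResiduals <- function(Y, X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    warning("design matrix is rank deficient; using least-norm solution")
    sv <- svd(X)
    tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
    pos <- sv$d > tol
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
    Y - X %*% beta
  } else {
    qr.resid(qrx, Y)
  }
}

#' Remove nuisance signals by linear regression
#'
#' Regresses every node's time course on the nuisance design (an intercept
#' is always included) and returns the residuals. Residuals are orthogonal
#' to every design column; a rank-deficient design is handled by the
#' least-norm solution with a warning.
#'
#' @param ts a [SubjectTimeSeries-class] object.
#' @param design nuisance design matrix (see [buildNuisanceDesign()]) with
#'   one row per volume.
#' @return A [SubjectTimeSeries-class] with residual signals.
#' @export
regressNuisance <- function(ts, design) {
  design <- as.matrix(design)
  if (nrow(design) != nVolumes(ts))
    stop("design must have one row per volume")
  ## constant columns are collinear with the intercept (and residuals are
  ## trivially orthogonal to them after demeaning): drop them from the fit
  isConst <- apply(design, 2L, function(col) max(col) == min(col))
  X <- cbind(intercept = 1, design[, !isConst, drop = FALSE])
  res <- .lsResiduals(signalMatrix(ts), X)
  out <- ts
  out@signals <- res
  out@processingLog <- c(ts@processingLog,
                         sprintf("nuisance regression (%d regressors)",
                                 ncol(design)))
  out
}

#' Zero-phase temporal band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the filter is zero-phase. Each node signal is
#' demeaned before filtering; the DC component is therefore removed.
#'
#' @param ts a [SubjectTimeSeries-class] object (TR taken from the object).
#' @param config a [preprocessConfig()] object supplying the band edges.
#' @return A filtered [SubjectTimeSeries-class].
#' @export
bandpass <- function(ts, config = preprocessConfig()) {
  n <- nVolumes(ts)
  if (n < 30L) stop("band-pass filtering needs at least 30 volumes")
  fs <- 1 / trSeconds(ts)
  nyq <- fs / 2
  if (config$bandHighHz >= nyq)
    stop(sprintf("band edge %g Hz is not below the Nyquist frequency %g Hz",
                 config$bandHighHz, nyq))
  bf <- signal::butter(4, c(config$bandLowHz, config$bandHighHz) / nyq,
                       type = "pass")
  x <- signalMatrix(ts)
  x <- sweep(x, 2L, colMeans(x))
  filtered <- apply(x, 2L, function(col) signal::filtfilt(bf, col))
  out <- ts
  out@signals <- filtered
  out@processingLog <- c(ts@processingLog,
                         sprintf("band-pass %g-%g Hz", config$bandLowHz,
                                 config$bandHighHz))
  out
}

.subsetVolumes <- function(ts, idx) {
  out <- ts
  out@signals <- ts@signals[idx, , drop = FALSE]
  if (nrow(ts@motion)) out@motion <- ts@motion[idx, , drop = FALSE]
  if (nrow(ts@nuisance)) out@nuisance <- ts@nuisance[idx, , drop = FALSE]
  out
}

#' Full ROI-level cleaning pipeline for one scan
#'
#' Applies, in order: initial-volume discard, nuisance regression (36- or
#' 27-parameter design built from the attached motion trace and nuisance
#' signals), zero-phase band-pass filtering, and motion scrubbing (volumes
#' with FD above threshold removed together with their censoring windows;
#' removed volumes are dropped, never interpolated). If the global signal is
#' needed but not attached, the mean node signal is used.
#'
#' @param ts a [SubjectTimeSeries-class] with motion trace and nuisance
#'   signals attached.
#' @param config a [preprocessConfig()] object.
#' @return list with `ts` (cleaned [SubjectTimeSeries-class] containing only
#'   surviving volumes), `keptVolumes` (indices into the post-discard
#'   series), and `fd` (the FD series used for scrubbing).
#' @export
preprocessSubject <- function(ts, config = preprocessConfig()) {
  if (!nrow(motionTrace(ts)))
    stop("preprocessSubject requires a motion trace")
  n <- nVolumes(ts)
  if (config$nDiscardInitial >= n - 1L)
    stop("too few volumes after discarding initial volumes")
  keep0 <- seq.int(config$nDiscardInitial + 1L, n)
  ts <- .subsetVolumes(ts, keep0)
  nuis <- nuisanceSignals(ts)
  wm <- if ("wm" %in% names(nuis)) nuis$wm else
    stop("nuisance signals must provide a 'wm' column")
  csf <- if ("csf" %in% names(nuis)) nuis$csf else
    stop("nuisance signals must provide a 'csf' column")
  globalSignal <- NULL
  if (config$useGlobalSignal)
    globalSignal <- if ("global" %in% names(nuis)) nuis$global else
      rowMeans(signalMatrix(ts))
  design <- buildNuisanceDesign(motionTrace(ts), wm, csf, globalSignal,
                                useGlobal = config$useGlobalSignal)
  ts <- regressNuisance(ts, design)
  ts <- bandpass(ts, config)
  fd <- computeFD(motionTrace(ts), config$rotationSphereRadiusMm)
  kept <- flagAndCensor(fd, config)
  out <- .subsetVolumes(ts, kept)
  out@processingLog <- c(out@processingLog,
                         sprintf("scrubbing kept %d/%d volumes", length(kept),
                                 length(fd)))
  list(ts = out, keptVolumes = kept, fd = fd)
}
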