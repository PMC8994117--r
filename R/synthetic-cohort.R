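#' @include AllClasses.R
NULL

#' Configuration of a synthetic longitudinal cohort
#'
#' Bundles the parameters of the synthetic-cohort generator: cohort sizes,
#' acquisition length, the block-structured inter-node covariance of the
#' control population, the AR(1) temporal autocorrelation, the post-operative
#' disruption applied around the designated peritumoral nodes (and their
#' contralateral homologues), the recovery profile over timepoints, the
#' language-score link, and head-motion parameters.
#'
#' Defaults mirror the study conditions the cohort emulates: 26 controls and
#' 34 patients, 240 volumes at TR = 2 s, and a baseline aphasia quotient (AQ)
#' population of mean 90.1 and SD 9.
#'
#' @param nControls,nPatients cohort sizes (defaults 26 and 34).
#' @param nVolumes scan length in volumes (default 240).
#' @param trSeconds repetition time in seconds (default 2).
#' @param baseWithinCorr within-network correlation of the control covariance
#'   (default 0.45).
#' @param baseBetweenCorr between-network correlation (default 0.08).
#' @param ar1Coeff lag-1 autoregression coefficient of the temporal process,
#'   in `[0, 1)` (default 0.3).
#' @param disruptionFrac fraction by which connectivity incident to the
#'   peritumoral neighbourhood is attenuated at the subacute timepoint, in
#'   `[0, 1]` (default 0.5).
#' @param recoveryProfile named numeric vector mapping timepoints to the
#'   fraction of the disruption remaining; must be 1 at the first
#'   post-operative timepoint present and 0 at `pre`. Default
#'   `c(pre = 0, w2 = 1, m1 = 0.5, m3 = 0, m6 = 0)`: full disruption two weeks
#'   after surgery, half remaining at one month, fully recovered in the
#'   chronic phase.
#' @param tumourNodeFrac fraction of one hemisphere's nodes designated
#'   peritumoral (default 0.25).
#' @param languageLinkSlope AQ points lost per unit attenuation fraction,
#'   divided by 100 (default 0.4: full attenuation costs 40 AQ points).
#' @param languageLinkNoiseSd SD of Gaussian noise added to generated AQ
#'   (default 2).
#' @param baselineAqMean,baselineAqSd baseline AQ population parameters
#'   (defaults 90.1 and 9).
#' @param globalArtifactSd SD of the shared global artifact added to every
#'   node signal (default 0.5, i.e. half the neural signal SD); the
#'   `global` nuisance channel measures this artifact, so global-signal
#'   regression removes it.
#' @param nMotionSpikes number of sudden head-motion events per scan
#'   (default 2).
#' @param motionSpikeMm size of each motion event as a sustained translation
#'   step, in mm (default 0.8; above the usual 0.5 mm framewise-displacement
#'   threshold so each spike is censored).
#' @param motionJitterSd SD of the per-volume random-walk steps of the
#'   translation parameters, in mm (default 0.01).
#' @param seed integer seed making the cohort fully reproducible.
#' @return A classed list (`CohortConfig`) of validated parameters.
#' @examples
#' cfg <- cohortConfig(nControls = 4, nPatients = 2, seed = 1)
#' cfg$nVolumes
#' @export
cohortConfig <- function(nControls = 26, nPatients = 34, nVolumes = 240,
                         trSeconds = 2, baseWithinCorr = 0.45,
                         baseBetweenCorr = 0.08, ar1Coeff = 0.3,
                         disruptionFrac = 0.5,
                         recoveryProfile = c(pre = 0, w2 = 1, m1 = 0.5,
                                             m3 = 0, m6 = 0),
                         tumourNodeFrac = 0.25, languageLinkSlope = 0.4,
                         languageLinkNoiseSd = 2, baselineAqMean = 90.1,
                         baselineAqSd = 9, globalArtifactSd = 0.5,
                         nMotionSpikes = 2,
                         motionSpikeMm = 0.8, motionJitterSd = 0.01,
                         seed = 1L) {
  stopifnot(nControls >= 1, nPatients >= 0, nVolumes >= 2, trSeconds > 0,
            baseWithinCorr >= 0, baseWithinCorr < 1,
            abs(baseBetweenCorr) < 1,
            ar1Coeff >= 0, ar1Coeff < 1,
            disruptionFrac >= 0, disruptionFrac <= 1,
            tumourNodeFrac > 0, tumourNodeFrac <= 1,
            languageLinkNoiseSd >= 0, globalArtifactSd >= 0,
            nMotionSpikes >= 0,
            motionSpikeMm >= 0, motionJitterSd >= 0)
  if (is.null(names(recoveryProfile)) ||
      !all(names(recoveryProfile) %in% .TIMEPOINTS))
    stop("recoveryProfile must be named with timepoints among ",
         paste(.TIMEPOINTS, collapse = ", "))
  if (any(recoveryProfile < 0 | recoveryProfile > 1))
    stop("recoveryProfile values must lie in [0, 1]")
  post <- intersect(.TIMEPOINTS[-1], names(recoveryProfile))
  if (disruptionFrac > 0 && length(post) &&
      recoveryProfile[[post[1]]] != 1)
    stop("recoveryProfile must equal 1 at the subacute (first post-operative) ",
         "timepoint for disrupted patients")
  structure(list(
    nControls = as.integer(nControls), nPatients = as.integer(nPatients),
    nVolumes = as.integer(nVolumes), trSeconds = trSeconds,
    baseWithinCorr = baseWithinCorr, baseBetweenCorr = baseBetweenCorr,
    ar1Coeff = ar1Coeff, disruptionFrac = disruptionFrac,
    recoveryProfile = recoveryProfile, tumourNodeFrac = tumourNodeFrac,
    languageLinkSlope = languageLinkSlope,
    languageLinkNoiseSd = languageLinkNoiseSd,
    baselineAqMean = baselineAqMean, baselineAqSd = baselineAqSd,
    globalArtifactSd = globalArtifactSd,
    nMotionSpikes = as.integer(nMotionSpikes), motionSpikeMm = motionSpikeMm,
    motionJitterSd = motionJitterSd, seed = as.integer(seed)),
    class = "CohortConfig")
}

## eigenvalue clipping at 0, then rescale to unit diagonal; attaches the
## largest absolute entry change as attribute "repair"
.nearPSDCorr <- function(m, maxRepair = 0.05) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 0) {
    attr(m, "repair") <- 0
    return(m)
  }
  v <- pmax(e$values, 0)
  r <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  repair <- max(abs(r - m))
  if (repair > maxRepair)
    stop(sprintf(
      "correlation structure is not achievable: positive-semi-definite repair changed an entry by %.3f (> %.3f)",
      repair, maxRepair))
  dimnames(r) <- dimnames(m)
  attr(r, "repair") <- repair
  r
}

#' Build the block-structured target covariance of the control population
#'
#' Constructs a node-by-node correlation matrix with unit diagonal,
#' `withinCorr` on off-diagonal entries joining nodes of the same network and
#' `betweenCorr` between networks. If the construction is not positive
#' semi-definite it is repaired by eigenvalue clipping followed by rescaling
#' to unit diagonal; a repair that changes any entry by more than `maxRepair`
#' is an error (the requested structure is then considered unachievable).
#'
#' @param networks list of [NetworkDefinition-class] objects with disjoint
#'   node sets.
#' @param withinCorr,betweenCorr target correlations (defaults 0.45 / 0.08).
#' @param maxRepair largest tolerated entry change during repair
#'   (default 0.05).
#' @return Correlation matrix with node ids as dimnames and an attribute
#'   `repair` giving the largest entry change applied (0 when none).
#' @examples
#' nets <- list(
#'   NetworkDefinition("a", data.frame(id = c("a1", "a2"),
#'     hemisphere = c("L", "R"), region = "a")),
#'   NetworkDefinition("b", data.frame(id = c("b1", "b2"),
#'     hemisphere = c("L", "R"), region = "b")))
#' buildTargetCovariance(nets, 0.45, 0.08)
#' @export
buildTargetCovariance <- function(networks, withinCorr = 0.45,
                                  betweenCorr = 0.08, maxRepair = 0.05) {
  ids <- unlist(lapply(networks, nodeIds))
  if (anyDuplicated(ids))
    stop("networks must have disjoint node sets")
  member <- rep(seq_along(networks), vapply(networks, length, 1L))
  n <- length(ids)
  m <- matrix(betweenCorr, n, n, dimnames = list(ids, ids))
  for (k in seq_along(networks)) {
    idx <- which(member == k)
    m[idx, idx] <- withinCorr
  }
  diag(m) <- 1
  .nearPSDCorr(m, maxRepair)
}

#' Simulate a stationary Gaussian AR(1) multivariate time series
#'
#' Draws a volumes-by-nodes series from a stationary first-order
#' autoregressive Gaussian process whose cross-sectional (stationary)
#' covariance equals `cov`: the initial state is `N(0, cov)` and innovations
#' have covariance `(1 - ar1^2) * cov`, so the marginal covariance is `cov`
#' at every volume.
#'
#' @param cov positive semi-definite covariance matrix (node dimnames used as
#'   node ids).
#' @param nVolumes number of volumes (>= 2).
#' @param ar1 autoregression coefficient in `[0, 1)`.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param trSeconds repetition time attached to the result (default 2).
#' @param subject,timepoint identifiers attached to the result.
#' @return A [SubjectTimeSeries-class] object (no motion trace attached).
#' @examples
#' cov <- diag(3); dimnames(cov) <- list(letters[1:3], letters[1:3])
#' ts <- simulateTimeseries(cov, 50, ar1 = 0.3, seed = 7)
#' nVolumes(ts)
#' @export
simulateTimeseries <- function(cov, nVolumes, ar1 = 0.3, seed = 1L,
                               trSeconds = 2, subject = NA_character_,
                               timepoint = NA_character_) {
  if (nVolumes < 2) stop("nVolumes must be at least 2")
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1)")
  cov <- as.matrix(cov)
  n <- ncol(cov)
  ids <- colnames(cov)
  if (is.null(ids)) ids <- sprintf("node%02d", seq_len(n))
  e <- eigen(cov, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    stop("cov must be positive semi-definite")
  ## matrix square root (handles PSD, not just PD)
  sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  x <- withr::with_seed(seed, {
    innov <- matrix(stats::rnorm(nVolumes * n), nVolumes, n) %*% sq
    out <- matrix(0, nVolumes, n)
    out[1L, ] <- innov[1L, ]
    scale <- sqrt(1 - ar1^2)
    for (t in 2:nVolumes)
      out[t, ] <- ar1 * out[t - 1L, ] + scale * innov[t, ]
    out
  })
  colnames(x) <- ids
  SubjectTimeSeries(x, trSeconds = trSeconds, subject = subject,
                    timepoint = timepoint)
}

## contralateral homologue: same within-hemisphere index in the opposite
## hemisphere of the same network (node sets are hemispherically symmetric)
.contralateralHomologues <- function(networks, nodes) {
  out <- character(0)
  for (net in networks) {
    nd <- nodeTable(net)
    left <- nd$id[nd$hemisphere == "L"]
    right <- nd$id[nd$hemisphere == "R"]
    k <- min(length(left), length(right))
    for (nodeId in intersect(nodes, nd$id)) {
      i <- match(nodeId, left)
      if (!is.na(i) && i <= k) out <- c(out, right[i])
      j <- match(nodeId, right)
      if (!is.na(j) && j <= k) out <- c(out, left[j])
    }
  }
  unique(out)
}

#' Attenuate connectivity around a peritumoral node neighbourhood
#'
#' Multiplies every off-diagonal covariance entry incident to the peritumoral
#' nodes, or to their contralateral homologues (same within-hemisphere index
#' in the opposite hemisphere of the same network), by `1 - attenuation`.
#' All other entries are unchanged. The result is repaired to positive
#' semi-definiteness if needed, as in [buildTargetCovariance()].
#'
#' @param cov node-by-node covariance with node-id dimnames.
#' @param networks list of [NetworkDefinition-class] objects covering the
#'   nodes (used to find homologues).
#' @param peritumoralNodes character vector of node ids, all in one
#'   hemisphere.
#' @param attenuation fraction in `[0, 1]`.
#' @param maxRepair see [buildTargetCovariance()].
#' @return Covariance matrix of the same dimension, attribute `repair` as in
#'   [buildTargetCovariance()], and attribute `affectedNodes` listing the
#'   attenuated nodes (peritumoral plus homologues).
#' @export
applyDisruption <- function(cov, networks, peritumoralNodes, attenuation,
                            maxRepair = 0.05) {
  if (attenuation < 0 || attenuation > 1)
    stop("attenuation must lie in [0, 1]")
  cov <- as.matrix(cov)
  ids <- colnames(cov)
  if (!all(peritumoralNodes %in% ids))
    stop("peritumoralNodes must all be present in cov")
  hemi <- unlist(lapply(networks, hemisphere))
  h <- unique(hemi[peritumoralNodes])
  if (length(setdiff(h, "midline")) > 1L)
    stop("peritumoralNodes must lie within one hemisphere")
  affected <- unique(c(peritumoralNodes,
                       .contralateralHomologues(networks, peritumoralNodes)))
  idx <- match(affected, ids)
  out <- cov
  scale <- 1 - attenuation
  out[idx, ] <- out[idx, ] * scale
  out[, idx] <- cov[, idx] * scale
  ## entries joining two affected nodes are attenuated once, not twice
  out[idx, idx] <- cov[idx, idx] * scale
  diag(out) <- diag(cov)
  out <- .nearPSDCorr(out, maxRepair)
  attr(out, "affectedNodes") <- affected
  out
}

## six-parameter motion trace: translations follow a small random walk with
## optional sustained step events (spikes); rotations held at 0
.simulateMotion <- function(nVolumes, nSpikes, spikeMm, jitterSd) {
  steps <- matrix(stats::rnorm(nVolumes * 3, sd = jitterSd), nVolumes, 3)
  steps[1L, ] <- 0
  if (nSpikes > 0 && nVolumes > 8L) {
    at <- sample(5:(nVolumes - 3L), nSpikes)
    steps[at, 1L] <- steps[at, 1L] + spikeMm * sample(c(-1, 1), nSpikes, TRUE)
  }
  trans <- apply(steps, 2L, cumsum)
  m <- cbind(trans, matrix(0, nVolumes, 3))
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

## unit-variance stationary AR(1) scalar series
.ar1Series <- function(n, ar1) {
  if (ar1 == 0) return(stats::rnorm(n))
  as.numeric(stats::arima.sim(list(ar = ar1), n)) * sqrt(1 - ar1^2)
}

## One observed scan = neural signal (target covariance) + a shared global
## artifact added to every node. The 'global' nuisance column measures that
## artifact (as a whole-brain global signal would), so regressing it out
## recovers the neural covariance; wm/csf are independent series with a
## small artifact component.
.observeScan <- function(neural, config, seed, subject, timepoint) {
  n <- nrow(neural)
  withr::with_seed(seed, {
    g <- .ar1Series(n, config$ar1Coeff)
    signals <- neural + config$globalArtifactSd * g
    nuis <- data.frame(
      wm = .ar1Series(n, config$ar1Coeff) + 0.3 * g,
      csf = .ar1Series(n, config$ar1Coeff) + 0.3 * g,
      global = g + stats::rnorm(n, sd = 0.02))
    motion <- .simulateMotion(n, config$nMotionSpikes, config$motionSpikeMm,
                              config$motionJitterSd)
    SubjectTimeSeries(signals, trSeconds = config$trSeconds, motion = motion,
                      nuisance = nuis, subject = subject,
                      timepoint = timepoint)
  })
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## AQ deficit distributed proportionally across the four subscores, so that
## the composite formula recovers the AQ exactly
.subscoresFromAQ <- function(aq) {
  f <- aq / 100
  data.frame(ss = 20 * f, com = 230 * f, rep = 100 * f, nam = 100 * f)
}

#' Generate one longitudinal synthetic patient
#'
#' For each requested timepoint, attenuates the control covariance by
#' `disruptionFrac * recoveryProfile[timepoint]` around the peritumoral
#' neighbourhood (and contralateral homologues), simulates an AR(1) time
#' series with motion trace and nuisance signals, and generates a language
#' record whose AQ is a noisy linear function of the current attenuation:
#' `AQ = baselineAQ - languageLinkSlope * attenuation * 100 + noise`,
#' clamped to `[0, 100]`, with subscores back-solved to be consistent with
#' the composite AQ formula.
#'
#' @param config a [cohortConfig()] object.
#' @param networks list of [NetworkDefinition-class] objects.
#' @param timepoints subset of `c("pre","w2","m1","m3","m6")`; only
#'   timepoints present in `config$recoveryProfile` are meaningful.
#' @param subject subject id string.
#' @param seed integer seed for this patient.
#' @param includeTimeseries set `FALSE` to skip time-series simulation and
#'   generate language records only (fast path for behavioural simulations).
#' @return list with elements `timeseries` (named list of
#'   [SubjectTimeSeries-class], one per timepoint; `NULL` when
#'   `includeTimeseries = FALSE`), `language` (`data.frame` with columns
#'   `subject, timepoint, ss, com, rep, nam, aq`), `peritumoralNodes`, and
#'   `attenuation` (named per-timepoint fractions).
#' @export
generatePatient <- function(config, networks, timepoints = .TIMEPOINTS,
                            subject = "P001", seed = 1L,
                            includeTimeseries = TRUE) {
  stopifnot(inherits(config, "CohortConfig"))
  timepoints <- intersect(.TIMEPOINTS, timepoints)
  if (!length(timepoints)) stop("no valid timepoints requested")
  unknown <- setdiff(timepoints, c("pre", names(config$recoveryProfile)))
  if (length(unknown))
    stop("recoveryProfile has no value for timepoint(s): ",
         paste(unknown, collapse = ", "))
  baseCov <- buildTargetCovariance(networks, config$baseWithinCorr,
                                   config$baseBetweenCorr)
  firstNet <- nodeTable(networks[[1L]])
  left <- firstNet$id[firstNet$hemisphere == "L"]
  nPeri <- max(1L, ceiling(config$tumourNodeFrac * length(left)))
  peri <- left[seq_len(nPeri)]
  prof <- config$recoveryProfile
  prof["pre"] <- 0
  att <- vapply(timepoints,
                function(tp) config$disruptionFrac * prof[[tp]], 1.0)
  names(att) <- timepoints

  lang <- withr::with_seed(seed, {
    baseline <- .clamp(stats::rnorm(1, config$baselineAqMean,
                                    config$baselineAqSd), 0, 100)
    .clamp(baseline - config$languageLinkSlope * att * 100 +
             stats::rnorm(length(att), 0, config$languageLinkNoiseSd),
           0, 100)
  })
  sub <- .subscoresFromAQ(lang)
  langDf <- data.frame(subject = subject, timepoint = timepoints,
                       ss = sub$ss, com = sub$com, rep = sub$rep,
                       nam = sub$nam, aq = as.numeric(lang),
                       row.names = NULL)

  tsList <- NULL
  if (includeTimeseries) {
    tsList <- vector("list", length(timepoints))
    names(tsList) <- timepoints
    for (i in seq_along(timepoints)) {
      tp <- timepoints[i]
      cv <- if (att[[tp]] > 0)
        applyDisruption(baseCov, networks, peri, att[[tp]])
      else baseCov
      tpSeed <- (seed * 53L + i * 101L) %% 2147483647L
      ts <- simulateTimeseries(cv, config$nVolumes, config$ar1Coeff,
                               seed = tpSeed, trSeconds = config$trSeconds,
                               subject = subject, timepoint = tp)
      tsList[[tp]] <- .observeScan(signalMatrix(ts), config, tpSeed + 1L,
                                   subject, tp)
    }
  }
  list(timeseries = tsList, language = langDf, peritumoralNodes = peri,
       attenuation = att)
}

#' Generate one synthetic control subject
#'
#' A single-run scan drawn from the undisrupted control covariance, with
#' motion trace and nuisance signals.
#'
#' @inheritParams generatePatient
#' @return A [SubjectTimeSeries-class] object.
#' @export
generateControl <- function(config, networks, subject = "C001", seed = 1L) {
  stopifnot(inherits(config, "CohortConfig"))
  baseCov <- buildTargetCovariance(networks, config$baseWithinCorr,
                                   config$baseBetweenCorr)
  ts <- simulateTimeseries(baseCov, config$nVolumes, config$ar1Coeff,
                           seed = seed, trSeconds = config$trSeconds,
                           subject = subject, timepoint = "control")
  .observeScan(signalMatrix(ts), config, (seed * 97L + 11L) %% 2147483647L,
               subject, "control")
}

#' Generate a full synthetic cohort
#'
#' Controls are single-run scans from the undisrupted covariance; patients
#' are observed at the timepoints of `config$recoveryProfile` (plus `pre`)
#' with connectivity attenuation scaled by the recovery profile. Per-subject
#' seeds are derived deterministically from `config$seed`, so identical
#' configurations yield bit-identical cohorts.
#'
#' @param config a [cohortConfig()] object.
#' @param networks list of [NetworkDefinition-class] objects.
#' @param includeTimeseries see [generatePatient()].
#' @return list with `controls` (list of [SubjectTimeSeries-class]),
#'   `patients` (list of [generatePatient()] results), `language` (combined
#'   language `data.frame`), and `manifest` (`data.frame` of subject ids,
#'   roles and seeds).
#' @export
generateCohort <- function(config, networks, includeTimeseries = TRUE) {
  stopifnot(inherits(config, "CohortConfig"))
  ctrlIds <- sprintf("C%03d", seq_len(config$nControls))
  patIds <- sprintf("P%03d", seq_len(config$nPatients))
  ctrlSeeds <- (config$seed + 1000L + seq_len(config$nControls)) %% 2147483647L
  patSeeds <- (config$seed + 2000L + seq_len(config$nPatients)) %% 2147483647L
  controls <- mapply(function(id, s)
    generateControl(config, networks, subject = id, seed = s),
    ctrlIds, ctrlSeeds, SIMPLIFY = FALSE)
  tps <- intersect(.TIMEPOINTS, unique(c("pre", names(config$recoveryProfile))))
  patients <- mapply(function(id, s)
    generatePatient(config, networks, timepoints = tps, subject = id,
                    seed = s, includeTimeseries = includeTimeseries),
    patIds, patSeeds, SIMPLIFY = FALSE)
  language <- do.call(rbind, c(lapply(patients, `[[`, "language"),
                               make.row.names = FALSE))
  manifest <- data.frame(
    subject = c(ctrlIds, patIds),
    role = c(rep("control", config$nControls),
             rep("patient", config$nPatients)),
    seed = c(ctrlSeeds, patSeeds), row.names = NULL)
  list(controls = controls, patients = patients, language = language,
       manifest = manifest)
}
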