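#' @include AllClasses.R
NULL

#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the cohort (either a
#' [cohortConfig()] to simulate, or an already-assembled cohort list shaped
#' like the output of [generateCohort()] -- e.g. built from files with
#' [readTimeseriesTSV()] and [readScoresTSV()]), the networks of interest,
#' the correlation threshold list, and the preprocessing configuration.
#'
#' @param cohort a [cohortConfig()] object, or a list with elements
#'   `controls`, `patients`, `language` as produced by [generateCohort()].
#' @param networks list of [NetworkDefinition-class] objects (at least one).
#' @param thresholds numeric vector of correlation thresholds, strictly in
#'   (0, 1) (default 0.2; the common sensitivity variants are 0.1 and 0.3).
#' @param preprocess a [preprocessConfig()] object; set
#'   `useGlobalSignal = FALSE` there for the no-global-signal variant.
#' @param outputDir directory for report tables and provenance, or `NULL`
#'   to skip writing.
#' @param seed integer seed for the run; overrides the cohort seed so a
#'   `RunConfig` is self-contained.
#' @return A classed list (`RunConfig`).
#' @export
runConfig <- function(cohort, networks, thresholds = 0.2,
                      preprocess = preprocessConfig(), outputDir = NULL,
                      seed = 1L) {
  stopifnot(length(networks) >= 1,
            all(vapply(networks, is, TRUE, "NetworkDefinition")),
            all(thresholds > 0 & thresholds < 1),
            inherits(preprocess, "PreprocessConfig"))
  if (inherits(cohort, "CohortConfig")) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, networks = networks,
                 thresholds = sort(thresholds), preprocess = preprocess,
                 outputDir = outputDir, seed = as.integer(seed)),
            class = "RunConfig")
}

.propertiesRow <- function(cm) {
  p <- globalNetworkProperties(cm)
  c(fc_strength = p@fcStrength, global_efficiency = p@globalEfficiency,
    local_efficiency = p@localEfficiency)
}

.METRICS <- c("fc_strength", "global_efficiency", "local_efficiency")

## per-network/threshold metrics for one cleaned scan; excluded (lesioned)
## nodes are dropped from the node set before correlation
.tsMetrics <- function(pp, networks, thresholds, subject, timepoint,
                       excludeNodes = NULL) {
  out <- list()
  for (net in networks) {
    ids <- setdiff(nodeIds(net), excludeNodes)
    cmFull <- correlationMatrix(pp, ids)
    for (thr in thresholds) {
      cm <- thresholdNetwork(cmFull, thr)
      out[[length(out) + 1L]] <- data.frame(
        subject = subject, timepoint = timepoint,
        network = networkName(net), threshold = thr,
        t(.propertiesRow(cm)), row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Run the full recovery-analysis pipeline
#'
#' Simulates (or takes) a cohort, preprocesses every scan, builds
#' thresholded connectivity networks, computes global network properties and
#' control-referenced Z-scores, scores language recovery, and assembles the
#' group-level tables: per-timepoint paired t-tests against the preoperative
#' baseline (for AQ and each Z-scored network property) and the correlation
#' between the AQ recovery ratio and each network recovery ratio. Scans
#' failing the minimum-volume guard are excluded and listed; the run
#' continues. Deterministic given the configuration and seed.
#'
#' A patient entry may carry an `excludeNodes` character vector naming
#' lesioned nodes: those nodes are dropped from the patient's matrices
#' *and* from the control reference used for that patient's Z-scores, so
#' patient and reference are always computed on the same node set.
#'
#' @param config a [runConfig()] object.
#' @return list with `metrics` (per subject x timepoint x network x
#'   threshold properties and Z-scores), `controlMetrics`, `language`,
#'   `recovery` (per-patient class, AQ ratio and network recovery ratios),
#'   `pairedTests`, `ratioCorrelations`, `exclusions` and `config`. Tables
#'   are also written to `config$outputDir` when set, together with a
#'   provenance JSON.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  cohort <- config$cohort
  if (inherits(cohort, "CohortConfig"))
    cohort <- generateCohort(cohort, config$networks)
  prep <- config$preprocess
  exclusions <- data.frame(subject = character(0), timepoint = character(0),
                           reason = character(0))
  note <- function(sub, tp, why)
    exclusions[nrow(exclusions) + 1L, ] <<- list(sub, tp, why)

  ## preprocess controls once; cleaned series are reused for any patient
  ## whose lesioned-node exclusions need a matched control reference
  ctrlClean <- list()
  ctrlRows <- list()
  for (ts in cohort$controls) {
    pp <- tryCatch(preprocessSubject(ts, prep)$ts,
                   minimumVolumesError = function(e) {
                     note(ts@subject, "control", conditionMessage(e))
                     NULL
                   })
    if (is.null(pp)) next
    ctrlClean[[ts@subject]] <- pp
    ctrlRows[[length(ctrlRows) + 1L]] <-
      .tsMetrics(pp, config$networks, config$thresholds, ts@subject,
                 "control")
  }
  controlMetrics <- do.call(rbind, ctrlRows)
  if (is.null(controlMetrics) || !nrow(controlMetrics))
    stop("no control scans survived preprocessing")

  patRows <- list()
  for (pat in cohort$patients) {
    excl <- pat$excludeNodes
    for (ts in pat$timeseries) {
      row <- tryCatch({
        pp <- preprocessSubject(ts, prep)$ts
        .tsMetrics(pp, config$networks, config$thresholds, ts@subject,
                   ts@timepoint, excludeNodes = excl)
      }, minimumVolumesError = function(e) {
        note(ts@subject, ts@timepoint, conditionMessage(e))
        NULL
      })
      if (!is.null(row)) {
        row$excluded_nodes <- length(excl)
        patRows[[length(patRows) + 1L]] <- row
      }
    }
  }
  metrics <- do.call(rbind, patRows)

  ## Z-scores against the control distribution, per network/threshold/metric;
  ## patients with excluded nodes get a control reference recomputed on the
  ## same reduced node set
  exclBySubject <- lapply(cohort$patients, `[[`, "excludeNodes")
  names(exclBySubject) <- vapply(cohort$patients,
                                 function(p) p$language$subject[1L], "")
  for (m in .METRICS) metrics[[paste0("z_", m)]] <- NA_real_
  for (net in unique(metrics$network)) {
    for (thr in unique(metrics$threshold)) {
      ci <- controlMetrics$network == net & controlMetrics$threshold == thr
      pi <- metrics$network == net & metrics$threshold == thr
      plain <- pi & metrics$excluded_nodes == 0L
      for (m in .METRICS)
        metrics[plain, paste0("z_", m)] <-
          networkZscore(metrics[plain, m], controlMetrics[ci, m])
      for (sub in unique(metrics$subject[pi & metrics$excluded_nodes > 0L])) {
        netDef <- config$networks[[match(net, vapply(config$networks,
                                                     networkName, ""))]]
        ref <- vapply(ctrlClean, function(pp) {
          cm <- thresholdNetwork(correlationMatrix(
            pp, setdiff(nodeIds(netDef), exclBySubject[[sub]])), thr)
          .propertiesRow(cm)
        }, numeric(3))
        si <- pi & metrics$subject == sub
        for (m in .METRICS)
          metrics[si, paste0("z_", m)] <-
            networkZscore(metrics[si, m], ref[m, ])
      }
    }
  }

  ## language scoring
  language <- cohort$language
  recRows <- list()
  for (sub in unique(language$subject)) {
    ls <- language[language$subject == sub, ]
    aq <- stats::setNames(ls$aq, ls$timepoint)
    cls <- tryCatch(classifyRecovery(aq), error = function(e) NA_character_)
    rr <- tryCatch(recoveryRatio(aq), error = function(e) NULL)
    row <- data.frame(subject = sub, recovery = cls,
                      aq_ratio = if (is.null(rr)) NA_real_ else rr$value,
                      aq_ratio_capped = if (is.null(rr)) NA else rr$capped,
                      row.names = NULL)
    ## network recovery ratios from the Z-score trajectories
    for (net in unique(metrics$network)) {
      for (thr in unique(metrics$threshold)) {
        sel <- metrics$subject == sub & metrics$network == net &
          metrics$threshold == thr
        for (m in .METRICS) {
          zs <- stats::setNames(metrics[sel, paste0("z_", m)],
                                metrics$timepoint[sel])
          nr <- tryCatch(recoveryRatio(zs)$value, error = function(e) NA_real_)
          row[[sprintf("net_ratio_%s_%s_thr%g", net, m, thr)]] <- nr
        }
      }
    }
    recRows[[length(recRows) + 1L]] <- row
  }
  recovery <- do.call(rbind, recRows)

  ## paired t-tests against the preoperative baseline
  ptRows <- list()
  addPaired <- function(measure, df, valueCol) {
    pre <- df[df$timepoint == "pre", c("subject", valueCol)]
    for (tp in setdiff(unique(df$timepoint), "pre")) {
      cur <- df[df$timepoint == tp, c("subject", valueCol)]
      merged <- merge(pre, cur, by = "subject")
      if (nrow(merged) < 2L) next
      res <- tryCatch(pairedT(merged[[2L]], merged[[3L]]),
                      error = function(e) NULL)
      if (is.null(res)) next
      ptRows[[length(ptRows) + 1L]] <<- data.frame(
        measure = measure, timepoint = tp, n = nrow(merged),
        t = res$t, df = res$df, p = res$p, row.names = NULL)
    }
  }
  addPaired("aq", data.frame(subject = language$subject,
                             timepoint = language$timepoint,
                             value = language$aq), "value")
  for (net in unique(metrics$network))
    for (thr in unique(metrics$threshold))
      for (m in .METRICS) {
        sel <- metrics$network == net & metrics$threshold == thr
        addPaired(sprintf("z_%s_%s_thr%g", net, m, thr),
                  metrics[sel, c("subject", "timepoint", paste0("z_", m))],
                  paste0("z_", m))
      }
  pairedTests <- do.call(rbind, ptRows)

  ## association between AQ recovery ratio and network recovery ratios
  corRows <- list()
  covars <- NULL
  if (all(c("sex", "age", "education", "grade") %in% colnames(language))) {
    cv <- unique(language[c("subject", "sex", "age", "education", "grade")])
    covars <- cv[match(recovery$subject, cv$subject), -1L]
    covars$sex <- as.numeric(factor(covars$sex))
  }
  netCols <- grep("^net_ratio_", colnames(recovery), value = TRUE)
  for (cl in netCols) {
    ok <- is.finite(recovery$aq_ratio) & is.finite(recovery[[cl]])
    k <- if (is.null(covars)) 0L else ncol(covars)
    if (sum(ok) <= k + 2L) next
    pc <- partialCorrelation(recovery$aq_ratio[ok], recovery[[cl]][ok],
                             if (is.null(covars)) NULL else covars[ok, ])
    corRows[[length(corRows) + 1L]] <- data.frame(
      network_ratio = cl, n = sum(ok), r = pc$r, df = pc$df, p = pc$p,
      row.names = NULL)
  }
  ratioCorrelations <- do.call(rbind, corRows)

  result <- list(metrics = metrics, controlMetrics = controlMetrics,
                 language = language, recovery = recovery,
                 pairedTests = pairedTests,
                 ratioCorrelations = ratioCorrelations,
                 exclusions = exclusions, config = config)
  if (!is.null(config$outputDir)) .writeRunReport(result, config$outputDir)
  result
}

.writeRunReport <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) if (!is.null(df))
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(result$metrics, "patient_metrics.tsv")
  wt(result$controlMetrics, "control_metrics.tsv")
  wt(result$language, "language_scores.tsv")
  wt(result$recovery, "recovery.tsv")
  wt(result$pairedTests, "paired_tests.tsv")
  wt(result$ratioCorrelations, "ratio_correlations.tsv")
  wt(result$exclusions, "exclusions.tsv")
  cfg <- result$config
  prov <- list(
    seed = cfg$seed, thresholds = cfg$thresholds,
    networks = vapply(cfg$networks, networkName, ""),
    preprocess = unclass(cfg$preprocess),
    cohort = if (inherits(cfg$cohort, "CohortConfig"))
      lapply(unclass(cfg$cohort), function(v)
        if (is.null(names(v))) v else as.list(v))
      else "user-supplied",
    package_version = as.character(utils::packageVersion("fcRecovery")))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
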