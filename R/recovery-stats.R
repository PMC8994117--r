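#' @include AllClasses.R
NULL

.AQ_MAX <- c(ss = 20, com = 230, rep = 100, nam = 100)

#' Aphasia quotient from the four language subscores
#'
#' `AQ = (S_ss + S_com/23 + S_rep/10 + S_nam/10) * 2`, combining spontaneous
#' speech (0-20), comprehension (0-230), repetition (0-100) and naming
#' (0-100) into a global severity score in `[0, 100]` (100 = no deficit).
#'
#' @param ss,com,rep,nam subscores (vectorized; recycled to a common
#'   length).
#' @return AQ value(s) in `[0, 100]`.
#' @examples
#' computeAQ(20, 230, 100, 100)  # 100
#' computeAQ(17.32, 210.44, 95.38, 87.96)  # 89.61
#' @export
computeAQ <- function(ss, com, rep, nam) {
  vals <- cbind(ss = ss, com = com, rep = rep, nam = nam)
  for (nm in colnames(vals)) {
    v <- vals[, nm]
    if (any(!is.finite(v) | v < 0 | v > .AQ_MAX[[nm]]))
      stop(sprintf("subscore '%s' outside its range [0, %g]", nm,
                   .AQ_MAX[[nm]]))
  }
  as.numeric((vals[, "ss"] + vals[, "com"] / 23 + vals[, "rep"] / 10 +
                vals[, "nam"] / 10) * 2)
}

.checkTrajectory <- function(values) {
  if (is.null(names(values)) || !all(names(values) %in% .TIMEPOINTS))
    stop("trajectory must be a named vector with names among ",
         paste(.TIMEPOINTS, collapse = ", "))
  values <- values[!is.na(values)]
  if (!"pre" %in% names(values))
    stop("trajectory must contain a preoperative value")
  values[intersect(.TIMEPOINTS, names(values))]   # canonical time order
}

#' Classify language recovery as good or poor
#'
#' A patient shows good recovery when the AQ returns to at least 80% of the
#' preoperative baseline by 3 months after surgery, or to at least 85% by
#' 6 months; otherwise recovery is poor. A missing timepoint simply skips
#' its clause; at least one chronic timepoint (3 or 6 months) is required.
#'
#' @param values named numeric vector of AQ values with names among
#'   `pre, w2, m1, m3, m6` (`NA`s treated as missing).
#' @return `"good"` or `"poor"`.
#' @examples
#' classifyRecovery(c(pre = 68.54, w2 = 39.02, m3 = 56.60))  # "good"
#' classifyRecovery(c(pre = 66.89, m1 = 50.23, m3 = 52.39))  # "poor"
#' @export
classifyRecovery <- function(values) {
  values <- .checkTrajectory(values)
  if (!any(.CHRONIC %in% names(values)))
    stop("trajectory must contain a chronic timepoint (m3 or m6)")
  pre <- values[["pre"]]
  good <- FALSE
  if ("m3" %in% names(values) && values[["m3"]] >= 0.80 * pre) good <- TRUE
  if ("m6" %in% names(values) && values[["m6"]] >= 0.85 * pre) good <- TRUE
  if (good) "good" else "poor"
}

#' Recovery ratio of a longitudinal trajectory
#'
#' The ratio of total recovery to transient decline:
#' `(chronic - subacute) / (pre - subacute)`, with the subacute value taken
#' at the earliest available post-operative timepoint (2 weeks, else
#' 1 month) and the chronic value at the latest available chronic timepoint
#' (6 months, else 3 months). A ratio of 1 means a full return to baseline.
#'
#' The ratio is set to 1 and flagged `capped` when it is undefined or
#' meaningless as a recovery measure: when there was no transient decline
#' (denominator `<= 1e-9`), or when the score had already returned to the
#' good-recovery criterion (80% of baseline) by the subacute observation
#' and did not increase further (non-positive numerator) -- the decline and
#' recovery then both happened before the first post-operative measurement.
#'
#' The same computation applies verbatim to Z-scored network-property
#' trajectories (network recovery ratio).
#'
#' @param values named numeric vector over `pre, w2, m1, m3, m6` (`NA`
#'   treated as missing); `pre`, one subacute and one chronic value are
#'   required.
#' @return list of class `RecoveryRatio` with elements `value`,
#'   `subacuteTimepoint`, `chronicTimepoint`, `capped`.
#' @examples
#' recoveryRatio(c(pre = 96.53, w2 = 79.62, m1 = 97.76, m3 = 99.45))$value
#' @export
recoveryRatio <- function(values) {
  values <- .checkTrajectory(values)
  sub <- intersect(.SUBACUTE, names(values))
  chr <- intersect(.CHRONIC, names(values))
  if (!length(sub) || !length(chr))
    stop("trajectory must contain a subacute (w2/m1) and a chronic (m3/m6) value")
  subTp <- sub[1L]                  # earliest post-operative observation
  chrTp <- chr[length(chr)]         # latest available chronic observation
  pre <- values[["pre"]]
  subacute <- values[[subTp]]
  chronic <- values[[chrTp]]
  num <- chronic - subacute
  den <- pre - subacute
  capped <- den <= 1e-9 || (num <= 0 && subacute >= 0.80 * pre)
  value <- if (capped) 1.0 else num / den
  structure(list(value = value, subacuteTimepoint = subTp,
                 chronicTimepoint = chrTp, capped = capped),
            class = "RecoveryRatio")
}

#' @export
print.RecoveryRatio <- function(x, ...) {
  cat(sprintf("Recovery ratio: %.3f (%s -> %s)%s\n", x$value,
              x$subacuteTimepoint, x$chronicTimepoint,
              if (x$capped) " [capped at 1]" else ""))
  invisible(x)
}

#' Paired and two-sample t-tests, chi-square test
#'
#' Thin, argument-checked wrappers around the classical tests used for
#' group-level inference: a paired t-test against baseline, a
#' pooled-variance (Student) two-sample t-test, and a Pearson chi-square
#' test on a 2 x k contingency table without continuity correction. All
#' p-values are two-sided.
#'
#' @param x,y paired measurement vectors of equal length (>= 2).
#' @return list with `t` (or `chisq`), `df` and `p`.
#' @examples
#' twoSampleT(rnorm(10), rnorm(12))
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 2L) stop("at least 2 pairs are required")
  if (stats::sd(x - y) == 0)
    stop("paired differences have zero variance; t is undefined")
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' @rdname pairedT
#' @param a,b independent sample vectors (each n >= 2).
#' @export
twoSampleT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both samples have zero variance; t is undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' @rdname pairedT
#' @param table 2 x k matrix of non-negative counts.
#' @export
chiSquare2xk <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L) stop("expected a 2 x k contingency table")
  if (any(table < 0)) stop("counts must be non-negative")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares regression on the covariates (plus intercept). The p-value
#' is from a t distribution with `n - k - 2` degrees of freedom, `k` being
#' the number of covariates. With no covariates this reduces to the plain
#' Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix / data.frame with one row per
#'   observation, or `NULL`.
#' @return list with `r`, `df` and `p`.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per observation")
    k <- ncol(covariates)
  }
  if (n <= k + 2L) stop("need n > k + 2 observations")
  X <- cbind(intercept = rep(1, n), covariates)
  collinear <- qr(X)$rank < ncol(X)
  if (collinear)
    warning("collinear covariates; using least-norm fit")
  rx <- if (collinear) suppressWarnings(.lsResiduals(cbind(x), X))
        else .lsResiduals(cbind(x), X)
  ry <- if (collinear) suppressWarnings(.lsResiduals(cbind(y), X))
        else .lsResiduals(cbind(y), X)
  r <- stats::cor(rx, ry)[1L]
  df <- n - k - 2L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tval), df))
}

.AQ_COLS <- paste0("aq_", .TIMEPOINTS)

.subjectTrajectory <- function(row) {
  present <- intersect(.AQ_COLS, names(row))
  v <- as.numeric(unlist(row[present]))
  names(v) <- sub("^aq_", "", present)
  v
}

#' Cohort-level summary of language recovery
#'
#' From a table of per-subject AQ trajectories and clinical covariates
#' (columns `subject, sex, age, education, grade, location, resection,
#' aq_pre, aq_w2, aq_m1, aq_m3, aq_m6`, optionally `group`), computes:
#' per-timepoint AQ means and SDs; counts by tumour grade, location and
#' recovery group; the number of subjects below a preoperative AQ cutoff;
#' per-subject recovery ratios and classifications; and per-group
#' recovery-ratio ranges. When a listed `group` column is present,
#' disagreements between the listed group and the rule-based classification
#' are reported in `ruleMismatches` (grouping summaries then use the listed
#' group).
#'
#' @param scores `data.frame` as above (see [readScoresTSV()]).
#' @param aqCutoff preoperative AQ cutoff for the deficit count
#'   (default 93.8).
#' @return list with elements `timepointSummary`, `gradeCounts`,
#'   `locationCounts`, `groupCounts`, `nBelowCutoff`, `perSubject`,
#'   `ratioRange` (per-group min/max of the recovery ratio) and
#'   `ruleMismatches`.
#' @export
summarizeCohort <- function(scores, aqCutoff = 93.8) {
  stopifnot(is.data.frame(scores), all(c("subject", .AQ_COLS[1]) %in%
                                         colnames(scores)))
  present <- intersect(.AQ_COLS, colnames(scores))
  tpSummary <- data.frame(
    timepoint = sub("^aq_", "", present),
    n = vapply(present, function(cl) sum(!is.na(scores[[cl]])), 1L),
    mean = vapply(present, function(cl) mean(scores[[cl]], na.rm = TRUE), 1.0),
    sd = vapply(present, function(cl) stats::sd(scores[[cl]], na.rm = TRUE), 1.0),
    row.names = NULL)

  per <- do.call(rbind, lapply(seq_len(nrow(scores)), function(i) {
    traj <- .subjectTrajectory(scores[i, ])
    rr <- recoveryRatio(traj)
    data.frame(subject = scores$subject[i],
               ruleClass = classifyRecovery(traj),
               ratio = rr$value, capped = rr$capped,
               subacuteTimepoint = rr$subacuteTimepoint,
               chronicTimepoint = rr$chronicTimepoint,
               row.names = NULL)
  }))
  if ("group" %in% colnames(scores)) {
    per$group <- scores$group
    mismatch <- per$subject[per$group != per$ruleClass]
  } else {
    per$group <- per$ruleClass
    mismatch <- character(0)
  }

  ratioRange <- do.call(rbind, lapply(split(per, per$group), function(g)
    data.frame(group = g$group[1L], n = nrow(g), min = min(g$ratio),
               max = max(g$ratio), row.names = NULL)))

  countTable <- function(col) if (col %in% colnames(scores))
    table(scores[[col]]) else NULL
  list(timepointSummary = tpSummary,
       gradeCounts = countTable("grade"),
       locationCounts = countTable("location"),
       groupCounts = table(per$group),
       nBelowCutoff = sum(scores$aq_pre < aqCutoff, na.rm = TRUE),
       perSubject = per,
       ratioRange = ratioRange,
       ruleMismatches = mismatch)
}
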