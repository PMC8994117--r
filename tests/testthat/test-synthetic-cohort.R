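test_that("target covariance has the requested block structure", {
  nets <- toyNetworks(6, 6)  # 3 L + 3 R per network
  m <- buildTargetCovariance(nets[1], withinCorr = 0.45, betweenCorr = 0.08)
  # single network of 6: all off-diagonals 0.45
  expect_equal(unname(m[upper.tri(m)]), rep(0.45, 15))

  m2 <- buildTargetCovariance(nets, withinCorr = 0.45, betweenCorr = 0.08)
  idsA <- nodeIds(nets[[1]])
  idsB <- nodeIds(nets[[2]])
  expect_equal(dim(m2), c(12, 12))
  expect_true(all(m2[idsA, idsB] == 0.08))
  offA <- m2[idsA, idsA][upper.tri(diag(6))]
  expect_true(all(offA == 0.45))
  expect_equal(unname(diag(m2)), rep(1, 12))
  expect_true(isSymmetric(m2))
})

test_that("zero correlations give the identity and big blocks stay PSD", {
  nets <- toyNetworks(4, 4)
  m <- buildTargetCovariance(nets, withinCorr = 0, betweenCorr = 0)
  expect_equal(unname(m), diag(8), ignore_attr = TRUE)

  # a 68-node single block at within 0.45 must be PSD (eigendecomposition)
  big <- NetworkDefinition("big", data.frame(
    id = sprintf("n%02d", 1:68),
    hemisphere = rep(c("L", "R"), each = 34), region = "big"))
  mb <- buildTargetCovariance(list(big), withinCorr = 0.45)
  expect_gte(min(eigen(mb, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(attr(mb, "repair"), 0)
})

test_that("disjointness is enforced", {
  net <- toyNetworks(4, 4)[[1]]
  expect_error(buildTargetCovariance(list(net, net)), "disjoint")
})

test_that("simulated series is deterministic and matches its target covariance", {
  nets <- toyNetworks(6, 6)
  cov <- buildTargetCovariance(nets, 0.45, 0.08)
  a <- simulateTimeseries(cov, 100, ar1 = 0.3, seed = 42)
  b <- simulateTimeseries(cov, 100, ar1 = 0.3, seed = 42)
  expect_identical(signalMatrix(a), signalMatrix(b))

  # Monte-Carlo recovery of the cross-sectional correlation structure
  long <- simulateTimeseries(cov, 1e5, ar1 = 0.3, seed = 7)
  r <- cor(signalMatrix(long))
  idsA <- nodeIds(nets[[1]])
  withinA <- r[idsA, idsA][upper.tri(diag(6))]
  expect_true(all(abs(withinA - 0.45) < 0.01))
  expect_true(all(abs(r[idsA, nodeIds(nets[[2]])] - 0.08) < 0.01))

  # independent nodes stay independent
  ident <- diag(4)
  dimnames(ident) <- list(letters[1:4], letters[1:4])
  il <- simulateTimeseries(ident, 1e5, ar1 = 0, seed = 3)
  ri <- cor(signalMatrix(il))
  expect_lt(max(abs(ri[upper.tri(ri)])), 0.02)
})

test_that("simulation rejects invalid inputs", {
  expect_error(simulateTimeseries(diag(2), 1, 0.3, 1), "at least 2")
  expect_error(simulateTimeseries(diag(2), 10, 1.0, 1), "ar1")
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # not PSD
  expect_error(simulateTimeseries(bad, 10, 0.3, 1), "semi-definite")
})

test_that("disruption attenuates only the peritumoral neighbourhood and homologues", {
  nets <- toyNetworks(6, 6)
  cov <- buildTargetCovariance(nets, 0.45, 0.08)

  expect_identical(unname(applyDisruption(cov, nets, "netA_L1", 0)[, ]),
                   unname(cov[, ]))

  d1 <- applyDisruption(cov, nets, "netA_L1", 1)
  expect_true(all(d1["netA_L1", setdiff(colnames(cov), "netA_L1")] == 0))
  # contralateral homologue (same within-hemisphere index, other side) too
  expect_setequal(attr(d1, "affectedNodes"), c("netA_L1", "netA_R1"))
  expect_true(all(d1["netA_R1", setdiff(colnames(cov), "netA_R1")] == 0))

  d5 <- applyDisruption(cov, nets, c("netA_L1", "netA_L2"), 0.5)
  untouched <- c("netA_L3", "netB_L1", "netB_R2")
  expect_identical(d5[untouched, untouched], cov[untouched, untouched])
  expect_equal(d5["netA_L1", "netA_L3"], 0.45 * 0.5)
  # edge between two affected nodes attenuated once, not twice
  expect_equal(d5["netA_L1", "netA_L2"], 0.45 * 0.5)

  expect_error(applyDisruption(cov, nets, "netA_L1", 1.2), "\\[0, 1\\]")
  expect_error(applyDisruption(cov, nets, c("netA_L1", "netA_R1"), 0.5),
               "one hemisphere")
})

test_that("patient language scores follow the attenuation link", {
  nets <- toyNetworks(6, 6)
  cfg <- cohortConfig(nVolumes = 60, disruptionFrac = 1,
                      recoveryProfile = c(pre = 0, w2 = 1, m3 = 0),
                      languageLinkSlope = 0.4, languageLinkNoiseSd = 0,
                      seed = 9)
  p <- generatePatient(cfg, nets, timepoints = c("pre", "w2", "m3"),
                       seed = 11, includeTimeseries = FALSE)
  aq <- setNames(p$language$aq, p$language$timepoint)
  expect_equal(aq[["m3"]], aq[["pre"]])          # full recovery
  expect_equal(aq[["w2"]], aq[["pre"]] - 40)     # slope 0.4 x 100 x 1.0
  # subscores back-solve consistently through the composite formula
  expect_equal(computeAQ(p$language$ss, p$language$com, p$language$rep,
                         p$language$nam),
               p$language$aq, tolerance = 1e-12)
})

test_that("cohorts are bit-reproducible given config and seed", {
  nets <- toyNetworks(4, 4)
  cfg <- cohortConfig(nControls = 2, nPatients = 2, nVolumes = 40,
                      recoveryProfile = c(pre = 0, w2 = 1, m3 = 0), seed = 21)
  c1 <- generateCohort(cfg, nets)
  c2 <- generateCohort(cfg, nets)
  expect_identical(c1$language, c2$language)
  expect_identical(signalMatrix(c1$controls[[1]]),
                   signalMatrix(c2$controls[[1]]))
  expect_identical(signalMatrix(c1$patients[[2]]$timeseries$w2),
                   signalMatrix(c2$patients[[2]]$timeseries$w2))
  expect_identical(motionTrace(c1$patients[[1]]$timeseries$pre),
                   motionTrace(c2$patients[[1]]$timeseries$pre))
})

test_that("full-recovery patients are almost always classified good", {
  nets <- toyNetworks(4, 4)
  cfg <- cohortConfig(disruptionFrac = 1, languageLinkSlope = 0.4,
                      languageLinkNoiseSd = 2,
                      recoveryProfile = c(pre = 0, w2 = 1, m3 = 0), seed = 1)
  labels <- vapply(1:200, function(s) {
    p <- generatePatient(cfg, nets, timepoints = c("pre", "w2", "m3"),
                         seed = s, includeTimeseries = FALSE)
    classifyRecovery(setNames(p$language$aq, p$language$timepoint))
  }, "")
  expect_gte(mean(labels == "good"), 0.95)
})

test_that("config validation catches impossible recovery profiles", {
  expect_error(cohortConfig(recoveryProfile = c(pre = 0, w2 = 0.5, m3 = 0)),
               "subacute")
  expect_error(cohortConfig(recoveryProfile = c(pre = 0, w2 = 1, m3 = 1.5)),
               "\\[0, 1\\]")
})
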