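mkTsFromCols <- function(...) {
  SubjectTimeSeries(cbind(...), trSeconds = 2)
}

test_that("packaged node sets have the documented structure", {
  lang <- builtinNetwork("language")
  expect_equal(length(lang), 68)
  h <- table(nodeTable(lang)$hemisphere)
  expect_equal(as.integer(h[c("L", "R")]), c(34L, 34L))
  expect_setequal(unique(nodeTable(lang)$region),
                  c("IFG", "MFG", "SFG", "STG", "MTG", "ITG", "PrG", "PoG",
                    "IPL"))

  cofp <- builtinNetwork("co_fp")
  expect_equal(length(cofp), 18)
  expect_equal(sum(grepl("^CO_", nodeTable(cofp)$region)), 7)
  expect_equal(sum(grepl("^FP_", nodeTable(cofp)$region)), 11)

  dmn <- builtinNetwork("dmn")
  expect_true(all(c("PCC", "vmPFC", "TPJ") %in% nodeTable(dmn)$region))
  expect_s4_class(builtinNetwork("men"), "NetworkDefinition")
  expect_error(builtinNetwork("nope"))
})

test_that("correlation networks are exact on worked series", {
  # exactly linear pair: r = 1
  ts <- mkTsFromCols(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(1, 3, 2, 4))
  cm <- correlationMatrix(ts)
  expect_equal(corMatrix(cm)["a", "b"], 1)

  # duplicated node signal: r = 1 for that pair
  ts2 <- mkTsFromCols(a = rnorm(30), b = 1:30)
  ts2@signals <- cbind(ts2@signals, a2 = ts2@signals[, "a"])
  expect_equal(corMatrix(correlationMatrix(ts2))["a", "a2"], 1)

  # zero-variance node: warning, edges zeroed
  ts3 <- mkTsFromCols(a = rnorm(20), b = rep(1, 20))
  expect_warning(cm3 <- correlationMatrix(ts3), "zero-variance")
  expect_equal(corMatrix(cm3)["a", "b"], 0)

  expect_error(correlationMatrix(mkTsFromCols(a = 1:2, b = 2:1)), "3")

  # independent long simulations decorrelate
  set.seed(4)
  tsl <- mkTsFromCols(a = rnorm(1e5), b = rnorm(1e5), c = rnorm(1e5))
  rl <- corMatrix(correlationMatrix(tsl))
  expect_lt(max(abs(rl[upper.tri(rl)])), 0.02)
})

test_that("Fisher z transform matches atanh and preserves edge ordering", {
  ts <- mkTsFromCols(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  cm <- correlationMatrix(ts)
  z <- fisherZ(cm)
  expect_equal(weightKind(z), "fisher_z")
  expect_equal(edgeWeights(z)["a", "b"], atanh(corMatrix(cm)["a", "b"]))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)

  # odd function: z(-r) = -z(r)
  neg <- cm; neg@r <- -cm@r; neg@weights <- -cm@weights
  expect_equal(edgeWeights(fisherZ(neg)), -edgeWeights(z))

  # strict monotonicity: ordering of weights preserved
  rv <- corMatrix(cm)[upper.tri(diag(3))]
  zv <- edgeWeights(z)[upper.tri(diag(3))]
  expect_equal(order(rv), order(zv))

  expect_error(fisherZ(fisherZ(cm)), "pearson_r")
})

test_that("thresholding is strict on r and never keeps negative correlations", {
  r <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  r["a", "b"] <- r["b", "a"] <- 0.19
  r["a", "c"] <- r["c", "a"] <- 0.21
  r["b", "d"] <- r["d", "b"] <- -0.6
  r["c", "d"] <- r["d", "c"] <- 0.45
  cm <- fcRecovery:::.connectivityMatrix(letters[1:4], r, r, "pearson_r",
                                         NA_real_)
  th <- thresholdNetwork(cm, 0.2)
  w <- edgeWeights(th)
  expect_equal(sum(w[upper.tri(w)] != 0), 2)   # 0.21 and 0.45 survive
  expect_equal(w["a", "c"], atanh(0.21))       # surviving weights are Fisher z
  expect_equal(w["b", "d"], 0)                 # negative r removed
  expect_equal(w["a", "b"], 0)                 # boundary: 0.19 <= 0.2 removed

  # brute-force filter oracle on random matrices + nestedness across 0.1/0.2/0.3
  set.seed(11)
  for (i in 1:20) {
    rr <- matrix(0, 5, 5)
    rr[upper.tri(rr)] <- runif(10, -1, 1)
    rr <- rr + t(rr)
    ids <- paste0("n", 1:5)
    dimnames(rr) <- list(ids, ids)
    cmr <- fcRecovery:::.connectivityMatrix(ids, rr, rr, "pearson_r", NA_real_)
    surv <- function(thr) which(edgeWeights(thresholdNetwork(cmr, thr)) != 0)
    expect_identical(surv(0.2), which(rr > 0.2))
    expect_true(all(surv(0.3) %in% surv(0.2)))
    expect_true(all(surv(0.2) %in% surv(0.1)))
  }

  # raw-r weight variant keeps correlations as weights
  thr <- thresholdNetwork(cm, 0.2, weightKind = "pearson_r")
  expect_equal(edgeWeights(thr)["c", "d"], 0.45)

  expect_error(thresholdNetwork(cm, 1.5), "strictly inside")

  # all-subthreshold matrix gives an empty network
  empty <- thresholdNetwork(cm, 0.6)
  expect_equal(sum(edgeWeights(empty)), 0)
  expect_equal(fcStrength(empty), 0)
})

test_that("edges classify by hemisphere and connectivity bin", {
  net <- NetworkDefinition("toy", data.frame(
    id = c("l1", "l2", "r1", "m1", "m2"),
    hemisphere = c("L", "L", "R", "midline", "midline"),
    region = "toy"))
  ids <- nodeIds(net)
  r <- matrix(0, 5, 5, dimnames = list(ids, ids))
  set <- function(a, b, v) r[a, b] <<- r[b, a] <<- v
  set("l1", "l2", 0.25)   # ipsi_left, fair
  set("l1", "r1", 0.45)   # interhemispheric, moderate
  set("r1", "m1", 0.65)   # midline counts with the other endpoint: ipsi_right
  set("m1", "m2", 0.3)    # midline-midline reported separately
  set("l2", "m2", 0.9)    # ipsi_left, strong
  cm <- fcRecovery:::.connectivityMatrix(ids, r, r, "pearson_r", NA_real_)
  ed <- classifyEdges(thresholdNetwork(cm, 0.2), net)
  key <- function(a, b) ed[ed$node_a == a & ed$node_b == b, ]
  expect_equal(key("l1", "l2")$class, "ipsi_left")
  expect_equal(key("l1", "l2")$bin, "fair")
  expect_equal(key("l1", "r1")$class, "interhemispheric")
  expect_equal(key("l1", "r1")$bin, "moderate")
  expect_equal(key("r1", "m1")$class, "ipsi_right")
  expect_equal(key("m1", "m2")$class, "midline")
  expect_equal(key("l2", "m2")$bin, "strong")
  expect_equal(key("l2", "m2")$z, atanh(0.9))

  other <- NetworkDefinition("small", data.frame(
    id = "l1", hemisphere = "L", region = "x"))
  expect_error(classifyEdges(cm, other), "hemisphere label")
})

test_that("connectivity matrices round-trip through TSV bit-exactly", {
  set.seed(8)
  ts <- mkTsFromCols(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  cm <- thresholdNetwork(correlationMatrix(ts), 0.0 + 1e-9)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMatrixTSV(edgeWeights(cm), f)
  expect_identical(readMatrixTSV(f), edgeWeights(cm))
  writeMatrixTSV(corMatrix(cm), f)
  expect_identical(readMatrixTSV(f), corMatrix(cm))
})
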