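mkMotion <- function(n) matrix(0, n, 6,
  dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))

test_that("framewise displacement follows the translation + sphere-arc formula", {
  m <- mkMotion(20)
  expect_equal(computeFD(m), rep(0, 20))

  m[10:20, 1] <- 0.3      # sustained +0.3 mm step in x at volume 10
  fd <- computeFD(m)
  expect_equal(fd[10], 0.3)
  expect_equal(fd[-10], rep(0, 19))

  m2 <- mkMotion(20)
  m2[5:20, 4] <- 0.01     # 0.01 rad rotation step, 50 mm sphere
  expect_equal(computeFD(m2, radius = 50)[5], 0.5)

  # invariant to a constant offset on all parameters
  expect_equal(computeFD(m + 1.7), computeFD(m))

  m3 <- mkMotion(5); m3[2, 3] <- NA
  expect_error(computeFD(m3), "non-finite")
})

test_that("scrubbing censors one volume before and two after each spike", {
  cfg <- preprocessConfig()
  expect_equal(flagAndCensor(rep(0, 240), cfg), 1:240)

  fd <- rep(0, 240); fd[100] <- 0.7
  kept <- flagAndCensor(fd, cfg)
  expect_equal(setdiff(1:240, kept), 99:102)
  expect_length(kept, 236)

  # overlapping windows, clipping at the series ends
  fd2 <- rep(0, 50); fd2[c(1, 2, 50)] <- 1
  kept2 <- flagAndCensor(fd2, preprocessConfig(minVolumes = 10))
  expect_equal(setdiff(1:50, kept2), c(1, 2, 3, 4, 49, 50))

  # fewer than the minimum surviving volumes must raise the exclusion error
  fdDense <- rep(c(0.6, 0, 0, 0, 0), 48)
  expect_error(flagAndCensor(fdDense, cfg), class = "minimumVolumesError")
})

test_that("scrubbing is idempotent", {
  set.seed(5)
  for (i in 1:20) {
    fd <- runif(200, 0, 0.8)
    cfg <- preprocessConfig(minVolumes = 0)
    kept <- flagAndCensor(fd, cfg)
    fdKept <- fd[kept]
    fdKept[1] <- 0  # first surviving volume has no predecessor
    expect_equal(flagAndCensor(fdKept, cfg), seq_along(kept))
  }
})

test_that("the nuisance design has the documented column structure", {
  n <- 50
  set.seed(1)
  motion <- matrix(rnorm(n * 6), n, 6)
  wm <- rnorm(n); csf <- rnorm(n); g <- rnorm(n)
  X <- buildNuisanceDesign(motion, wm, csf, g, useGlobal = TRUE)
  expect_equal(ncol(X), 36)
  # without the global signal the whole column family goes: 8 + 8 + 16
  X32 <- buildNuisanceDesign(motion, wm, csf, useGlobal = FALSE)
  expect_equal(ncol(X32), 32)
  expect_false(any(grepl("global", colnames(X32))))

  # derivative of a linear ramp is constant (0 at the first volume)
  ramp <- matrix(seq_len(n), n, 6) * 0.1
  Xr <- buildNuisanceDesign(ramp, wm, csf, g)
  expect_equal(unname(Xr[-1, "d_tx"]), rep(0.1, n - 1))
  expect_equal(unname(Xr[1, "d_tx"]), 0)
  # quadratic block is the elementwise square of base + derivative
  expect_equal(unname(X[, 19:36]), unname(X[, 1:18]^2))

  # zero motion and constant tissue signals: rank <= 2 after demeaning
  Xc <- buildNuisanceDesign(mkMotion(n), rep(1, n), rep(2, n), rep(3, n))
  Xd <- sweep(Xc, 2, colMeans(Xc))
  expect_lte(qr(Xd)$rank, 2)

  expect_error(buildNuisanceDesign(motion, wm[-1], csf, g), "per volume")
})

test_that("nuisance regression orthogonalizes against every regressor", {
  n <- 80
  set.seed(2)
  design <- cbind(matrix(rnorm(n * 6), n, 6), wm = rnorm(n), csf = rnorm(n))
  design <- buildNuisanceDesign(design[, 1:6], design[, 7], design[, 8],
                                rnorm(n))
  y <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("n", 1:4)))
  ts <- SubjectTimeSeries(y, trSeconds = 2)
  res <- signalMatrix(regressNuisance(ts, design))
  Xd <- sweep(design, 2, colMeans(design))
  expect_lt(max(abs(crossprod(Xd, res))) / n, 1e-8)

  # a signal equal to a regressor is removed entirely
  ts1 <- SubjectTimeSeries(cbind(a = design[, 3]), trSeconds = 2)
  expect_lt(max(abs(signalMatrix(regressNuisance(ts1, design)))), 1e-10)

  # empty design = intercept only: output is the demeaned input
  ts2 <- SubjectTimeSeries(y, trSeconds = 2)
  res2 <- signalMatrix(regressNuisance(ts2, matrix(numeric(0), n, 0)))
  expect_equal(res2, sweep(y, 2, colMeans(y)), tolerance = 1e-12)

  # residuals match the explicit pseudo-inverse normal-equations solution
  X <- cbind(1, design)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(signalMatrix(regressNuisance(ts, design)), y - X %*% beta,
               tolerance = 1e-10, ignore_attr = TRUE)

  # rank-deficient designs fall back to the least-norm solution
  dup <- cbind(design, design[, 2] - design[, 5])
  expect_warning(res3 <- regressNuisance(ts, dup), "rank deficient")
  Xd3 <- sweep(dup, 2, colMeans(dup))
  expect_lt(max(abs(crossprod(Xd3, signalMatrix(res3)))) / n, 1e-8)
})

test_that("band-pass keeps the passband and rejects DC and fast oscillations", {
  n <- 240; tr <- 2
  t <- (seq_len(n) - 1) * tr
  cfg <- preprocessConfig()

  mkTs <- function(x) SubjectTimeSeries(cbind(sig = x), trSeconds = tr)

  # constant input is annihilated (DC removal)
  const <- signalMatrix(bandpass(mkTs(rep(5, n)), cfg))
  expect_lt(max(abs(const)), 1e-6)

  tone <- function(f) sin(2 * pi * f * t)
  in05 <- tone(0.05)
  out05 <- signalMatrix(bandpass(mkTs(in05), cfg))[, 1]
  ratio05 <- toneAmplitude(out05, 0.05, tr) / toneAmplitude(in05, 0.05, tr)
  expect_gte(ratio05, 0.95)

  in20 <- tone(0.2)
  out20 <- signalMatrix(bandpass(mkTs(in20), cfg))[, 1]
  ratio20 <- toneAmplitude(out20, 0.2, tr) / toneAmplitude(in20, 0.2, tr)
  expect_lte(ratio20, 0.10)

  # edges must be below Nyquist for the sampling rate
  slow <- SubjectTimeSeries(cbind(sig = rnorm(n)), trSeconds = 10)
  expect_error(bandpass(slow, cfg), "Nyquist")
})

test_that("the full cleaning pipeline discards, regresses, filters and scrubs", {
  nets <- toyNetworks(6, 6)
  cfg <- cohortConfig(nVolumes = 240, nMotionSpikes = 1, seed = 3)
  ctrl <- generateControl(cfg, nets, seed = 8)
  pp <- preprocessSubject(ctrl, preprocessConfig())
  # 10 discarded, then one sustained spike costs 4 volumes
  expect_equal(length(pp$fd), 230)
  expect_lte(nVolumes(pp$ts), 230 - 4 * sum(pp$fd > 0.5))
  expect_equal(nVolumes(pp$ts), length(pp$keptVolumes))
  expect_match(paste(unlist(pp$ts@processingLog), collapse = ";"),
               "nuisance.*band-pass.*scrubbing")

  # heavily corrupted scans are rejected with the exclusion error
  cfgBad <- cohortConfig(nVolumes = 240, nMotionSpikes = 60, seed = 4)
  bad <- generateControl(cfgBad, nets, seed = 2)
  expect_error(preprocessSubject(bad, preprocessConfig()),
               class = "minimumVolumesError")
})
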