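test_that("computeTraceFret is the per-frame acceptor share", {
  tr <- constantTrace(0.5, nFrames = 100)
  expect_equal(computeTraceFret(tr), rep(0.5, 100))
  tr <- constantTrace(0.8, nFrames = 100)   # acceptor = 4 x donor
  expect_equal(computeTraceFret(tr), rep(0.8, 100))
  # below-floor frames are unassigned, not given spurious ratios
  tr2 <- stepTrace(c(0.5, 0.5), c(50, 50))
  tr2@donor[51:100] <- 1
  tr2@acceptor[51:100] <- 1
  e <- computeTraceFret(tr2)
  expect_true(all(is.na(e[51:100])))
  zero <- new("FretTrace", time = c(0, 0.1), donor = c(0, 0),
              acceptor = c(0, 0), frameInterval = 0.1)
  expect_error(computeTraceFret(zero), "all-zero")

  # simulated bound state at E = 0.62: time average within noise
  st <- traceStates("MID", 0.62, 1e-4)
  cfg <- traceSimConfig(st, matrix(0, 1, 1), duration = 300, noiseSd = 50)
  tr3 <- simulateTrace(cfg, seed = 91)
  expect_equal(mean(computeTraceFret(tr3)), 0.62, tolerance = 0.005)
})

test_that("filterTraces keeps traces alive past the minimum span", {
  mkBleached <- function(tBleach) {
    tr <- constantTrace(0.6, nFrames = 3000)
    dead <- traceTime(tr) >= tBleach
    tr@donor[dead] <- 0; tr@acceptor[dead] <- 0
    tr
  }
  early <- mkBleached(60)    # bleaches at 60 s: excluded at 3.5 min
  alive <- constantTrace(0.6, nFrames = 3000)  # alive 300 s: retained
  kept <- filterTraces(list(early, alive), minDuration = 210)
  expect_length(kept, 1)
  expect_identical(kept[[1]], alive)

  # ensemble with exponential bleaching: survival ~ exp(-k_b * 210 s)
  kb <- 1 / 300
  st <- traceStates("MID", 0.6, 1e-4)
  cfg <- traceSimConfig(st, matrix(0, 1, 1), duration = 300, noiseSd = 20,
                        acceptorBleachRate = kb, donorBleachRate = 0)
  set.seed(92)
  traces <- lapply(1:300, function(i) simulateTrace(cfg))
  # acceptor bleaching alone keeps total intensity up; count via truth
  surv <- vapply(traces, function(tr)
    traceMetadata(tr)$acceptorBleachTime >= 210, logical(1))
  pExp <- exp(-kb * 210)
  expect_lt(abs(mean(surv) - pExp), 4 * sqrt(pExp * (1 - pExp) / 300))
})

test_that("segmentStates reproduces noiseless and noisy state paths", {
  # noiseless step MID -> HIGH at frame 100
  tr <- stepTrace(c(0.6, 0.8), c(100, 100))
  seg <- segmentDefault(tr)
  dw <- dwells(seg)
  expect_equal(dw$state, c("MID", "HIGH"))
  expect_equal(dw$tStart, c(0, 10))
  expect_equal(dw$duration, c(10, 10))

  # noisy constant MID within the half-width: one dwell spanning the trace
  set.seed(93)
  trN <- constantTrace(0.6, nFrames = 1000, noiseSd = 50)  # E sd ~ 0.05
  segN <- segmentStates(computeTraceFret(trN),
                        c(LOW = 0.2, MID = 0.6, HIGH = 0.8),
                        halfWidth = 0.1, minDwellFrames = 3)
  expect_equal(nrow(dwells(segN)), 1)
  expect_equal(dwells(segN)$state, "MID")
  expect_equal(dwells(segN)$duration, 100)

  # simulated MID -> LOW -> HIGH path recovered within min-dwell slack
  trP <- stepTrace(c(0.6, 0.2, 0.8), c(300, 120, 300))
  set.seed(94)
  trP@donor <- trP@donor + rnorm(720, 0, 40)
  trP@acceptor <- trP@acceptor + rnorm(720, 0, 40)
  segP <- segmentDefault(trP)
  expect_equal(rle(dwells(segP)$state)$values, c("MID", "LOW", "HIGH"))

  # invariant under uniform intensity rescaling of both channels
  trS <- trP
  trS@donor <- trP@donor * 7
  trS@acceptor <- trP@acceptor * 7
  expect_identical(stateLabels(segmentDefault(trS)), stateLabels(segP))
  expect_error(segmentStates(rep(0.5, 10), c(LOW = 0.2, MID = 0.25)),
               "overlapping")
})

test_that("findBindingTime measures the post-injection waiting time", {
  # transition exactly at injection
  tr <- stepTrace(c(0.6, 0.8), c(600, 400), injectionTime = 60)
  seg <- segmentDefault(tr)
  expect_equal(findBindingTime(seg, 60, "HIGH"), 0)
  # no transition: no-binding flag
  tr0 <- stepTrace(0.6, 1000, injectionTime = 60)
  t0 <- findBindingTime(segmentDefault(tr0), 60, "HIGH")
  expect_true(is.na(t0))
  expect_true(isTRUE(attr(t0, "no_binding")))
  # bleached before injection: both dyes dark from 5 s on
  trB <- stepTrace(0.6, 1000)
  trB@donor[51:1000] <- 0; trB@acceptor[51:1000] <- 0
  expect_error(findBindingTime(segmentDefault(trB), 60, "HIGH"), "bleached")

  # ensemble: mean waiting time ~ 1/k (truncation-corrected)
  k <- 0.05
  ens <- simulateDisplacementEnsemble(150, pNoBinding = 0, pIntermediate = 0,
                                      kBind = k, duration = 400,
                                      injectionTime = 40, noiseSd = 30,
                                      seed = 95)
  ts <- vapply(ens, function(tr) {
    seg <- segmentDefault(tr)
    findBindingTime(seg, injectionTime(tr), "HIGH")
  }, numeric(1))
  ts <- ts[!is.na(ts)]
  tMax <- 360
  truncMean <- (1 / k) - tMax * exp(-k * tMax) / (1 - exp(-k * tMax))
  expect_equal(mean(ts), truncMean, tolerance = 0.15)
})

test_that("fitDwellRate is the reciprocal mean lifetime", {
  f <- fitDwellRate(c(1, 2, 3))
  expect_equal(fitRate(f), 0.5)
  expect_true("low_confidence" %in% fitFlags(f))
  f1 <- fitDwellRate(4)
  expect_equal(fitRate(f1), 0.25)
  expect_true("low_confidence" %in% fitFlags(f1))
  expect_error(fitDwellRate(numeric(0)), "empty")

  set.seed(96)
  d <- rexp(1000, 0.1)
  expect_equal(fitRate(fitDwellRate(d)), 0.1, tolerance = 0.1)
  # censored dwells are excluded by default, used by the censored MLE
  dd <- data.frame(duration = c(d, rep(30, 100)),
                   censored = c(rep(FALSE, 1000), rep(TRUE, 100)))
  expect_equal(fitRate(fitDwellRate(dd)), fitRate(fitDwellRate(d)))
  fc <- fitDwellRate(dd, method = "censored_mle")
  expect_equal(fitRate(fc), 1000 / sum(dd$duration))
})

test_that("fitAssociationConstant recovers the second-order slope", {
  conc <- c(0.2e-6, 0.5e-6, 1e-6)
  exact <- data.frame(concentration = conc, kObs = 8.4e4 * conc)
  f <- suppressWarnings(fitAssociationConstant(exact))  # zero-residual fit
  expect_equal(fitRate(f), 8.4e4, tolerance = 1e-9)
  zero <- data.frame(concentration = conc, kObs = 0)
  expect_equal(fitRate(fitAssociationConstant(zero)), 0)
  expect_error(fitAssociationConstant(
    data.frame(concentration = c(1e-6, 1e-6), kObs = c(1, 2))), "distinct")

  # end to end from simulated waiting times (n = 50/concentration)
  bt <- simulateBindingTimes(8.4e4, conc, nPerConc = 50, seed = 97)
  fS <- fitAssociationConstant(bindingRatesByConcentration(bt))
  expect_equal(fitRate(fS), 8.4e4, tolerance = 0.2)
})

test_that("classifyTrace applies the displacement-pathway rules", {
  classify <- function(eLevels, lengths) {
    tr <- stepTrace(eLevels, lengths, injectionTime = 30)
    classifyTrace(segmentDefault(tr), 30)
  }
  direct <- classify(c(0.6, 0.8), c(400, 400))
  expect_equal(direct$category, "DISPLACEMENT_DIRECT")
  expect_equal(direct$nLowVisits, 0)

  via <- classify(c(0.6, 0.2, 0.8), c(400, 100, 400))
  expect_equal(via$category, "DISPLACEMENT_VIA_INTERMEDIATE")
  expect_equal(via$nLowVisits, 1)

  none <- classify(0.6, 900)
  expect_equal(none$category, "NO_BINDING")

  ret <- classify(c(0.6, 0.2, 0.6), c(400, 100, 400))
  expect_equal(ret$category, "INTERMEDIATE_RETURN")
  expect_equal(ret$nIntermediateReturns, 1)

  multi <- classify(c(0.6, 0.8, 0.2, 0.8), c(300, 200, 100, 300))
  expect_equal(multi$category, "MULTI_TRANSITION")
  expect_equal(multi$nHighTransitions, 2)

  empty <- new("StateSegmentation", labels = rep("UNASSIGNED", 10))
  expect_error(classifyTrace(empty, 0), "unsegmented")
})

test_that("classificationSummary counts terminal categories", {
  cats <- c(rep("NO_BINDING", 46), rep("DISPLACEMENT_DIRECT", 32),
            rep("DISPLACEMENT_VIA_INTERMEDIATE", 22))
  sm <- classificationSummary(cats)
  expect_equal(sm$displacementTotal, 0.54)
  expect_equal(sm$viaIntermediateShare, 22 / 54)
  expect_equal(sum(sm$fractions), 1)
  smAllNo <- classificationSummary(rep("NO_BINDING", 10))
  expect_equal(smAllNo$displacementTotal, 0)
  expect_true(is.na(smAllNo$viaIntermediateShare))

  # generator-labeled ensemble: high per-trace agreement; the only allowed
  # confusion is a true intermediate visit shorter than the 3-frame
  # segmentation resolution collapsing a VIA trace onto DIRECT
  ens <- simulateDisplacementEnsemble(150, pNoBinding = 0.3,
                                      pIntermediate = 0.5, noiseSd = 20,
                                      seed = 98)
  cls <- do.call(rbind, lapply(ens, function(tr)
    classifyTrace(segmentDefault(tr), injectionTime(tr))))
  truth <- vapply(ens, function(tr) traceMetadata(tr)$categoryTruth, "")
  agree <- cls$category == truth
  expect_gt(mean(agree), 0.95)
  expect_true(all(truth[!agree] == "DISPLACEMENT_VIA_INTERMEDIATE" &
                  cls$category[!agree] == "DISPLACEMENT_DIRECT"))
})

test_that("fluctuation segments are reported where rolling variance is high", {
  set.seed(99)
  e <- c(rep(0.6, 200), runif(100, 0.2, 0.9), rep(0.8, 200))
  fl <- findFluctuationSegments(e, window = 9, varThreshold = 0.01)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$tStart, 20, tolerance = 0.05)
  expect_equal(fl$duration, 10, tolerance = 0.15)
  quiet <- findFluctuationSegments(rep(0.6, 300))
  expect_equal(nrow(quiet), 0)
})
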