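test_that("computeES returns the exact count ratios", {
  es <- computeES(50, 50, 100)
  expect_equal(es$e, 0.5)
  expect_equal(es$s, 0.5)
  # donor-only molecule: no acceptor signal anywhere
  es <- computeES(100, 0, 0)
  expect_equal(es$e, 0)
  expect_equal(es$s, 1)
  # counts placed at the RecO-ssDNA population center
  es <- computeES(22, 78, 100)
  expect_equal(es$e, 0.78)
  expect_equal(es$s, 0.50)
  # zero denominators are undefined, not zero
  es <- computeES(0, 0, 10)
  expect_true(is.na(es$e))
  expect_equal(es$s, 0)
  expect_true(is.na(computeES(0, 0, 0)$s))
  # ratio property: invariant under uniform scaling of all three counts
  expect_equal(computeES(10, 30, 40), computeES(50, 150, 200))
  expect_error(computeES(-1, 0, 0), ">= 0")
})

test_that("detectBursts finds constructed and simulated bursts", {
  expect_length(detectBursts(new("PhotonStream")), 0)

  # one cluster of 300 photons over 2 ms on silent background
  set.seed(71)
  t0 <- 0.0102
  ts <- sort(runif(300, t0, t0 + 0.002))
  ph <- sample(c("donor_exc", "acceptor_exc"), 300, replace = TRUE)
  ch <- ifelse(ph == "acceptor_exc", "acceptor_em",
               sample(c("donor_em", "acceptor_em"), 300, replace = TRUE))
  stream <- new("PhotonStream", timestamps = ts, excitationPhase = ph,
                detectionChannel = ch, alternationPeriod = 1e-4,
                duration = 0.1)
  found <- detectBursts(stream, binTime = 6e-4, countThreshold = 30)
  expect_equal(length(found), 1L)
  b <- bursts(found)
  expect_equal(b$iDD + b$iDA + b$iAA, 300)

  # high-SNR simulated stream: every generated burst is recovered
  sp <- speciesSpec("mid", 0.5, 0.05, 0.5, 0.05, 1)
  cfg <- alexSimConfig(sp, nBursts = 50, burstSizeMean = 300,
                       backgroundRate = 0, duration = 30)
  sim <- simulateAlexBursts(cfg, seed = 72, returnStream = TRUE)
  det <- detectBursts(sim$stream, binTime = 6e-4, countThreshold = 30)
  expect_equal(length(det), 50L)
  expect_error(detectBursts(sim$stream, binTime = 0), "binTime")
})

test_that("selectFretSpecies gates strictly on S and is idempotent", {
  b <- data.frame(tStart = 1:3, tEnd = 1:3 + 1e-3, iDD = c(90, 50, 10),
                  iDA = c(0, 0, 0), iAA = c(810, 50, 0),
                  e = c(0, 0, 0), s = c(0.10, 0.50, 0.90))
  bs <- new("BurstSet", bursts = b)
  sel <- selectFretSpecies(bs)
  expect_equal(bursts(sel)$s, 0.50)
  expect_length(selectFretSpecies(new("BurstSet")), 0)
  expect_identical(bursts(selectFretSpecies(sel)), bursts(sel))  # idempotent
  expect_error(selectFretSpecies(bs, 0.8, 0.2), "sMin")

  # 30% donor-only contaminant is removed; ~70% retained (binomial oracle)
  mix <- threeSpeciesMixture(donorOnlyFraction = 0.3)
  all <- simulateAlexBursts(alexSimConfig(mix, nBursts = 4000), seed = 73)
  sel <- selectFretSpecies(all)
  expect_false(any(bursts(sel)$species == "donor_only"))
  expect_lt(abs(length(sel) - 0.7 * 4000), 4 * sqrt(4000 * 0.7 * 0.3))
})

test_that("fitFretHistogram recovers component locations and areas", {
  # single tight cluster at the SSB-ssDNA peak
  set.seed(81)
  e1 <- rnorm(2000, 0.58, 0.03)
  f1 <- fitFretHistogram(e1, 1)
  expect_equal(f1$mean, 0.58, tolerance = 0.02)

  # two well-separated components with 700/300 bursts: area ratio 7:3
  sp <- rbind(speciesSpec("lo", 0.2, 0.05, 0.5, 0.05, 0.7),
              speciesSpec("hi", 0.8, 0.05, 0.5, 0.05, 0.3))
  b <- bursts(simulateAlexBursts(alexSimConfig(sp, nBursts = 5000), seed = 82))
  f2 <- fitFretHistogram(b$e, 2)
  ratio <- f2$area[1] / sum(f2$area)
  nLo <- sum(b$species == "lo")
  expect_equal(ratio, nLo / 5000, tolerance = 0.05)

  # degenerate identical values: mean exact, sd pinned at its lower bound
  f3 <- fitFretHistogram(rep(0.4, 50), 1, binWidth = 0.02)
  expect_equal(f3$mean, 0.4)
  expect_equal(f3$sd, 0.01)
  expect_equal(f3$area, 50)
  expect_error(fitFretHistogram(runif(5), 1), "at least 10")
  expect_error(fitFretHistogram(runif(100), 0), "nComponents")
})

test_that("likelihood mixture fit cross-checks the histogram decomposition", {
  sp <- rbind(speciesSpec("lo", 0.2, 0.06, 0.5, 0.05, 0.5),
              speciesSpec("hi", 0.8, 0.06, 0.5, 0.05, 0.5))
  b <- bursts(simulateAlexBursts(alexSimConfig(sp, nBursts = 4000), seed = 83))
  fh <- fitFretHistogram(b$e, 2)
  fm <- fitFretHistogram(b$e, 2, method = "mixture")
  expect_equal(fh$mean, fm$mean, tolerance = 0.02)
})

test_that("bindingFraction is the bound-area share", {
  comp <- data.frame(mean = c(0.1, 0.6), sd = c(0.05, 0.05), area = c(50, 50))
  expect_equal(bindingFraction(comp, boundIndex = 2, freeIndex = 1), 0.5)
  comp$area <- c(0, 100)
  expect_equal(bindingFraction(comp, 2, 1), 1.0)
  comp$area <- c(0, 0)
  expect_error(bindingFraction(comp, 2, 1), "zero")

  # 60/40 simulated mixture recovered through the full fit
  sp <- rbind(speciesSpec("free", 0.09, 0.06, 0.5, 0.05, 0.4),
              speciesSpec("bound", 0.58, 0.06, 0.5, 0.05, 0.6))
  b <- bursts(simulateAlexBursts(alexSimConfig(sp, nBursts = 4000), seed = 84))
  comp <- fitFretHistogram(b$e, 2)
  fTrue <- mean(b$species == "bound")   # realized multinomial draw
  expect_lt(abs(bindingFraction(comp, 2, 1) - fTrue), 0.05)
})

test_that("fitKd recovers the dissociation constant", {
  conc <- 0.28 * 10^seq(-1.5, 1.5, length.out = 8)
  # noiseless: machine-precision recovery and exact half-saturation
  tc0 <- simulateTitration(0.28, 1, conc, burstsPerPoint = Inf)
  f0 <- fitKd(tc0)
  expect_equal(fitRate(f0), 0.28, tolerance = 1e-6)
  expect_equal(fitParams(f0)$halfSaturationTheta, 0.5)
  # fixed Hill coefficient variant
  expect_equal(fitRate(fitKd(tc0, fixHillN = 1)), 0.28, tolerance = 1e-6)

  # binomially noisy curves: median relative error below 15%
  set.seed(85)
  errs <- vapply(1:50, function(i) {
    tc <- simulateTitration(0.28, 1, conc, burstsPerPoint = 1000)
    abs(fitRate(fitKd(tc)) - 0.28) / 0.28
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)

  # a curve that never crosses 0.5 is flagged as extrapolated
  lowC <- 0.28 * 10^seq(-3, -1, length.out = 5)
  tcLow <- simulateTitration(0.28, 1, lowC, burstsPerPoint = Inf)
  expect_true("extrapolated_kd" %in% fitFlags(fitKd(tcLow)))
  expect_error(fitKd(simulateTitration(1, 1, c(0.5, 1, 2),
                                       burstsPerPoint = Inf)), "4")
})

test_that("fractionsVsTime counts bursts per window exactly", {
  wins <- list(free = c(0.0, 0.25), ssb_bound = c(0.4, 0.7),
               reco_bound = c(0.71, 1.0))
  b <- data.frame(tStart = c(5, 15, 15, 15, 25, 35),
                  tEnd = c(5, 15, 15, 15, 25, 35) + 1e-3,
                  iDD = 1, iDA = 1, iAA = 1,
                  e = c(0.1, 0.1, 0.5, 0.8, 0.35, 0.5),
                  s = 0.5)
  ks <- fractionsVsTime(new("BurstSet", bursts = b), wins, binWidth = 10)
  fr <- fractions(ks)
  expect_equal(unname(fr[1, "free"]), 1)         # single burst, one window
  expect_equal(unname(fr[2, ]), c(1, 1, 1) / 3)  # one burst in each window
  # burst at E = 0.35 falls outside all windows: empty-bin flag
  expect_equal(burstCounts(ks)[3], 0L)
  expect_true(all(is.na(fr[3, ])))
  expect_equal(unname(fr[4, "ssb_bound"]), 1)
  expect_error(fractionsVsTime(new("BurstSet", bursts = b),
                               list(free = c(0, 0.5), ssb_bound = c(0.4, 0.7),
                                    reco_bound = c(0.8, 1)), 10),
               "disjoint")
})

test_that("fitExchangeRate recovers the relaxation rate", {
  tb <- seq(150, 3600, length.out = 12)
  k <- 1.10e-3
  s0 <- simulateExchangeSeries(k, 0.9, 0.1, tb, burstsPerBin = Inf)
  f0 <- fitExchangeRate(s0)
  expect_equal(fitRate(f0), k, tolerance = 1e-6)
  expect_equal(fitParams(f0)$halfLife, log(2) / fitRate(f0))

  # flat series: rate ~ 0 with the no-exchange flag
  flat <- simulateExchangeSeries(0, 0.8, 0.1, tb, burstsPerBin = 500, seed = 86)
  ff <- fitExchangeRate(flat)
  expect_equal(fitRate(ff), 0)
  expect_true("no_exchange" %in% fitFlags(ff))

  # fixed-plateau variant on complete exchange
  sC <- simulateExchangeSeries(k, 1, 0, tb, burstsPerBin = Inf)
  expect_equal(fitRate(fitExchangeRate(sC, fixPlateau = 0)), k,
               tolerance = 1e-6)
  expect_error(fitExchangeRate(simulateExchangeSeries(k, 1, 0, tb[1:3],
                                                      burstsPerBin = Inf)),
               "5 bins")
})

test_that("gated mixture pipeline recovers species means and fractions end to end", {
  mix <- threeSpeciesMixture(donorOnlyFraction = 0.3)
  bs <- simulateAlexBursts(alexSimConfig(mix, nBursts = 10000), seed = 87)
  sel <- selectFretSpecies(bs)
  comp <- fitFretHistogram(bursts(sel)$e, 3)
  expect_lt(max(abs(comp$mean - c(0.09, 0.58, 0.78))), 0.02)
  fracHat <- comp$area / sum(comp$area)
  expect_lt(max(abs(fracHat - 1 / 3)), 0.05)
})
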