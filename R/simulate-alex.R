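# Truncated-normal draws on [0, 1] via inverse-CDF; keeps the per-burst
# (E, S) jitter Gaussian-shaped without clipping mass onto the bounds.
.rtrunc01 <- function(n, mean, sd) {
  lo <- stats::pnorm((0 - mean) / sd)
  hi <- stats::pnorm((1 - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

.drawBurstSizes <- function(n, config) {
  floorN <- 20L
  if (config@burstSizeModel == "shifted_poisson") {
    lambda <- max(config@burstSizeMean - floorN, 0)
    floorN + stats::rpois(n, lambda)
  } else {
    sdlog <- 0.5
    meanlog <- log(config@burstSizeMean) - sdlog^2 / 2
    pmax(floorN, round(stats::rlnorm(n, meanlog, sdlog)))
  }
}

#' Simulate an ensemble of ALEX single-molecule bursts
#'
#' Draws each burst from one species of the configured mixture (by weight),
#' gives it a total photon count from the configured burst-size distribution
#' (20-photon floor), jitters its (E, S) around the species centers with a
#' truncated Gaussian, and splits photons by nested binomial draws: a
#' fraction S of the photons fall in the donor-excitation phase, and a
#' fraction E of those are emitted in the acceptor channel. Per-channel
#' Poisson background is added on top (a burst nominally spans two
#' acquisition bins). The generating species label is stored with every
#' burst so downstream recovery tests can count against ground truth.
#'
#' @param config an [AlexSimConfig-class] object.
#' @param seed integer RNG seed (the generator is bit-reproducible given
#'   `(config, seed)`).
#' @param returnStream if `TRUE`, additionally emit a timestamped
#'   [PhotonStream-class] with bursts placed at random times, photon
#'   timestamps consistent with the laser alternation period, and uniform
#'   background photons; used to exercise burst detection.
#' @return a [BurstSet-class], or `list(bursts=, stream=)` when
#'   `returnStream = TRUE`.
#' @seealso [detectBursts()], [computeES()], [selectFretSpecies()]
#' @export
simulateAlexBursts <- function(config, seed = NULL, returnStream = FALSE) {
  stopifnot(is(config, "AlexSimConfig"))
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config@nBursts
  sp <- config@species
  if (n == 0L) {
    empty <- new("BurstSet")
    return(if (returnStream) list(bursts = empty, stream = new("PhotonStream"))
           else empty)
  }

  idx <- sample.int(nrow(sp), n, replace = TRUE, prob = sp$fraction)
  size <- .drawBurstSizes(n, config)
  eTrue <- .rtrunc01(n, sp$eMean[idx], sp$eSd[idx])
  sTrue <- .rtrunc01(n, sp$sMean[idx], sp$sSd[idx])

  nDex <- stats::rbinom(n, size, sTrue)        # donor-excitation photons
  iDA <- stats::rbinom(n, nDex, eTrue)
  iDD <- nDex - iDA
  iAA <- size - nDex
  if (config@backgroundRate > 0) {
    bg <- 2 * config@backgroundRate            # nominal 2-bin transit
    iDD <- iDD + stats::rpois(n, bg)
    iDA <- iDA + stats::rpois(n, bg)
    iAA <- iAA + stats::rpois(n, bg)
  }

  transit <- 2 * config@binTime
  tStart <- stats::runif(n, 0, max(config@duration - transit, transit))
  b <- data.frame(tStart = tStart, tEnd = tStart + transit,
                  iDD = iDD, iDA = iDA, iAA = iAA,
                  e = NA_real_, s = NA_real_,
                  species = sp$name[idx],
                  stringsAsFactors = FALSE)
  b <- b[order(b$tStart), , drop = FALSE]
  rownames(b) <- NULL
  es <- computeES(b$iDD, b$iDA, b$iAA)
  b$e <- es$e
  b$s <- es$s
  burstSet <- new("BurstSet", bursts = b)

  if (!returnStream) return(burstSet)

  P <- config@alternationPeriod
  half <- P / 2
  nCycles <- max(1L, floor(transit / P))
  stampPhotons <- function(t0, count, phase) {
    if (count == 0) return(numeric(0))
    cyc <- sample.int(nCycles, count, replace = TRUE) - 1L
    offset <- if (phase == "donor_exc") 0 else half
    t0 + cyc * P + offset + stats::runif(count, 0, half)
  }
  ts <- vector("list", nrow(b))
  ph <- vector("list", nrow(b))
  ch <- vector("list", nrow(b))
  for (i in seq_len(nrow(b))) {
    tDD <- stampPhotons(b$tStart[i], b$iDD[i], "donor_exc")
    tDA <- stampPhotons(b$tStart[i], b$iDA[i], "donor_exc")
    tAA <- stampPhotons(b$tStart[i], b$iAA[i], "acceptor_exc")
    ts[[i]] <- c(tDD, tDA, tAA)
    ph[[i]] <- c(rep("donor_exc", b$iDD[i] + b$iDA[i]),
                 rep("acceptor_exc", b$iAA[i]))
    ch[[i]] <- c(rep("donor_em", b$iDD[i]), rep("acceptor_em", b$iDA[i]),
                 rep("acceptor_em", b$iAA[i]))
  }
  ts <- unlist(ts); ph <- unlist(ph); ch <- unlist(ch)
  if (config@backgroundRate > 0) {
    nBins <- config@duration / config@binTime
    for (channel in .CHANNELS) {
      nbg <- stats::rpois(1, config@backgroundRate * nBins)
      tb <- stats::runif(nbg, 0, config@duration)
      ts <- c(ts, tb)
      ph <- c(ph, ifelse(tb %% P < half, "donor_exc", "acceptor_exc"))
      ch <- c(ch, rep(channel, nbg))
    }
  }
  ord <- order(ts)
  stream <- new("PhotonStream", timestamps = ts[ord],
                excitationPhase = ph[ord], detectionChannel = ch[ord],
                alternationPeriod = P, duration = config@duration)
  list(bursts = burstSet, stream = stream)
}

#' Simulate an SSB-to-RecO exchange time course
#'
#' Models the displacement of SSB from ssDNA after RecO addition as a
#' first-order relaxation of the SSB-bound fraction,
#' \eqn{f(t) = f_\infty + (f_0 - f_\infty) e^{-k t}}, with the RecO-bound
#' fraction rising complementarily and the free-ssDNA fraction constant.
#' Per-bin observed fractions are multinomial draws of `burstsPerBin`
#' bursts (or the exact expectations when `burstsPerBin = Inf`).
#'
#' @param kExch exchange rate, 1/s (>= 0).
#' @param fSsb0 initial SSB-bound fraction of the bound population scale
#'   (must satisfy `fSsb0 + fFree <= 1`).
#' @param fFree constant free-ssDNA fraction.
#' @param timeBins numeric vector of bin-center times, seconds (nonempty).
#' @param burstsPerBin bursts counted per bin; `Inf` for a noiseless series.
#' @param seed RNG seed.
#' @param fSsbInf plateau SSB-bound fraction (default 0, complete exchange).
#' @return a [KineticSeries-class] carrying the generating parameters in
#'   `groundTruth`.
#' @seealso [fitExchangeRate()]
#' @export
simulateExchangeSeries <- function(kExch, fSsb0, fFree, timeBins,
                                   burstsPerBin = 500, seed = NULL,
                                   fSsbInf = 0) {
  stopifnot(kExch >= 0, fSsb0 >= 0, fSsb0 <= 1, fFree >= 0, fFree <= 1,
            fSsb0 + fFree <= 1 + 1e-12, fSsbInf >= 0, fSsbInf <= fSsb0)
  if (length(timeBins) == 0) stop("timeBins must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  fSsb <- fSsbInf + (fSsb0 - fSsbInf) * exp(-kExch * timeBins)
  fReco <- 1 - fFree - fSsb
  expected <- cbind(free = rep(fFree, length(timeBins)),
                    ssb_bound = fSsb, reco_bound = fReco)
  if (is.infinite(burstsPerBin)) {
    obs <- expected
    counts <- rep(0L, length(timeBins))
  } else {
    obs <- t(vapply(seq_along(timeBins), function(i) {
      stats::rmultinom(1, burstsPerBin, expected[i, ])[, 1] / burstsPerBin
    }, numeric(3)))
    colnames(obs) <- colnames(expected)
    counts <- rep(as.integer(burstsPerBin), length(timeBins))
  }
  new("KineticSeries", binCenters = as.numeric(timeBins), fractions = obs,
      counts = counts,
      groundTruth = list(kExch = kExch, fSsb0 = fSsb0, fSsbInf = fSsbInf,
                         fFree = fFree, expected = expected))
}

#' Simulate a single-molecule binding titration
#'
#' Expected bound fraction follows the Hill isotherm
#' \eqn{\theta(C) = C^n / (K_d^n + C^n)}; the observed fraction at each
#' concentration is a binomial draw over `burstsPerPoint` bursts.
#'
#' @param kd dissociation constant (> 0), any concentration unit as long as
#'   it matches `concentrations`.
#' @param hillN Hill coefficient (default 1).
#' @param concentrations nonnegative concentrations.
#' @param burstsPerPoint bursts per titration point; `Inf` for a noiseless
#'   curve.
#' @param seed RNG seed.
#' @return a [TitrationCurve-class] with generating parameters in
#'   `groundTruth`.
#' @seealso [fitKd()]
#' @export
simulateTitration <- function(kd, hillN = 1, concentrations,
                              burstsPerPoint = 1000, seed = NULL) {
  stopifnot(kd > 0, all(concentrations >= 0))
  if (!is.null(seed)) set.seed(seed)
  thetaExp <- ifelse(concentrations == 0, 0,
                     concentrations^hillN / (kd^hillN + concentrations^hillN))
  if (is.infinite(burstsPerPoint)) {
    theta <- thetaExp
    counts <- rep(0L, length(concentrations))
  } else {
    theta <- stats::rbinom(length(concentrations), burstsPerPoint, thetaExp) /
      burstsPerPoint
    counts <- rep(as.integer(burstsPerPoint), length(concentrations))
  }
  new("TitrationCurve", concentrations = as.numeric(concentrations),
      theta = theta, counts = counts,
      groundTruth = list(kd = kd, hillN = hillN, expected = thetaExp))
}

#' Simulate single-molecule binding waiting times
#'
#' Under pseudo-first-order association the waiting time for a protein at
#' concentration C to bind a surface-tethered ssDNA is exponential with rate
#' \eqn{k_a C}.
#'
#' @param kA second-order association constant, 1/(M s) (> 0).
#' @param concentrations protein concentrations, molar.
#' @param nPerConc waiting times drawn per concentration.
#' @param seed RNG seed.
#' @return data.frame with columns `concentration` (M) and `waitingTime` (s).
#' @seealso [fitAssociationConstant()]
#' @export
simulateBindingTimes <- function(kA, concentrations, nPerConc = 50,
                                 seed = NULL) {
  stopifnot(kA > 0, all(concentrations > 0), nPerConc >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(concentrations, function(C) {
    data.frame(concentration = C,
               waitingTime = stats::rexp(nPerConc, rate = kA * C))
  })
  do.call(rbind, out)
}
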