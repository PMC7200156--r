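# Sample a continuous-time Markov chain path (Gillespie) on [t0, tEnd].
# Returns data.frame(time = entry times, state = integer indices).
.sampleCTMC <- function(rateMatrix, initialState, t0, tEnd) {
  exitRates <- rowSums(rateMatrix) - diag(rateMatrix)
  times <- t0
  states <- initialState
  t <- t0
  s <- initialState
  while (TRUE) {
    r <- exitRates[s]
    if (r <= 0) break
    t <- t + stats::rexp(1, r)
    if (t >= tEnd) break
    p <- rateMatrix[s, ]
    p[s] <- 0
    s <- sample.int(length(p), 1, prob = p)
    times <- c(times, t)
    states <- c(states, s)
  }
  data.frame(time = times, state = states)
}

# Per-frame state index from a path (left-continuous step function).
.pathToFrames <- function(path, frameTimes) {
  idx <- findInterval(frameTimes, path$time)
  idx[idx < 1] <- 1
  path$state[idx]
}

# Render donor/acceptor intensities from a per-frame E series with Gaussian
# channel noise and irreversible single-step bleaching.
.renderChannels <- function(eFrames, frameTimes, totalIntensity, noiseSd,
                            donorBleachTime, acceptorBleachTime) {
  n <- length(frameTimes)
  acceptor <- totalIntensity * eFrames
  donor <- totalIntensity * (1 - eFrames)
  accAlive <- frameTimes < acceptorBleachTime
  donAlive <- frameTimes < donorBleachTime
  # acceptor bleached: its emission is lost and the donor recovers the full
  # excitation; donor bleached: no FRET pair emission at all
  acceptor[!accAlive] <- 0
  donor[!accAlive & donAlive] <- totalIntensity
  donor[!donAlive] <- 0
  acceptor[!donAlive] <- 0
  donor <- donor + stats::rnorm(n, 0, noiseSd)
  acceptor <- acceptor + stats::rnorm(n, 0, noiseSd)
  list(donor = donor, acceptor = acceptor,
       bleached = !(accAlive & donAlive))
}

#' Simulate a two-channel TIRF smFRET time trace
#'
#' The hidden state path is a continuous-time Markov chain over the
#' configured FRET states, sampled by the Gillespie algorithm and
#' discretized at the frame interval. Before `injectionTime` the chain is
#' held in `initialState` (flow-channel protocol: the competing protein is
#' absent until injection). Each trace draws its state FRET values once from
#' `N(eMean, eSd)` (molecule-to-molecule heterogeneity), then per-frame
#' donor/acceptor intensities are rendered with Gaussian channel noise;
#' photobleaching is a single irreversible step per channel with exponential
#' timing. The ground-truth per-frame state path is stored in the trace.
#'
#' @param config a [TraceSimConfig-class].
#' @param seed RNG seed.
#' @return a [FretTrace-class] whose `stateTruth` holds the generating state
#'   label per frame (`"BLEACHED"` after the first bleaching event) and whose
#'   `metadata$stateE` holds the per-trace state FRET values.
#' @seealso [computeTraceFret()], [segmentStates()]
#' @export
simulateTrace <- function(config, seed = NULL) {
  stopifnot(is(config, "TraceSimConfig"))
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  st <- config@states
  k <- nrow(st)
  dt <- config@frameInterval
  n <- max(1L, round(config@duration / dt))
  frameTimes <- (seq_len(n) - 1L) * dt

  path <- .sampleCTMC(config@rateMatrix, config@initialState,
                      config@injectionTime, config@duration)
  if (config@injectionTime > 0)
    path <- rbind(data.frame(time = 0, state = config@initialState), path)
  stateFrames <- .pathToFrames(path, frameTimes)

  stateE <- pmin(pmax(stats::rnorm(k, st$eMean, st$eSd), 0), 1)
  eFrames <- stateE[stateFrames]

  dBleach <- if (config@donorBleachRate > 0)
    stats::rexp(1, config@donorBleachRate) else Inf
  aBleach <- if (config@acceptorBleachRate > 0)
    stats::rexp(1, config@acceptorBleachRate) else Inf
  ch <- .renderChannels(eFrames, frameTimes, config@totalIntensity,
                        config@noiseSd, dBleach, aBleach)

  truth <- st$label[stateFrames]
  truth[ch$bleached] <- "BLEACHED"

  new("FretTrace", time = frameTimes, donor = ch$donor,
      acceptor = ch$acceptor, frameInterval = dt,
      injectionTime = if (config@injectionTime > 0) config@injectionTime else NA_real_,
      metadata = list(stateE = stats::setNames(stateE, st$label),
                      donorBleachTime = dBleach, acceptorBleachTime = aBleach,
                      path = path),
      stateTruth = truth)
}

#' Simulate a displacement-experiment trace ensemble
#'
#' Emulates the injection experiment in which RecO is added to preformed
#' SSB-ssDNA complexes: each trace starts in the SSB-bound MID state
#' (E ~ 0.6); after injection it either never leaves MID (no RecO binding),
#' converts directly MID to HIGH (E ~ 0.8, direct displacement), or passes
#' through the low-FRET heterotrimer intermediate (E ~ 0.2) on the way to
#' HIGH. Binding waiting times and intermediate dwells are exponential. The
#' generating category of every trace is stored in its metadata so
#' classifier fidelity can be scored against ground truth.
#'
#' @param nTraces number of traces.
#' @param pNoBinding probability that a trace never shows RecO binding.
#' @param pIntermediate probability, conditional on displacement, of an
#'   intermediate-state visit.
#' @param kBind post-injection binding rate, 1/s.
#' @param kIntermediateExit intermediate-state exit rate, 1/s.
#' @param injectionTime,duration,frameInterval seconds.
#' @param totalIntensity,noiseSd counts/frame.
#' @param levels named numeric FRET levels (`LOW`, `MID`, `HIGH`).
#' @param seed RNG seed.
#' @return list of [FretTrace-class]; each `metadata$categoryTruth` is one of
#'   `"NO_BINDING"`, `"DISPLACEMENT_DIRECT"`, `"DISPLACEMENT_VIA_INTERMEDIATE"`.
#' @seealso [classifyTrace()], [classificationSummary()]
#' @export
simulateDisplacementEnsemble <- function(nTraces, pNoBinding = 0,
                                         pIntermediate = 0.015,
                                         kBind = 0.05,
                                         kIntermediateExit = 0.2,
                                         injectionTime = 60, duration = 300,
                                         frameInterval = 0.1,
                                         totalIntensity = 1000, noiseSd = 50,
                                         levels = c(LOW = 0.2, MID = 0.6, HIGH = 0.8),
                                         seed = NULL) {
  stopifnot(pNoBinding >= 0, pNoBinding <= 1,
            pIntermediate >= 0, pIntermediate <= 1,
            kBind > 0, kIntermediateExit > 0,
            duration > injectionTime, injectionTime >= 0)
  if (!is.null(seed)) set.seed(seed)
  dt <- frameInterval
  n <- round(duration / dt)
  frameTimes <- (seq_len(n) - 1L) * dt
  lapply(seq_len(nTraces), function(i) {
    u <- stats::runif(1)
    eFrames <- rep(levels[["MID"]], n)
    truth <- rep("MID", n)
    if (u < pNoBinding) {
      category <- "NO_BINDING"
    } else {
      tBind <- injectionTime + stats::rexp(1, kBind)
      via <- stats::runif(1) < pIntermediate
      if (via) {
        tLowEnd <- tBind + stats::rexp(1, kIntermediateExit)
        low <- frameTimes >= tBind & frameTimes < tLowEnd
        high <- frameTimes >= tLowEnd
        eFrames[low] <- levels[["LOW"]]; truth[low] <- "LOW"
        eFrames[high] <- levels[["HIGH"]]; truth[high] <- "HIGH"
        category <- "DISPLACEMENT_VIA_INTERMEDIATE"
      } else {
        high <- frameTimes >= tBind
        eFrames[high] <- levels[["HIGH"]]; truth[high] <- "HIGH"
        category <- "DISPLACEMENT_DIRECT"
      }
      # a binding event after the trace end is, observably, no binding
      if (tBind >= duration) category <- "NO_BINDING"
    }
    ch <- .renderChannels(eFrames, frameTimes, totalIntensity, noiseSd,
                          Inf, Inf)
    new("FretTrace", time = frameTimes, donor = ch$donor,
        acceptor = ch$acceptor, frameInterval = dt,
        injectionTime = injectionTime,
        metadata = list(categoryTruth = category, levels = levels),
        stateTruth = truth)
  })
}
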