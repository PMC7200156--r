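#' Describe one FRET species in an ALEX mixture
#'
#' A species is a population of diffusing molecules with a characteristic
#' apparent FRET efficiency and stoichiometry, e.g. bare ssDNA (E ~ 0.09),
#' the SSB-ssDNA complex (E ~ 0.58), the RecO-ssDNA complex (E ~ 0.78), or a
#' donor-only contaminant (S ~ 1).
#'
#' @param name character label.
#' @param eMean,sMean population centers, in [0, 1].
#' @param eSd,sSd per-burst Gaussian jitter widths, > 0.
#' @param fraction mixture weight in [0, 1].
#' @return one-row data.frame; rbind rows to build a mixture.
#' @examples
#' rbind(speciesSpec("free", 0.09, 0.05, 0.5, 0.07, 0.5),
#'       speciesSpec("ssb",  0.58, 0.07, 0.5, 0.07, 0.5))
#' @export
speciesSpec <- function(name, eMean, eSd, sMean, sSd, fraction) {
  stopifnot(eMean >= 0, eMean <= 1, sMean >= 0, sMean <= 1,
            eSd > 0, sSd > 0, fraction >= 0, fraction <= 1)
  data.frame(name = as.character(name), eMean = eMean, eSd = eSd,
             sMean = sMean, sSd = sSd, fraction = fraction,
             stringsAsFactors = FALSE)
}

#' Configuration for the ALEX burst simulator
#'
#' @slot species data.frame of species rows (see [speciesSpec()]); fractions
#'   must sum to 1 within 1e-9.
#' @slot nBursts integer, number of bursts.
#' @slot burstSizeMean numeric, mean photons per burst (> 0).
#' @slot burstSizeModel character, `"shifted_poisson"` (default) or
#'   `"lognormal"`; both have a 20-photon floor.
#' @slot backgroundRate numeric, background photons per bin per channel.
#' @slot binTime numeric, seconds (default 0.6 ms, the acquisition bin).
#' @slot duration numeric, acquisition time in seconds (stream mode).
#' @slot alternationPeriod numeric, seconds (default 100 us).
#'
#' @export
setClass("AlexSimConfig",
  representation(species = "data.frame", nBursts = "integer",
                 burstSizeMean = "numeric", burstSizeModel = "character",
                 backgroundRate = "numeric", binTime = "numeric",
                 duration = "numeric", alternationPeriod = "numeric"),
  prototype(nBursts = 1000L, burstSizeMean = 300, burstSizeModel = "shifted_poisson",
            backgroundRate = 0, binTime = 6e-4, duration = 600,
            alternationPeriod = 1e-4)
)

setValidity("AlexSimConfig", function(object) {
  sp <- object@species
  need <- c("name", "eMean", "eSd", "sMean", "sSd", "fraction")
  if (!all(need %in% names(sp))) return("species must be built with speciesSpec()")
  if (abs(sum(sp$fraction) - 1) > 1e-9) return("species fractions must sum to 1")
  if (object@nBursts < 0) return("nBursts must be >= 0")
  if (object@burstSizeMean <= 0) return("burstSizeMean must be > 0")
  if (!object@burstSizeModel %in% c("shifted_poisson", "lognormal"))
    return("burstSizeModel must be 'shifted_poisson' or 'lognormal'")
  if (object@backgroundRate < 0) return("backgroundRate must be >= 0")
  if (object@binTime <= 0) return("binTime must be > 0")
  if (object@alternationPeriod <= 0) return("alternationPeriod must be > 0")
  TRUE
})

#' @rdname AlexSimConfig-class
#' @param species,nBursts,burstSizeMean,burstSizeModel,backgroundRate,binTime,duration,alternationPeriod
#'   see the class slots.
#' @export
alexSimConfig <- function(species, nBursts = 1000L, burstSizeMean = 300,
                          burstSizeModel = "shifted_poisson",
                          backgroundRate = 0, binTime = 6e-4, duration = 600,
                          alternationPeriod = 1e-4) {
  new("AlexSimConfig", species = species, nBursts = as.integer(nBursts),
      burstSizeMean = burstSizeMean, burstSizeModel = burstSizeModel,
      backgroundRate = backgroundRate, binTime = binTime, duration = duration,
      alternationPeriod = alternationPeriod)
}

#' Configuration for the TIRF trace simulator
#'
#' States are discrete FRET levels; the hidden path is a continuous-time
#' Markov chain over them. Before `injectionTime` the chain is held in
#' `initialState` (the flow-channel protocol: the rate matrix only applies
#' once the competing protein is injected).
#'
#' @slot states data.frame with columns `label`, `eMean`, `eSd`.
#' @slot rateMatrix square numeric matrix of transition rates (1/s), row =
#'   from-state, column = to-state, off-diagonals >= 0; diagonal ignored.
#' @slot initialState integer index of the pre-injection state.
#' @slot frameInterval numeric, seconds/frame (default 0.1 s).
#' @slot duration numeric, trace length in seconds (default 300 s).
#' @slot injectionTime numeric, seconds (0 = chain free from the start).
#' @slot totalIntensity numeric, donor + acceptor counts per frame.
#' @slot noiseSd numeric, Gaussian noise per channel (counts/frame).
#' @slot donorBleachRate,acceptorBleachRate numeric, 1/s.
#'
#' @export
setClass("TraceSimConfig",
  representation(states = "data.frame", rateMatrix = "matrix",
                 initialState = "integer", frameInterval = "numeric",
                 duration = "numeric", injectionTime = "numeric",
                 totalIntensity = "numeric", noiseSd = "numeric",
                 donorBleachRate = "numeric", acceptorBleachRate = "numeric"),
  prototype(initialState = 1L, frameInterval = 0.1, duration = 300,
            injectionTime = 0, totalIntensity = 1000, noiseSd = 50,
            donorBleachRate = 0, acceptorBleachRate = 0)
)

setValidity("TraceSimConfig", function(object) {
  st <- object@states
  if (!all(c("label", "eMean", "eSd") %in% names(st)))
    return("states must have columns label, eMean, eSd")
  k <- nrow(st)
  if (!all(dim(object@rateMatrix) == c(k, k)))
    return("rateMatrix must be k x k for k states")
  off <- object@rateMatrix; diag(off) <- 0
  if (any(off < 0)) return("rateMatrix off-diagonals must be >= 0")
  if (object@initialState < 1 || object@initialState > k)
    return("initialState out of range")
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  if (object@injectionTime < 0 || object@duration < object@injectionTime)
    return("need duration >= injectionTime >= 0")
  if (object@donorBleachRate < 0 || object@acceptorBleachRate < 0)
    return("bleach rates must be >= 0")
  TRUE
})

#' @rdname TraceSimConfig-class
#' @param states,rateMatrix,initialState,frameInterval,duration,injectionTime,totalIntensity,noiseSd,donorBleachRate,acceptorBleachRate
#'   see the class slots.
#' @export
traceSimConfig <- function(states, rateMatrix, initialState = 1L,
                           frameInterval = 0.1, duration = 300,
                           injectionTime = 0, totalIntensity = 1000,
                           noiseSd = 50, donorBleachRate = 0,
                           acceptorBleachRate = 0) {
  new("TraceSimConfig", states = states, rateMatrix = rateMatrix,
      initialState = as.integer(initialState), frameInterval = frameInterval,
      duration = duration, injectionTime = injectionTime,
      totalIntensity = totalIntensity, noiseSd = noiseSd,
      donorBleachRate = donorBleachRate, acceptorBleachRate = acceptorBleachRate)
}

#' Helper to build the states table for [traceSimConfig()]
#' @param label,eMean,eSd vectors of equal length.
#' @export
traceStates <- function(label, eMean, eSd) {
  data.frame(label = as.character(label), eMean = eMean, eSd = eSd,
             stringsAsFactors = FALSE)
}

#' Configuration for the two-color colocalization simulator
#'
#' Each pair starts colocalized (surface-tethered donor-labeled DNA plus
#' acceptor-labeled protein); the acceptor partner disappears at the first of
#' an exponential photobleaching event and an exponential dissociation event.
#' In image mode, per-frame two-channel images with Gaussian PSF spots and
#' Poisson noise are rendered as well.
#'
#' @slot nPairs integer.
#' @slot acceptorBleachRate,dissociationRate numeric, 1/s.
#' @slot duration,frameInterval numeric, seconds.
#' @slot imageMode logical.
#' @slot psfSigma numeric, pixels.
#' @slot imageShape integer of length 2 (rows, cols).
#' @slot spotPhotons numeric, expected photons per spot per frame.
#' @slot background numeric, expected photons per pixel per frame.
#' @slot channelOffset numeric of length 2, rigid pixel shift of channel B.
#'
#' @export
setClass("ColocSimConfig",
  representation(nPairs = "integer", acceptorBleachRate = "numeric",
                 dissociationRate = "numeric", duration = "numeric",
                 frameInterval = "numeric", imageMode = "logical",
                 psfSigma = "numeric", imageShape = "integer",
                 spotPhotons = "numeric", background = "numeric",
                 channelOffset = "numeric"),
  prototype(nPairs = 100L, acceptorBleachRate = 0, dissociationRate = 0,
            duration = 300, frameInterval = 1, imageMode = FALSE,
            psfSigma = 1.2, imageShape = c(64L, 64L), spotPhotons = 2000,
            background = 5, channelOffset = c(0, 0))
)

setValidity("ColocSimConfig", function(object) {
  if (object@nPairs < 0) return("nPairs must be >= 0")
  if (object@acceptorBleachRate < 0 || object@dissociationRate < 0)
    return("rates must be >= 0")
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  if (object@imageMode && object@psfSigma <= 0)
    return("psfSigma must be > 0 in image mode")
  if (length(object@imageShape) != 2 || length(object@channelOffset) != 2)
    return("imageShape and channelOffset must have length 2")
  TRUE
})

#' @rdname ColocSimConfig-class
#' @param nPairs,acceptorBleachRate,dissociationRate,duration,frameInterval,imageMode,psfSigma,imageShape,spotPhotons,background,channelOffset
#'   see the class slots.
#' @export
colocSimConfig <- function(nPairs = 100L, acceptorBleachRate = 0,
                           dissociationRate = 0, duration = 300,
                           frameInterval = 1, imageMode = FALSE,
                           psfSigma = 1.2, imageShape = c(64L, 64L),
                           spotPhotons = 2000, background = 5,
                           channelOffset = c(0, 0)) {
  new("ColocSimConfig", nPairs = as.integer(nPairs),
      acceptorBleachRate = acceptorBleachRate,
      dissociationRate = dissociationRate, duration = duration,
      frameInterval = frameInterval, imageMode = imageMode,
      psfSigma = psfSigma, imageShape = as.integer(imageShape),
      spotPhotons = spotPhotons, background = background,
      channelOffset = as.numeric(channelOffset))
}
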