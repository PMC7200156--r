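#' @import methods
NULL

# Phase / channel / state label vocabularies used throughout.
.PHASES   <- c("donor_exc", "acceptor_exc")
.CHANNELS <- c("donor_em", "acceptor_em")
.STATES   <- c("LOW", "MID", "HIGH", "UNASSIGNED", "BLEACHED")

#' Timestamped ALEX photon stream
#'
#' Container for a photon stream recorded under alternating laser excitation
#' (ALEX): one record per detected photon, carrying its arrival time, the
#' excitation phase during which it arrived (`donor_exc` or `acceptor_exc`)
#' and the detection channel (`donor_em` or `acceptor_em`).
#'
#' @slot timestamps numeric, photon arrival times in seconds, nondecreasing.
#' @slot excitationPhase character, `"donor_exc"` or `"acceptor_exc"` per photon.
#' @slot detectionChannel character, `"donor_em"` or `"acceptor_em"` per photon.
#' @slot alternationPeriod numeric, laser alternation period in seconds.
#' @slot duration numeric, total acquisition time in seconds.
#'
#' @export
setClass("PhotonStream",
  representation(
    timestamps = "numeric",
    excitationPhase = "character",
    detectionChannel = "character",
    alternationPeriod = "numeric",
    duration = "numeric"
  ),
  prototype(
    timestamps = numeric(0),
    excitationPhase = character(0),
    detectionChannel = character(0),
    alternationPeriod = 1e-4,
    duration = 0
  )
)

setValidity("PhotonStream", function(object) {
  n <- length(object@timestamps)
  msg <- character(0)
  if (length(object@excitationPhase) != n || length(object@detectionChannel) != n)
    msg <- c(msg, "timestamps, excitationPhase and detectionChannel must have equal length")
  if (n > 1 && is.unsorted(object@timestamps))
    msg <- c(msg, "timestamps must be nondecreasing")
  if (n > 0 && !all(object@excitationPhase %in% .PHASES))
    msg <- c(msg, "excitationPhase values must be 'donor_exc' or 'acceptor_exc'")
  if (n > 0 && !all(object@detectionChannel %in% .CHANNELS))
    msg <- c(msg, "detectionChannel values must be 'donor_em' or 'acceptor_em'")
  if (object@alternationPeriod <= 0) msg <- c(msg, "alternationPeriod must be > 0")
  if (length(msg)) msg else TRUE
})

#' Set of detected single-molecule bursts
#'
#' One row per burst: start/end times, the three ALEX photon counts
#' (`iDD` donor-excitation/donor-emission, `iDA` donor-excitation/
#' acceptor-emission, `iAA` acceptor-excitation/acceptor-emission) and the
#' derived apparent FRET efficiency `e` and stoichiometry `s`. Synthetic
#' bursts additionally carry a `species` ground-truth column.
#'
#' @slot bursts data.frame with columns `tStart`, `tEnd`, `iDD`, `iDA`,
#'   `iAA`, `e`, `s` and optionally `species`.
#'
#' @export
setClass("BurstSet", representation(bursts = "data.frame"),
  prototype(bursts = data.frame(
    tStart = numeric(0), tEnd = numeric(0),
    iDD = integer(0), iDA = integer(0), iAA = integer(0),
    e = numeric(0), s = numeric(0)
  ))
)

setValidity("BurstSet", function(object) {
  need <- c("tStart", "tEnd", "iDD", "iDA", "iAA", "e", "s")
  miss <- setdiff(need, names(object@bursts))
  if (length(miss))
    return(paste("bursts is missing columns:", paste(miss, collapse = ", ")))
  b <- object@bursts
  if (nrow(b) == 0) return(TRUE)
  if (any(b$iDD < 0 | b$iDA < 0 | b$iAA < 0)) return("photon counts must be >= 0")
  ok_e <- is.na(b$e) | (b$e >= 0 & b$e <= 1)
  ok_s <- is.na(b$s) | (b$s >= 0 & b$s <= 1)
  if (!all(ok_e)) return("e must lie in [0, 1] where defined")
  if (!all(ok_s)) return("s must lie in [0, 1] where defined")
  TRUE
})

#' Two-channel TIRF smFRET intensity time trace
#'
#' Donor and acceptor intensities of one surface-immobilized molecule,
#' sampled at a fixed frame interval. Synthetic traces carry the hidden
#' ground-truth state path in `stateTruth`.
#'
#' @slot time numeric, frame times in seconds.
#' @slot donor,acceptor numeric, per-frame intensities (counts/frame).
#' @slot frameInterval numeric, seconds per frame.
#' @slot injectionTime numeric, protein injection time in seconds (`NA` if none).
#' @slot metadata list, free-form condition metadata (ssDNA length,
#'   concentrations, condition label).
#' @slot stateTruth character, ground-truth state label per frame
#'   (length 0 when unknown).
#'
#' @export
setClass("FretTrace",
  representation(
    time = "numeric", donor = "numeric", acceptor = "numeric",
    frameInterval = "numeric", injectionTime = "numeric",
    metadata = "list", stateTruth = "character"
  ),
  prototype(
    time = numeric(0), donor = numeric(0), acceptor = numeric(0),
    frameInterval = 0.1, injectionTime = NA_real_,
    metadata = list(), stateTruth = character(0)
  )
)

setValidity("FretTrace", function(object) {
  n <- length(object@time)
  if (length(object@donor) != n || length(object@acceptor) != n)
    return("time, donor and acceptor must have equal length")
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  if (length(object@stateTruth) && length(object@stateTruth) != n)
    return("stateTruth must be empty or match the number of frames")
  TRUE
})

#' Discrete-state segmentation of a FRET trace
#'
#' Per-frame state labels (`LOW`/`MID`/`HIGH`/`UNASSIGNED`/`BLEACHED`) and the
#' derived ordered dwell list. Dwells tile the assigned portion of the trace.
#'
#' @slot labels character, one state label per frame.
#' @slot dwells data.frame with columns `state`, `tStart`, `duration`,
#'   `censored` (logical: truncated by trace end or bleaching).
#' @slot levels named numeric, FRET level centers keyed by state label.
#' @slot frameInterval numeric, seconds per frame.
#'
#' @export
setClass("StateSegmentation",
  representation(
    labels = "character", dwells = "data.frame",
    levels = "numeric", frameInterval = "numeric"
  ),
  prototype(
    labels = character(0),
    dwells = data.frame(state = character(0), tStart = numeric(0),
                        duration = numeric(0), censored = logical(0)),
    levels = c(LOW = 0.2, MID = 0.6, HIGH = 0.8),
    frameInterval = 0.1
  )
)

setValidity("StateSegmentation", function(object) {
  if (!all(object@labels %in% .STATES))
    return("labels must be LOW/MID/HIGH/UNASSIGNED/BLEACHED")
  need <- c("state", "tStart", "duration", "censored")
  if (!all(need %in% names(object@dwells)))
    return("dwells must have columns state, tStart, duration, censored")
  if (nrow(object@dwells) && any(object@dwells$duration <= 0))
    return("dwell durations must be > 0")
  TRUE
})

#' Time-resolved species-fraction series
#'
#' Per-time-bin fractions of the free, SSB-bound and RecO-bound ssDNA
#' populations, as counted from selected bursts; the substrate for
#' exchange-rate fitting.
#'
#' @slot binCenters numeric, bin centers in seconds.
#' @slot fractions matrix with columns `free`, `ssb_bound`, `reco_bound`;
#'   each row sums to 1 (rows from empty bins are `NA` and flagged).
#' @slot counts integer, bursts per bin.
#' @slot groundTruth list, generator parameters when synthetic.
#'
#' @export
setClass("KineticSeries",
  representation(binCenters = "numeric", fractions = "matrix",
                 counts = "integer", groundTruth = "list"),
  prototype(binCenters = numeric(0),
            fractions = matrix(numeric(0), ncol = 3,
                               dimnames = list(NULL, c("free", "ssb_bound", "reco_bound"))),
            counts = integer(0), groundTruth = list())
)

setValidity("KineticSeries", function(object) {
  if (nrow(object@fractions) != length(object@binCenters))
    return("fractions must have one row per bin")
  if (ncol(object@fractions) != 3)
    return("fractions must have three columns (free, ssb_bound, reco_bound)")
  if (length(object@counts) != length(object@binCenters))
    return("counts must have one entry per bin")
  rs <- rowSums(object@fractions)
  ok <- is.na(rs) | abs(rs - 1) < 1e-9
  if (!all(ok)) return("fraction triplets must sum to 1")
  if (any(object@counts < 0)) return("counts must be >= 0")
  TRUE
})

#' Concentration-dependent binding curve
#'
#' Bound fraction \eqn{\theta} versus ligand concentration; the substrate for
#' Hill-equation dissociation-constant fitting.
#'
#' @slot concentrations numeric, molar.
#' @slot theta numeric, bound fraction per point, in [0, 1].
#' @slot counts integer, bursts per point.
#' @slot groundTruth list, generator parameters when synthetic.
#'
#' @export
setClass("TitrationCurve",
  representation(concentrations = "numeric", theta = "numeric",
                 counts = "integer", groundTruth = "list"),
  prototype(concentrations = numeric(0), theta = numeric(0),
            counts = integer(0), groundTruth = list())
)

setValidity("TitrationCurve", function(object) {
  if (length(object@theta) != length(object@concentrations))
    return("theta must have one value per concentration")
  if (length(object@theta) && any(object@theta < 0 | object@theta > 1, na.rm = TRUE))
    return("theta must lie in [0, 1]")
  if (any(object@concentrations < 0)) return("concentrations must be >= 0")
  TRUE
})

#' Fitted rate / constant with uncertainty
#'
#' Generic result of a kinetic or equilibrium fit: exchange rate, dwell exit
#' rate, second-order association constant, or dissociation constant. `params`
#' carries model-specific extras (plateau, Hill coefficient, half-saturation);
#' `flags` carries data-quality annotations (`"no_exchange"`,
#' `"low_confidence"`, `"extrapolated_kd"`, ...).
#'
#' @slot rate numeric, the fitted quantity (units depend on `model`).
#' @slot uncertainty numeric, standard error in the same units (`NA` if not
#'   estimable).
#' @slot model character, model label.
#' @slot params list, auxiliary fitted parameters.
#' @slot flags character, zero or more annotation flags.
#'
#' @export
setClass("RateFit",
  representation(rate = "numeric", uncertainty = "numeric",
                 model = "character", params = "list", flags = "character"),
  prototype(rate = NA_real_, uncertainty = NA_real_, model = "unspecified",
            params = list(), flags = character(0))
)

setValidity("RateFit", function(object) {
  if (!is.na(object@rate) && object@rate < 0) return("rate must be >= 0")
  if (!is.na(object@uncertainty) && object@uncertainty < 0)
    return("uncertainty must be >= 0")
  TRUE
})

#' Colocalization time-course result
#'
#' Per-frame colocalized fraction of two-color pairs plus the fraction at the
#' evaluation time (default 4.5 min after treatment) and, when a no-treatment
#' control is supplied, the bleaching-corrected fraction.
#'
#' @slot nPairs integer, number of pairs scored.
#' @slot time numeric, frame times in seconds.
#' @slot fraction numeric, colocalized fraction per frame.
#' @slot evalTime numeric, evaluation time in seconds.
#' @slot fractionAtEval numeric, fraction at `evalTime`.
#' @slot controlFraction numeric, no-treatment fraction (`NA` if absent).
#' @slot correctedFraction numeric, `fractionAtEval / controlFraction`
#'   clipped to [0, 1] (`NA` if no control).
#'
#' @export
setClass("ColocResult",
  representation(nPairs = "integer", time = "numeric", fraction = "numeric",
                 evalTime = "numeric", fractionAtEval = "numeric",
                 controlFraction = "numeric", correctedFraction = "numeric"),
  prototype(nPairs = 0L, time = numeric(0), fraction = numeric(0),
            evalTime = 270, fractionAtEval = NA_real_,
            controlFraction = NA_real_, correctedFraction = NA_real_)
)

setValidity("ColocResult", function(object) {
  if (length(object@fraction) != length(object@time))
    return("fraction must have one value per frame")
  f <- c(object@fraction, object@fractionAtEval, object@controlFraction,
         object@correctedFraction)
  f <- f[!is.na(f)]
  if (length(f) && any(f < 0 | f > 1)) return("fractions must lie in [0, 1]")
  TRUE
})
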