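#' Accessors for fretx S4 containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a fretx S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bursts", function(x) standardGeneric("bursts"))
#' @rdname accessors
#' @export
setMethod("bursts", "BurstSet", function(x) x@bursts)

#' @rdname accessors
#' @export
setGeneric("dwells", function(x) standardGeneric("dwells"))
#' @rdname accessors
#' @export
setMethod("dwells", "StateSegmentation", function(x) x@dwells)

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setMethod("stateLabels", "StateSegmentation", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setMethod("frameInterval", "FretTrace", function(x) x@frameInterval)
#' @rdname accessors
#' @export
setMethod("frameInterval", "StateSegmentation", function(x) x@frameInterval)

#' @rdname accessors
#' @export
setGeneric("injectionTime", function(x) standardGeneric("injectionTime"))
#' @rdname accessors
#' @export
setMethod("injectionTime", "FretTrace", function(x) x@injectionTime)

#' @rdname accessors
#' @export
setGeneric("donorIntensity", function(x) standardGeneric("donorIntensity"))
#' @rdname accessors
#' @export
setMethod("donorIntensity", "FretTrace", function(x) x@donor)

#' @rdname accessors
#' @export
setGeneric("acceptorIntensity", function(x) standardGeneric("acceptorIntensity"))
#' @rdname accessors
#' @export
setMethod("acceptorIntensity", "FretTrace", function(x) x@acceptor)

#' @rdname accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setMethod("traceTime", "FretTrace", function(x) x@time)

#' @rdname accessors
#' @export
setGeneric("stateTruth", function(x) standardGeneric("stateTruth"))
#' @rdname accessors
#' @export
setMethod("stateTruth", "FretTrace", function(x) x@stateTruth)

#' @rdname accessors
#' @export
setGeneric("traceMetadata", function(x) standardGeneric("traceMetadata"))
#' @rdname accessors
#' @export
setMethod("traceMetadata", "FretTrace", function(x) x@metadata)

#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setMethod("binCenters", "KineticSeries", function(x) x@binCenters)

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setMethod("fractions", "KineticSeries", function(x) x@fractions)

#' @rdname accessors
#' @export
setGeneric("burstCounts", function(x) standardGeneric("burstCounts"))
#' @rdname accessors
#' @export
setMethod("burstCounts", "KineticSeries", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("burstCounts", "TitrationCurve", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))
#' @rdname accessors
#' @export
setMethod("concentrations", "TitrationCurve", function(x) x@concentrations)

#' @rdname accessors
#' @export
setGeneric("boundFraction", function(x) standardGeneric("boundFraction"))
#' @rdname accessors
#' @export
setMethod("boundFraction", "TitrationCurve", function(x) x@theta)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "KineticSeries", function(x) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("groundTruth", "TitrationCurve", function(x) x@groundTruth)

#' @rdname accessors
#' @export
setGeneric("fitRate", function(x) standardGeneric("fitRate"))
#' @rdname accessors
#' @export
setMethod("fitRate", "RateFit", function(x) x@rate)

#' @rdname accessors
#' @export
setGeneric("fitUncertainty", function(x) standardGeneric("fitUncertainty"))
#' @rdname accessors
#' @export
setMethod("fitUncertainty", "RateFit", function(x) x@uncertainty)

#' @rdname accessors
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setMethod("fitParams", "RateFit", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("fitFlags", function(x) standardGeneric("fitFlags"))
#' @rdname accessors
#' @export
setMethod("fitFlags", "RateFit", function(x) x@flags)

#' @rdname accessors
#' @export
setGeneric("colocCurve", function(x) standardGeneric("colocCurve"))
#' @rdname accessors
#' @export
setMethod("colocCurve", "ColocResult", function(x)
  data.frame(time = x@time, fraction = x@fraction))

#' @rdname accessors
#' @export
setGeneric("fractionAtEval", function(x) standardGeneric("fractionAtEval"))
#' @rdname accessors
#' @export
setMethod("fractionAtEval", "ColocResult", function(x) x@fractionAtEval)

setMethod("length", "PhotonStream", function(x) length(x@timestamps))
setMethod("length", "BurstSet", function(x) nrow(x@bursts))
setMethod("length", "FretTrace", function(x) length(x@time))

setMethod("show", "PhotonStream", function(object) {
  cat("PhotonStream with", length(object@timestamps), "photons over",
      format(object@duration), "s\n")
  cat("  alternation period:", format(object@alternationPeriod * 1e6), "us\n")
  if (length(object@timestamps)) {
    cat("  phases:  ", paste(sprintf("%s=%d", names(table(object@excitationPhase)),
                                     as.integer(table(object@excitationPhase))),
                             collapse = ", "), "\n")
  }
})

setMethod("show", "BurstSet", function(object) {
  b <- object@bursts
  cat("BurstSet with", nrow(b), "bursts\n")
  if (nrow(b)) {
    cat(sprintf("  median photons/burst: %.0f\n",
                stats::median(b$iDD + b$iDA + b$iAA)))
    cat(sprintf("  E: median %.3f   S: median %.3f\n",
                stats::median(b$e, na.rm = TRUE), stats::median(b$s, na.rm = TRUE)))
    if ("species" %in% names(b))
      cat("  ground-truth species:",
          paste(names(table(b$species)), collapse = ", "), "\n")
  }
})

setMethod("show", "FretTrace", function(object) {
  cat("FretTrace:", length(object@time), "frames at",
      format(object@frameInterval), "s/frame")
  if (!is.na(object@injectionTime))
    cat(", injection at", format(object@injectionTime), "s")
  cat("\n")
  if (length(object@stateTruth)) cat("  carries ground-truth state path\n")
})

setMethod("show", "StateSegmentation", function(object) {
  cat("StateSegmentation:", length(object@labels), "frames,",
      nrow(object@dwells), "dwells\n")
  if (length(object@labels))
    print(table(factor(object@labels, levels = .STATES)))
})

setMethod("show", "RateFit", function(object) {
  cat(sprintf("RateFit [%s]: %.6g", object@model, object@rate))
  if (!is.na(object@uncertainty)) cat(sprintf(" +/- %.3g", object@uncertainty))
  cat("\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf("ColocResult: %d pairs; fraction %.3f at t = %.0f s\n",
              object@nPairs, object@fractionAtEval, object@evalTime))
  if (!is.na(object@correctedFraction))
    cat(sprintf("  bleaching-corrected: %.3f (control %.3f)\n",
                object@correctedFraction, object@controlFraction))
})
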