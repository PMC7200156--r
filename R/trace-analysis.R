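#' Per-frame FRET efficiency of a TIRF trace
#'
#' \eqn{E = I_A / (I_D + I_A)} per frame. Frames whose total intensity falls
#' below a background floor (dye bleached, or no molecule) get `NA` instead
#' of a spurious ratio.
#'
#' @param trace a [FretTrace-class].
#' @param backgroundFloor counts/frame below which a frame is unassigned;
#'   `NULL` (default) uses 25% of the median total intensity of the trace.
#' @return numeric E series (NA where undefined).
#' @export
computeTraceFret <- function(trace, backgroundFloor = NULL) {
  stopifnot(is(trace, "FretTrace"))
  d <- donorIntensity(trace)
  a <- acceptorIntensity(trace)
  if (length(d) == 0) stop("empty trace")
  tot <- d + a
  if (all(tot == 0)) stop("all-zero trace")
  if (is.null(backgroundFloor)) backgroundFloor <- 0.25 * stats::median(tot)
  e <- ifelse(tot >= backgroundFloor & tot > 0, a / tot, NA_real_)
  pmin(pmax(e, 0), 1)
}

#' Filter traces by unbleached observation span
#'
#' Retains traces whose assigned (above-floor) span from the start reaches
#' `minDuration` — the trace-selection rule that excludes dye-bleaching
#' events from binding-fraction counts (default 3.5 min). Optionally also
#' requires the intensity loss, when it occurs, to be a single irreversible
#' step (no recovery above the floor), the signature of one dye pair.
#'
#' @param traces list of [FretTrace-class].
#' @param minDuration seconds (default 210 s = 3.5 min).
#' @param requireSingleDyePair logical.
#' @param backgroundFloor passed to [computeTraceFret()].
#' @return the retained sublist.
#' @export
filterTraces <- function(traces, minDuration = 210,
                         requireSingleDyePair = FALSE,
                         backgroundFloor = NULL) {
  keep <- vapply(traces, function(tr) {
    e <- computeTraceFret(tr, backgroundFloor)
    alive <- !is.na(e)
    firstDead <- match(FALSE, alive)
    span <- if (is.na(firstDead)) length(e) else firstDead - 1L
    ok <- span * frameInterval(tr) >= minDuration
    if (ok && requireSingleDyePair && !is.na(firstDead))
      ok <- !any(alive[firstDead:length(alive)])
    ok
  }, logical(1))
  traces[keep]
}

#' Segment a FRET series into discrete states
#'
#' Nearest-level thresholding: each frame is assigned to the closest level
#' center within `halfWidth`, otherwise `UNASSIGNED` (`NA` frames are
#' `BLEACHED`). Runs shorter than `minDwellFrames` are merged into their
#' flanking state (the earlier state wins) to reject single-frame shot
#' noise; the surviving runs of assigned states become the dwell list.
#' Dwells truncated by the trace start, trace end or bleaching are marked
#' censored. The assignment depends only on E, so it is invariant under
#' uniform intensity rescaling of both channels.
#'
#' @param eSeries numeric E series (from [computeTraceFret()]).
#' @param levelCenters named FRET level centers; names must be among
#'   `LOW`, `MID`, `HIGH`; centers must be separated by more than
#'   `2 * halfWidth`.
#' @param halfWidth assignment half-window in E units (default 0.12).
#' @param minDwellFrames minimum run length in frames (default 3 = 0.3 s at
#'   100 ms resolution).
#' @param frameInterval seconds/frame.
#' @return a [StateSegmentation-class].
#' @export
segmentStates <- function(eSeries, levelCenters = c(LOW = 0.2, MID = 0.6, HIGH = 0.8),
                          halfWidth = 0.12, minDwellFrames = 3,
                          frameInterval = 0.1) {
  stopifnot(length(levelCenters) >= 1, !is.null(names(levelCenters)))
  if (!all(names(levelCenters) %in% c("LOW", "MID", "HIGH")))
    stop("levelCenters names must be among LOW, MID, HIGH")
  # overlapping half-windows are resolved by nearest-center assignment, but
  # a center falling inside another's window would be genuinely ambiguous
  cs <- sort(levelCenters)
  if (length(cs) > 1 && any(diff(cs) <= halfWidth))
    stop("overlapping levels: centers must be separated by more than halfWidth")

  n <- length(eSeries)
  labels <- rep("UNASSIGNED", n)
  labels[is.na(eSeries)] <- "BLEACHED"
  idxOk <- which(!is.na(eSeries))
  if (length(idxOk)) {
    d <- abs(outer(eSeries[idxOk], levelCenters, `-`))
    nearest <- max.col(-d, ties.method = "first")
    within <- d[cbind(seq_along(idxOk), nearest)] <= halfWidth
    labels[idxOk[within]] <- names(levelCenters)[nearest[within]]
  }

  # merge sub-minimum runs into the flanking state; earlier state wins
  repeat {
    r <- rle(labels)
    short <- which(r$lengths < minDwellFrames & r$values != "BLEACHED")
    if (length(r$lengths) <= 1 || length(short) == 0) break
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- if (i > 1) r$values[i - 1] else r$values[i + 1]
    labels <- inverse.rle(r)
  }

  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  assigned <- r$values %in% c("LOW", "MID", "HIGH")
  censored <- logical(length(r$values))
  for (i in which(assigned)) {
    touchesEdge <- starts[i] == 1L || ends[i] == n
    nextBleach <- i < length(r$values) && r$values[i + 1] == "BLEACHED"
    censored[i] <- touchesEdge || nextBleach
  }
  dw <- data.frame(state = r$values[assigned],
                   tStart = (starts[assigned] - 1L) * frameInterval,
                   duration = r$lengths[assigned] * frameInterval,
                   censored = censored[assigned],
                   stringsAsFactors = FALSE)
  rownames(dw) <- NULL
  new("StateSegmentation", labels = labels, dwells = dw,
      levels = levelCenters, frameInterval = frameInterval)
}

#' Waiting time to the first stable visit of a target state
#'
#' Returns the delay between protein injection and the start of the first
#' dwell in `targetState` at or after the injection time — the binding time
#' t of an association-kinetics measurement. `NA` (with the `"no_binding"`
#' attribute set) when the trace never reaches the target state.
#'
#' @param seg a [StateSegmentation-class].
#' @param injectionTime seconds, within the trace.
#' @param targetState `"LOW"`, `"MID"` or `"HIGH"`.
#' @return waiting time in seconds, or `NA` if no binding occurred.
#' @export
findBindingTime <- function(seg, injectionTime, targetState) {
  stopifnot(is(seg, "StateSegmentation"))
  n <- length(stateLabels(seg))
  if (injectionTime < 0 || injectionTime > n * frameInterval(seg))
    stop("injectionTime outside the trace")
  injFrame <- min(max(1L, floor(injectionTime / frameInterval(seg)) + 1L), n)
  if (stateLabels(seg)[injFrame] == "BLEACHED")
    stop("trace bleached before injection")
  dw <- dwells(seg)
  hit <- dw$state == targetState & (dw$tStart + dw$duration) > injectionTime
  if (!any(hit)) {
    out <- NA_real_
    attr(out, "no_binding") <- TRUE
    return(out)
  }
  max(dw$tStart[which(hit)[1]] - injectionTime, 0)
}

#' Fit a single-exponential rate to a dwell-time distribution
#'
#' The transition rate is the reciprocal of the average lifetime of the
#' single-exponential dwell-time distribution; for exponential data the
#' maximum-likelihood estimate is exactly `1/mean(durations)`. Dwells
#' censored by the trace end or bleaching are excluded by default; the
#' right-censored maximum-likelihood estimator (events divided by total
#' observed time) is available instead. Fewer than 10 complete dwells fall
#' back to the reciprocal mean with a low-confidence flag.
#'
#' @param durations dwell durations in seconds, or a data.frame with
#'   `duration` and `censored` columns (as from [dwells()]).
#' @param censored logical vector matching `durations` (ignored when a
#'   data.frame is supplied).
#' @param method `"exclude_censored"` (default) or `"censored_mle"`.
#' @return a [RateFit-class] with `rate` in 1/s, `params$meanLifetime`, and
#'   `params$n` (dwells used).
#' @export
fitDwellRate <- function(durations, censored = NULL,
                         method = c("exclude_censored", "censored_mle")) {
  method <- match.arg(method)
  if (is.data.frame(durations)) {
    censored <- durations$censored
    durations <- durations$duration
  }
  if (is.null(censored)) censored <- rep(FALSE, length(durations))
  if (length(durations) == 0) stop("empty dwell list")
  stopifnot(all(durations > 0))
  flags <- character(0)
  if (method == "censored_mle") {
    nEvents <- sum(!censored)
    if (nEvents == 0) stop("no uncensored dwell events")
    rate <- nEvents / sum(durations)
    n <- length(durations)
  } else {
    d <- durations[!censored]
    if (length(d) == 0) stop("no complete dwells after censoring exclusion")
    if (length(d) < 10) flags <- c(flags, "low_confidence")
    rate <- 1 / mean(d)
    n <- length(d)
  }
  new("RateFit", rate = rate, uncertainty = rate / sqrt(n),
      model = "exponential_dwell",
      params = list(meanLifetime = 1 / rate, n = n), flags = flags)
}

#' Observed binding rates per concentration from waiting times
#'
#' Per concentration, the pseudo-first-order rate is the reciprocal of the
#' mean binding time (the convention used for association-kinetics plots);
#' the single-exponential MLE rate is identical and reported alongside its
#' standard error.
#'
#' @param bindingTimes data.frame with `concentration` (M) and
#'   `waitingTime` (s) columns (as from [simulateBindingTimes()]).
#' @return data.frame with `concentration`, `kObs` (1/s), `kObsSe`, `n`.
#' @seealso [fitAssociationConstant()]
#' @export
bindingRatesByConcentration <- function(bindingTimes) {
  stopifnot(all(c("concentration", "waitingTime") %in% names(bindingTimes)))
  t <- bindingTimes$waitingTime
  ok <- !is.na(t)
  sp <- split(t[ok], bindingTimes$concentration[ok])
  out <- data.frame(concentration = as.numeric(names(sp)),
                    kObs = vapply(sp, function(x) 1 / mean(x), numeric(1)),
                    kObsSe = vapply(sp, function(x) 1 / mean(x) / sqrt(length(x)),
                                    numeric(1)),
                    n = vapply(sp, length, numeric(1)))
  rownames(out) <- NULL
  out[order(out$concentration), , drop = FALSE]
}

#' Fit the second-order association constant
#'
#' Weighted linear fit of the observed pseudo-first-order binding rate
#' versus protein concentration, \eqn{k_{obs} = k_a C}, through the origin
#' by default (an intercept can be freed). The slope is the second-order
#' association constant in 1/(M s).
#'
#' @param ratesByConcentration data.frame with `concentration` (M) and
#'   `kObs` (1/s); an optional `kObsSe` column supplies weights
#'   (1/se^2).
#' @param intercept fit a free intercept (default `FALSE`).
#' @return a [RateFit-class]: `rate` = slope (1/(M s)), `params$intercept`.
#' @export
fitAssociationConstant <- function(ratesByConcentration, intercept = FALSE) {
  d <- ratesByConcentration
  stopifnot(all(c("concentration", "kObs") %in% names(d)))
  if (length(unique(d$concentration)) < 2)
    stop("need at least 2 distinct concentrations")
  w <- if ("kObsSe" %in% names(d) && all(d$kObsSe > 0)) 1 / d$kObsSe^2
       else rep(1, nrow(d))
  fm <- if (intercept) kObs ~ concentration else kObs ~ 0 + concentration
  fit <- stats::lm(fm, data = d, weights = w)
  sm <- summary(fit)$coefficients
  slope <- sm["concentration", "Estimate"]
  se <- sm["concentration", "Std. Error"]
  b0 <- if (intercept) stats::coef(fit)[["(Intercept)"]] else 0
  new("RateFit", rate = max(slope, 0), uncertainty = se,
      model = "linear_association", params = list(intercept = b0))
}

#' Classify the post-injection displacement pathway of one trace
#'
#' Applies the pathway rules to the post-injection dwell sequence of a
#' segmented trace: never leaving the SSB-bound MID level is no binding; a
#' MID-to-HIGH conversion without a LOW visit is direct displacement; any
#' LOW (heterotrimer intermediate) dwell on the way to a terminal HIGH is
#' displacement via the intermediate; a LOW visit that returns to MID
#' without ever reaching HIGH is an intermediate return; reaching HIGH more
#' than once (or leaving it again) marks a multi-transition trace. LOW
#' visits and HIGH entries are tallied for multi-transition statistics.
#'
#' @param seg a [StateSegmentation-class] covering the post-injection span.
#' @param injTime injection time in seconds.
#' @return one-row data.frame with `category`, `nLowVisits`,
#'   `nHighTransitions`, `nIntermediateReturns`.
#' @seealso [classificationSummary()]
#' @export
classifyTrace <- function(seg, injTime) {
  stopifnot(is(seg, "StateSegmentation"))
  dw <- dwells(seg)
  if (nrow(dw) == 0) stop("unsegmented trace (no assigned dwells)")
  post <- dw[dw$tStart + dw$duration > injTime, , drop = FALSE]
  if (nrow(post) == 0) stop("no assigned dwells after injection")
  s <- rle(post$state)$values
  nLow <- sum(s == "LOW")
  nHigh <- sum(s == "HIGH")
  lowToMid <- sum(s[-length(s)] == "LOW" & s[-1] == "MID")
  terminal <- s[length(s)]
  category <-
    if (nHigh == 0 && nLow == 0) "NO_BINDING"
    else if (nHigh == 0) "INTERMEDIATE_RETURN"
    else if (terminal == "HIGH" && nHigh == 1 && nLow == 0) "DISPLACEMENT_DIRECT"
    else if (terminal == "HIGH" && nHigh == 1) "DISPLACEMENT_VIA_INTERMEDIATE"
    else "MULTI_TRANSITION"
  data.frame(category = category, nLowVisits = nLow,
             nHighTransitions = nHigh, nIntermediateReturns = lowToMid,
             stringsAsFactors = FALSE)
}

#' Summarize trace classifications into population fractions
#'
#' Fractions per terminal category (summing to 1), the total displacement
#' fraction (direct + via-intermediate + multi-transition displacements
#' ending in HIGH are direct/via by construction), and, among displaced
#' traces, the share that visited the intermediate — the per-trace analogue
#' of a displacement-population bar plot.
#'
#' @param classes data.frame of [classifyTrace()] rows (rbind them), or a
#'   character vector of categories.
#' @return list with `fractions` (named, sums to 1), `displacementTotal`,
#'   `viaIntermediateShare` (NA when no displacements), and `n`.
#' @export
classificationSummary <- function(classes) {
  cats <- if (is.data.frame(classes)) classes$category else as.character(classes)
  if (length(cats) == 0) stop("no classified traces")
  lv <- c("NO_BINDING", "DISPLACEMENT_DIRECT", "DISPLACEMENT_VIA_INTERMEDIATE",
          "INTERMEDIATE_RETURN", "MULTI_TRANSITION")
  if (!all(cats %in% lv)) stop("unknown category label")
  tab <- table(factor(cats, levels = lv))
  frac <- as.numeric(tab) / length(cats)
  names(frac) <- lv
  direct <- frac[["DISPLACEMENT_DIRECT"]]
  via <- frac[["DISPLACEMENT_VIA_INTERMEDIATE"]]
  disp <- direct + via
  list(fractions = frac,
       displacementTotal = disp,
       viaIntermediateShare = if (disp > 0) via / disp else NA_real_,
       n = length(cats))
}

#' Detect pre-binding FRET fluctuation segments
#'
#' Flags runs where the rolling-window variance of the E series exceeds a
#' threshold — the unstable, rapidly fluctuating FRET stretches that precede
#' full binding of a two-site binder on short ssDNA. Reported for trace
#' annotation; not used in rate fits.
#'
#' @param eSeries numeric E series.
#' @param window rolling window in frames (odd; default 9).
#' @param varThreshold variance threshold in E^2 units (default 0.01).
#' @param frameInterval seconds/frame.
#' @return data.frame with `tStart` and `duration` of fluctuation segments.
#' @export
findFluctuationSegments <- function(eSeries, window = 9, varThreshold = 0.01,
                                    frameInterval = 0.1) {
  stopifnot(window >= 3)
  n <- length(eSeries)
  if (n < window) return(data.frame(tStart = numeric(0), duration = numeric(0)))
  half <- floor(window / 2)
  rv <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    seg <- eSeries[(i - half):(i + half)]
    if (all(!is.na(seg))) rv[i] <- stats::var(seg)
  }
  hot <- !is.na(rv) & rv > varThreshold
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(tStart = (starts[sel] - 1L) * frameInterval,
             duration = r$lengths[sel] * frameInterval)
}
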