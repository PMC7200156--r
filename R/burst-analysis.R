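#' Apparent FRET efficiency and stoichiometry from ALEX photon counts
#'
#' Computes the apparent (uncorrected) FRET efficiency
#' \eqn{E = I_{DA} / (I_{DD} + I_{DA})} and stoichiometry
#' \eqn{S = (I_{DD} + I_{DA}) / (I_{DD} + I_{DA} + I_{AA})}. No gamma-factor,
#' donor-leakage or direct-excitation corrections are applied; these are the
#' raw sorting coordinates of the E-S histogram. S ~ 1 marks donor-only
#' molecules (no acceptor signal), S ~ 0 acceptor-only ones.
#'
#' @param iDD,iDA,iAA photon counts (vectors of equal length):
#'   donor-excitation/donor-emission, donor-excitation/acceptor-emission,
#'   acceptor-excitation/acceptor-emission.
#' @return data.frame with columns `e` and `s`; a zero denominator yields
#'   `NA` (undefined, distinct from a numeric zero).
#' @examples
#' computeES(50, 50, 100)   # E = 0.5, S = 0.5
#' computeES(100, 0, 0)     # donor-only: E = 0, S = 1
#' @export
computeES <- function(iDD, iDA, iAA) {
  stopifnot(length(iDD) == length(iDA), length(iDA) == length(iAA))
  if (any(c(iDD, iDA, iAA) < 0)) stop("photon counts must be >= 0")
  dex <- iDD + iDA
  tot <- dex + iAA
  e <- ifelse(dex > 0, iDA / dex, NA_real_)
  s <- ifelse(tot > 0, dex / tot, NA_real_)
  data.frame(e = e, s = s)
}

#' Detect single-molecule bursts in an ALEX photon stream
#'
#' Fixed-bin burst search: photons are binned at `binTime` (default the
#' 0.6 ms acquisition bin) and contiguous runs of bins with at least
#' `countThreshold` photons form one burst each. Per-burst channel counts
#' are classified by (excitation phase, detection channel); bursts whose
#' total photon count falls below `minPhotons` are discarded.
#'
#' @param stream a [PhotonStream-class].
#' @param binTime bin width in seconds (> 0).
#' @param countThreshold minimum photons per bin to call a bin "on" (> 0).
#' @param minPhotons minimum total photons for a retained burst.
#' @return a [BurstSet-class] with E and S computed per burst.
#' @export
detectBursts <- function(stream, binTime = 6e-4, countThreshold = 30,
                         minPhotons = 30) {
  stopifnot(is(stream, "PhotonStream"))
  if (binTime <= 0) stop("binTime must be > 0")
  if (countThreshold <= 0) stop("countThreshold must be > 0")
  n <- length(stream@timestamps)
  if (n == 0) return(new("BurstSet"))
  binIdx <- floor(stream@timestamps / binTime)
  counts <- table(binIdx)
  hot <- as.numeric(names(counts))[counts >= countThreshold]
  if (length(hot) == 0) return(new("BurstSet"))
  hot <- sort(hot)
  runStart <- c(TRUE, diff(hot) > 1)
  runId <- cumsum(runStart)
  rows <- lapply(split(hot, runId), function(bins) {
    t0 <- min(bins) * binTime
    t1 <- (max(bins) + 1) * binTime
    sel <- stream@timestamps >= t0 & stream@timestamps < t1
    ph <- stream@excitationPhase[sel]
    ch <- stream@detectionChannel[sel]
    iDD <- sum(ph == "donor_exc" & ch == "donor_em")
    iDA <- sum(ph == "donor_exc" & ch == "acceptor_em")
    iAA <- sum(ph == "acceptor_exc" & ch == "acceptor_em")
    data.frame(tStart = t0, tEnd = t1, iDD = iDD, iDA = iDA, iAA = iAA)
  })
  b <- do.call(rbind, rows)
  b <- b[b$iDD + b$iDA + b$iAA >= minPhotons, , drop = FALSE]
  rownames(b) <- NULL
  es <- computeES(b$iDD, b$iDA, b$iAA)
  b$e <- es$e
  b$s <- es$s
  new("BurstSet", bursts = b)
}

#' Select doubly labeled molecules by stoichiometry
#'
#' Retains bursts whose stoichiometry lies strictly inside
#' (`sMin`, `sMax`) — the standard ALEX gate (default 0.25 < S < 0.75) that
#' keeps molecules carrying both an active donor and an active acceptor and
#' rejects donor-only (S ~ 1) and acceptor-only (S ~ 0) contaminants.
#' Order is preserved; the operation is idempotent.
#'
#' @param x a [BurstSet-class].
#' @param sMin,sMax gate bounds, `sMin < sMax`.
#' @return the gated [BurstSet-class].
#' @export
selectFretSpecies <- function(x, sMin = 0.25, sMax = 0.75) {
  stopifnot(is(x, "BurstSet"))
  if (sMin >= sMax) stop("sMin must be < sMax")
  b <- bursts(x)
  keep <- !is.na(b$s) & b$s > sMin & b$s < sMax
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("BurstSet", bursts = out)
}

# Build the sum-of-Gaussians model formula and start list for k components.
.gaussSumFormula <- function(k) {
  terms <- vapply(seq_len(k), function(i)
    sprintf("a%d * exp(-(x - m%d)^2 / (2 * s%d^2))", i, i, i), character(1))
  stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
}

#' Decompose a 1D FRET histogram into Gaussian components
#'
#' Bins the E values at `binWidth` (default 0.02 E units) and least-squares
#' fits a sum of `nComponents` Gaussians to the binned counts — the same
#' operation as fitting the 1D FRET histograms above an E-S plot. Component
#' areas are returned in burst units (integral of the component divided by
#' the bin width), so they can be used directly as the \eqn{A_i} of a
#' binding-fraction computation.
#'
#' @param eValues numeric FRET efficiencies (needs at least
#'   `10 * nComponents` points).
#' @param nComponents number of Gaussian components (>= 1).
#' @param binWidth histogram bin width in E units.
#' @param initMeans optional numeric vector of starting means (recycled to
#'   `nComponents`); when absent, k-means centers of `eValues` are used.
#' @param method `"histogram"` (default, least squares on binned counts) or
#'   `"mixture"` (Gaussian-mixture maximum likelihood via \pkg{mclust}, as an
#'   independent cross-check; requires \pkg{mclust}).
#' @return data.frame with one row per component, columns `mean`, `sd`,
#'   `area`, sorted by `mean`.
#' @seealso [bindingFraction()]
#' @export
fitFretHistogram <- function(eValues, nComponents, binWidth = 0.02,
                             initMeans = NULL, method = c("histogram", "mixture")) {
  method <- match.arg(method)
  eValues <- eValues[!is.na(eValues)]
  if (nComponents < 1) stop("nComponents must be >= 1")
  if (length(eValues) < 10 * nComponents)
    stop("need at least 10 points per component")
  if (stats::sd(eValues) < 1e-12) {
    # degenerate: all values identical; sd pinned at its lower bound
    return(data.frame(mean = eValues[1], sd = binWidth / 2,
                      area = length(eValues)))
  }
  if (method == "mixture") {
    if (!requireNamespace("mclust", quietly = TRUE))
      stop("method = 'mixture' requires the mclust package")
    # Mclust evaluates an internal mclustBIC() call in this frame, so the
    # function must be visible here even without attaching mclust
    mclustBIC <- mclust::mclustBIC
    fit <- mclust::Mclust(eValues, G = nComponents, modelNames = "V",
                          verbose = FALSE)
    out <- data.frame(mean = as.numeric(fit$parameters$mean),
                      sd = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
                      area = as.numeric(fit$parameters$pro) * length(eValues))
    return(out[order(out$mean), , drop = FALSE])
  }

  lo <- min(0, floor(min(eValues) / binWidth) * binWidth)
  hi <- max(1, ceiling(max(eValues) / binWidth) * binWidth)
  breaks <- seq(lo, hi + binWidth / 2, by = binWidth)
  h <- graphics::hist(eValues, breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$counts

  if (is.null(initMeans)) {
    if (nComponents == 1) {
      initMeans <- mean(eValues)
    } else {
      km <- stats::kmeans(eValues, centers = nComponents, nstart = 5)
      initMeans <- sort(as.numeric(km$centers))
    }
  } else {
    initMeans <- sort(rep_len(as.numeric(initMeans), nComponents))
  }
  start <- list()
  lower <- upper <- numeric(0)
  for (i in seq_len(nComponents)) {
    aInit <- max(y[which.min(abs(x - initMeans[i]))], 1)
    start[[paste0("a", i)]] <- aInit
    start[[paste0("m", i)]] <- initMeans[i]
    start[[paste0("s", i)]] <- max(0.05, binWidth)
    lower <- c(lower, 0, lo, binWidth / 2)
    upper <- c(upper, Inf, hi, (hi - lo))
  }
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(.gaussSumFormula(nComponents), data = dat,
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Gaussian histogram fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  out <- data.frame(
    mean = cf[paste0("m", seq_len(nComponents))],
    sd = abs(cf[paste0("s", seq_len(nComponents))]),
    area = cf[paste0("a", seq_len(nComponents))] *
      abs(cf[paste0("s", seq_len(nComponents))]) * sqrt(2 * pi) / binWidth
  )
  rownames(out) <- NULL
  out[order(out$mean), , drop = FALSE]
}

#' Bound fraction from fitted histogram components
#'
#' \eqn{\theta = A_{bound} / (A_{bound} + A_{free})}, where the A's are the
#' areas of the bound-complex and free-ssDNA components of a FRET-histogram
#' decomposition.
#'
#' @param components data.frame from [fitFretHistogram()].
#' @param boundIndex,freeIndex row indices of the bound and free components.
#' @return the bound fraction in [0, 1].
#' @export
bindingFraction <- function(components, boundIndex, freeIndex) {
  stopifnot(boundIndex <= nrow(components), freeIndex <= nrow(components))
  aB <- components$area[boundIndex]
  aF <- components$area[freeIndex]
  if (aB + aF <= 0) stop("both component areas are zero")
  aB / (aB + aF)
}

#' Fit a Hill binding isotherm to a titration curve
#'
#' Nonlinear least squares of \eqn{\theta(C) = C^n / (K_d^n + C^n)} to the
#' observed bound fractions, weighted by the per-point burst counts when
#' available. The dissociation constant equals the half-saturation point of
#' the fitted curve by construction; `params$halfSaturationTheta` reports the
#' consistency check \eqn{\theta(K_d) = 0.5}.
#'
#' @param curve a [TitrationCurve-class] with at least 4 points spanning the
#'   transition.
#' @param fixHillN fix the Hill coefficient to this value (e.g. 1); `NULL`
#'   (default) fits it freely.
#' @return a [RateFit-class]: `rate` = Kd (concentration units of the
#'   curve), `uncertainty` = its standard error, `params` with `hillN` and
#'   the half-saturation check; the flag `"extrapolated_kd"` is set when the
#'   observed curve never crosses 0.5.
#' @export
fitKd <- function(curve, fixHillN = NULL) {
  stopifnot(is(curve, "TitrationCurve"))
  C <- concentrations(curve)
  th <- boundFraction(curve)
  ok <- !is.na(th)
  C <- C[ok]; th <- th[ok]
  if (length(C) < 4) stop("need at least 4 titration points")
  w <- burstCounts(curve)[ok]
  if (all(w == 0)) w <- rep(1, length(C))
  flags <- character(0)
  if (max(th) < 0.5) flags <- c(flags, "extrapolated_kd")
  # start Kd where the observed curve crosses 0.5 (or the mid concentration)
  kd0 <- tryCatch(stats::approx(th, C, xout = 0.5, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(C[C > 0])
  dat <- data.frame(C = C, th = th)
  if (is.null(fixHillN)) {
    fit <- minpack.lm::nlsLM(th ~ C^n / (kd^n + C^n), data = dat,
                             start = list(kd = kd0, n = 1),
                             lower = c(kd = 1e-12 * kd0, n = 0.1),
                             upper = c(kd = Inf, n = 10),
                             weights = w,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    n <- stats::coef(fit)[["n"]]
    nSe <- summary(fit)$coefficients["n", "Std. Error"]
  } else {
    n <- fixHillN
    fit <- minpack.lm::nlsLM(th ~ C^n / (kd^n + C^n), data = dat,
                             start = list(kd = kd0),
                             lower = c(kd = 1e-12 * kd0), weights = w,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    nSe <- NA_real_
  }
  kd <- stats::coef(fit)[["kd"]]
  kdSe <- summary(fit)$coefficients["kd", "Std. Error"]
  new("RateFit", rate = kd, uncertainty = kdSe, model = "hill",
      params = list(hillN = n, hillNSe = nSe,
                    halfSaturationTheta = kd^n / (kd^n + kd^n)),
      flags = flags)
}

#' Species fractions versus time from timestamped bursts
#'
#' Bins selected bursts by start time and, within each bin, counts the
#' fraction whose FRET efficiency falls in each species window (free ssDNA,
#' SSB-bound, RecO-bound). Bursts outside all windows are excluded from the
#' denominator. Empty bins get `NA` fractions and are flagged by a zero
#' count.
#'
#' @param x a [BurstSet-class] (already stoichiometry-gated).
#' @param speciesWindows named list of `c(lo, hi)` E intervals with names
#'   `free`, `ssb_bound`, `reco_bound`; windows must be disjoint.
#' @param binWidth time-bin width, seconds.
#' @return a [KineticSeries-class].
#' @seealso [fitExchangeRate()]
#' @export
fractionsVsTime <- function(x, speciesWindows, binWidth) {
  stopifnot(is(x, "BurstSet"), binWidth > 0)
  need <- c("free", "ssb_bound", "reco_bound")
  if (!all(need %in% names(speciesWindows)))
    stop("speciesWindows must be named free, ssb_bound, reco_bound")
  wins <- speciesWindows[need]
  iv <- do.call(rbind, wins)
  ord <- order(iv[, 1])
  if (any(iv[ord, 1][-1] < iv[ord, 2][-length(ord)]))
    stop("species windows must be disjoint")
  b <- bursts(x)
  binIdx <- floor(b$tStart / binWidth)
  allBins <- seq(min(binIdx), max(binIdx))
  centers <- (allBins + 0.5) * binWidth
  frac <- matrix(NA_real_, nrow = length(allBins), ncol = 3,
                 dimnames = list(NULL, need))
  counts <- integer(length(allBins))
  for (j in seq_along(allBins)) {
    e <- b$e[binIdx == allBins[j]]
    inWin <- vapply(need, function(sp)
      sum(e >= wins[[sp]][1] & e <= wins[[sp]][2], na.rm = TRUE), numeric(1))
    tot <- sum(inWin)
    counts[j] <- as.integer(tot)
    if (tot > 0) frac[j, ] <- inWin / tot
  }
  new("KineticSeries", binCenters = centers, fractions = frac,
      counts = counts, groundTruth = list())
}

#' Fit the exchange rate of an SSB-to-RecO population time course
#'
#' Least-squares fit of the single-exponential relaxation
#' \eqn{f_{ssb}(t) = f_\infty + (f_0 - f_\infty) e^{-k t}} to the SSB-bound
#' fraction of a kinetic series — the standard two-state exchange model under
#' excess competing ligand. The plateau \eqn{f_\infty} is free by default and
#' can be fixed (e.g. to 0 for complete exchange).
#'
#' @param series a [KineticSeries-class] with at least 5 usable bins.
#' @param fixPlateau fix \eqn{f_\infty} to this value; `NULL` fits it freely.
#' @return a [RateFit-class]: `rate` = k (1/s), `params` with `f0`, `fInf`
#'   and the fitted half-completion time `halfLife = log(2)/k`. A flat
#'   series returns rate ~ 0 with the `"no_exchange"` flag; a series rising
#'   beyond noise gets `"non_monotone"`.
#' @export
fitExchangeRate <- function(series, fixPlateau = NULL) {
  stopifnot(is(series, "KineticSeries"))
  t <- binCenters(series)
  f <- fractions(series)[, "ssb_bound"]
  ok <- !is.na(f)
  t <- t[ok]; f <- f[ok]
  if (length(t) < 5) stop("need at least 5 bins")
  w <- burstCounts(series)[ok]
  hasCounts <- any(w > 0)
  if (!hasCounts) w <- rep(1, length(t))
  flags <- character(0)
  span <- max(f) - min(f)
  # binomial sampling scale of the per-bin fractions; 0 for noiseless input
  noiseScale <- if (hasCounts)
    sqrt(mean(pmax(f * (1 - f), 0)) / mean(w)) else 0
  if (span <= max(3 * noiseScale, 1e-9)) {
    return(new("RateFit", rate = 0, uncertainty = NA_real_,
               model = "single_exponential",
               params = list(f0 = mean(f), fInf = mean(f), halfLife = Inf),
               flags = "no_exchange"))
  }
  if (f[length(f)] > f[1] + 3 * noiseScale) flags <- c(flags, "non_monotone")
  k0 <- log(2) / (max(t) / 2)
  dat <- data.frame(t = t, f = f)
  if (is.null(fixPlateau)) {
    fit <- minpack.lm::nlsLM(f ~ fInf + (f0 - fInf) * exp(-k * t), data = dat,
                             start = list(f0 = f[1], fInf = f[length(f)], k = k0),
                             lower = c(f0 = 0, fInf = 0, k = 0),
                             upper = c(f0 = 1, fInf = 1, k = Inf),
                             weights = w,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    fInf <- fixPlateau
    fit <- minpack.lm::nlsLM(f ~ fInf + (f0 - fInf) * exp(-k * t), data = dat,
                             start = list(f0 = f[1], k = k0),
                             lower = c(f0 = 0, k = 0),
                             upper = c(f0 = 1, k = Inf), weights = w,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  k <- cf[["k"]]
  kSe <- summary(fit)$coefficients["k", "Std. Error"]
  fInfHat <- if (is.null(fixPlateau)) cf[["fInf"]] else fixPlateau
  # a noisy flat series can pass the range pre-screen yet fit a spurious
  # slow decay; require the relaxation amplitude to be significant
  if (hasCounts) {
    amp <- cf[["f0"]] - fInfHat
    ampSe <- tryCatch({
      v <- stats::vcov(fit)
      if (is.null(fixPlateau))
        sqrt(v["f0", "f0"] + v["fInf", "fInf"] - 2 * v["f0", "fInf"])
      else sqrt(v["f0", "f0"])
    }, error = function(e) 0)
    if (is.finite(ampSe) && abs(amp) <= 2 * ampSe) {
      return(new("RateFit", rate = 0, uncertainty = NA_real_,
                 model = "single_exponential",
                 params = list(f0 = mean(f), fInf = mean(f), halfLife = Inf),
                 flags = "no_exchange"))
    }
  }
  new("RateFit", rate = k, uncertainty = kSe, model = "single_exponential",
      params = list(f0 = cf[["f0"]], fInf = fInfHat,
                    halfLife = if (k > 0) log(2) / k else Inf),
      flags = flags)
}
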