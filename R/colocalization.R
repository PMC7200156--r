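#' Detect fluorescent spots in a single-channel image
#'
#' Local-maximum detection above `background + thresholdSigma * noise`
#' (background and noise estimated robustly as the image median and MAD),
#' followed by sub-pixel centroid refinement over a
#' `(2 * ceiling(2 * psfSigma) + 1)^2` window. Maxima closer than
#' `2 * psfSigma` are deduplicated; the brighter spot wins.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param thresholdSigma detection threshold in noise units (default 5).
#' @param psfSigma expected spot width in pixels (> 0).
#' @return data.frame with `x`, `y` (0-based pixel-center coordinates) and
#'   `intensity` (background-subtracted window sum), ordered by intensity.
#' @export
detectSpots <- function(image, thresholdSigma = 5, psfSigma = 1.2) {
  stopifnot(is.matrix(image))
  if (psfSigma <= 0) stop("psfSigma must be > 0")
  bg <- stats::median(image)
  noise <- stats::mad(image)
  if (noise == 0) noise <- sqrt(max(bg, 1))  # Poisson-limited floor
  thr <- bg + thresholdSigma * noise
  nr <- nrow(image); nc <- ncol(image)
  w <- ceiling(2 * psfSigma)
  cand <- which(image > thr, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  # keep only local maxima over a 3x3 neighborhood
  isMax <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1, r - 1):min(nr, r + 1)
    cc <- max(1, c - 1):min(nc, c + 1)
    image[r, c] >= max(image[rr, cc])
  }, logical(1))
  cand <- cand[isMax, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  spots <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1, r - w):min(nr, r + w)
    cc <- max(1, c - w):min(nc, c + w)
    win <- image[rr, cc, drop = FALSE] - bg
    win[win < 0] <- 0
    tot <- sum(win)
    if (tot <= 0) return(NULL)
    # centroid in 0-based pixel-center coordinates
    y <- sum((rr - 1) * rowSums(win)) / tot
    x <- sum((cc - 1) * colSums(win)) / tot
    data.frame(x = x, y = y, intensity = tot)
  })
  spots <- do.call(rbind, spots)
  spots <- spots[order(-spots$intensity), , drop = FALSE]
  # minimum separation 2 * psfSigma; brighter spot wins
  keep <- rep(TRUE, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (!keep[i]) next
    if (i < nrow(spots)) {
      later <- (i + 1):nrow(spots)
      d <- sqrt((spots$x[later] - spots$x[i])^2 + (spots$y[later] - spots$y[i])^2)
      keep[later][d < 2 * psfSigma] <- FALSE
    }
  }
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair spots across two channels
#'
#' Greedy one-to-one nearest-neighbor matching after applying the rigid
#' channel registration `offset` to channel B: the closest remaining (a, b)
#' pair is accepted while its distance is within `radius`.
#'
#' @param spotsA,spotsB data.frames with `x`, `y` columns (see
#'   [detectSpots()]).
#' @param offset numeric length-2 pixel shift mapping channel B onto A
#'   (`bAligned = b - offset`).
#' @param radius matching radius in pixels (> 0).
#' @return list with `pairs` (data.frame `a`, `b`, `distance`: row indices
#'   into the inputs) and `unmatchedA`, `unmatchedB` (integer indices).
#' @export
pairChannels <- function(spotsA, spotsB, offset = c(0, 0), radius = 2) {
  if (radius <= 0) stop("radius must be > 0")
  nA <- nrow(spotsA); nB <- nrow(spotsB)
  pairs <- data.frame(a = integer(0), b = integer(0), distance = numeric(0))
  if (nA > 0 && nB > 0) {
    bx <- spotsB$x - offset[1]
    by <- spotsB$y - offset[2]
    d <- sqrt(outer(spotsA$x, bx, `-`)^2 + outer(spotsA$y, by, `-`)^2)
    freeA <- rep(TRUE, nA); freeB <- rep(TRUE, nB)
    repeat {
      d2 <- d
      d2[!freeA, ] <- Inf
      d2[, !freeB] <- Inf
      m <- which.min(d2)
      if (length(m) == 0 || d2[m] > radius) break
      ia <- (m - 1) %% nA + 1
      ib <- (m - 1) %/% nA + 1
      pairs <- rbind(pairs, data.frame(a = ia, b = ib, distance = d2[m]))
      freeA[ia] <- FALSE; freeB[ib] <- FALSE
      if (!any(freeA) || !any(freeB)) break
    }
  }
  list(pairs = pairs,
       unmatchedA = setdiff(seq_len(nA), pairs$a),
       unmatchedB = setdiff(seq_len(nB), pairs$b))
}

#' Colocalized fraction over time
#'
#' Fraction of pairs with both partners present at each frame, and at the
#' evaluation time (default 4.5 min after treatment). When presence loss is
#' irreversible (bleaching/dissociation only) the curve is monotone
#' non-increasing.
#'
#' @param presenceA,presenceB logical matrices, frames x pairs.
#' @param time frame times in seconds.
#' @param evalTime evaluation time in seconds (default 270 s = 4.5 min).
#' @param controlFraction optional no-treatment colocalized fraction at the
#'   same evaluation time; supplies the bleaching correction.
#' @return a [ColocResult-class].
#' @seealso [bleachingCorrectedFraction()]
#' @export
colocFraction <- function(presenceA, presenceB, time, evalTime = 270,
                          controlFraction = NA_real_) {
  stopifnot(is.matrix(presenceA), is.matrix(presenceB),
            all(dim(presenceA) == dim(presenceB)),
            nrow(presenceA) == length(time))
  if (ncol(presenceA) == 0) stop("no pairs")
  both <- presenceA & presenceB
  frac <- rowMeans(both)
  iEval <- which.min(abs(time - evalTime))
  fEval <- frac[iEval]
  corrected <- if (!is.na(controlFraction))
    bleachingCorrectedFraction(fEval, controlFraction) else NA_real_
  new("ColocResult", nPairs = ncol(presenceA), time = as.numeric(time),
      fraction = frac, evalTime = evalTime, fractionAtEval = fEval,
      controlFraction = controlFraction, correctedFraction = corrected)
}

#' Photobleaching-corrected colocalized fraction
#'
#' Divides the observed colocalized fraction by the no-treatment control
#' fraction measured at the same time, removing the acceptor-photobleaching
#' contribution (independent exponential losses factorize, so the ratio
#' depends on the treatment-induced dissociation only). Clipped to [0, 1].
#'
#' @param observed observed colocalized fraction.
#' @param control no-treatment colocalized fraction (> 0).
#' @return corrected fraction in [0, 1].
#' @export
bleachingCorrectedFraction <- function(observed, control) {
  stopifnot(observed >= 0, observed <= 1, control <= 1)
  if (control <= 0) stop("control fraction must be > 0")
  min(max(observed / control, 0), 1)
}

#' Track spot presence through an image stack
#'
#' Image-mode presence: a spot is present in a frame when [detectSpots()]
#' finds a spot within `radius` of its reference position.
#'
#' @param images list of per-frame image matrices (one channel).
#' @param refPositions n x 2 matrix of reference (x, y) positions.
#' @param radius presence radius in pixels.
#' @param thresholdSigma,psfSigma passed to [detectSpots()].
#' @return logical matrix, frames x spots.
#' @export
trackPresence <- function(images, refPositions, radius = 2,
                          thresholdSigma = 5, psfSigma = 1.2) {
  refPositions <- as.matrix(refPositions)
  out <- matrix(FALSE, nrow = length(images), ncol = nrow(refPositions))
  for (f in seq_along(images)) {
    sp <- detectSpots(images[[f]], thresholdSigma, psfSigma)
    if (nrow(sp) == 0) next
    for (i in seq_len(nrow(refPositions))) {
      d <- sqrt((sp$x - refPositions[i, 1])^2 + (sp$y - refPositions[i, 2])^2)
      out[f, i] <- any(d <= radius)
    }
  }
  out
}
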