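# Render one frame: expected photons from Gaussian PSF spots plus flat
# background, then Poisson noise. positions is an n x 2 matrix (x, y) in
# 0-based pixel-center coordinates; rows of the image are y, columns x.
.renderFrame <- function(positions, present, shape, psfSigma, spotPhotons,
                         background) {
  lambda <- matrix(background, nrow = shape[1], ncol = shape[2])
  if (any(present)) {
    xs <- 0:(shape[2] - 1)
    ys <- 0:(shape[1] - 1)
    for (i in which(present)) {
      dx <- stats::dnorm(xs, positions[i, 1], psfSigma)
      dy <- stats::dnorm(ys, positions[i, 2], psfSigma)
      lambda <- lambda + spotPhotons * outer(dy, dx)
    }
  }
  matrix(stats::rpois(length(lambda), lambda), nrow = shape[1])
}

#' Simulate a two-color colocalization experiment
#'
#' Each pair represents a surface-tethered donor-labeled ssDNA (channel A)
#' colocalized at time zero with an acceptor-labeled protein (channel B).
#' The acceptor partner disappears at the first of two competing exponential
#' events: acceptor photobleaching (rate `acceptorBleachRate`) and protein
#' dissociation (rate `dissociationRate`). In image mode, per-frame
#' two-channel images are rendered with Gaussian PSF spots at fixed random
#' positions (channel B rigidly shifted by `channelOffset`) and Poisson
#' photon noise.
#'
#' @param config a [ColocSimConfig-class].
#' @param seed RNG seed.
#' @return a list with elements
#'   \describe{
#'     \item{time}{frame times, seconds}
#'     \item{presenceA,presenceB}{logical matrices, frames x pairs}
#'     \item{truth}{data.frame with per-pair `bleachTime`, `dissocTime`,
#'       `endTime`, `cause`}
#'     \item{positionsA,positionsB}{pair positions (image mode only)}
#'     \item{imagesA,imagesB}{lists of per-frame integer matrices (image
#'       mode only)}
#'   }
#' @seealso [colocFraction()], [detectSpots()], [pairChannels()]
#' @export
simulateColoc <- function(config, seed = NULL) {
  stopifnot(is(config, "ColocSimConfig"))
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config@nPairs
  time <- seq(0, config@duration, by = config@frameInterval)
  bleach <- if (config@acceptorBleachRate > 0)
    stats::rexp(n, config@acceptorBleachRate) else rep(Inf, n)
  dissoc <- if (config@dissociationRate > 0)
    stats::rexp(n, config@dissociationRate) else rep(Inf, n)
  endTime <- pmin(bleach, dissoc)
  cause <- ifelse(is.infinite(endTime), "none",
                  ifelse(bleach <= dissoc, "bleach", "dissociation"))
  presenceA <- matrix(TRUE, nrow = length(time), ncol = n)
  presenceB <- outer(time, endTime, `<`)
  out <- list(time = time, presenceA = presenceA, presenceB = presenceB,
              truth = data.frame(bleachTime = bleach, dissocTime = dissoc,
                                 endTime = endTime, cause = cause))
  if (config@imageMode) {
    shape <- config@imageShape
    margin <- 4 * config@psfSigma
    posA <- cbind(stats::runif(n, margin, shape[2] - 1 - margin),
                  stats::runif(n, margin, shape[1] - 1 - margin))
    posB <- sweep(posA, 2, config@channelOffset, `+`)
    out$positionsA <- posA
    out$positionsB <- posB
    out$imagesA <- lapply(seq_along(time), function(f)
      .renderFrame(posA, presenceA[f, ], shape, config@psfSigma,
                   config@spotPhotons, config@background))
    out$imagesB <- lapply(seq_along(time), function(f)
      .renderFrame(posB, presenceB[f, ], shape, config@psfSigma,
                   config@spotPhotons, config@background))
  }
  out
}
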