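# Shared synthetic fixtures, built in code at test time.

# The three diffusing-species mixture (free ssDNA, SSB-bound, RecO-bound)
# plus a donor-only contaminant, as seen in the ALEX E-S measurements.
threeSpeciesMixture <- function(donorOnlyFraction = 0.3) {
  f <- (1 - donorOnlyFraction) / 3
  rbind(speciesSpec("free",       0.09, 0.07, 0.50, 0.07, f),
        speciesSpec("ssb_bound",  0.58, 0.07, 0.50, 0.07, f),
        speciesSpec("reco_bound", 0.78, 0.07, 0.50, 0.07, f),
        speciesSpec("donor_only", 0.05, 0.05, 0.95, 0.03, donorOnlyFraction))
}

# A constant-state FretTrace with symmetric Gaussian channel noise.
constantTrace <- function(e, nFrames = 3000, total = 1000, noiseSd = 0,
                          frameInterval = 0.1, injectionTime = NA_real_) {
  time <- (seq_len(nFrames) - 1) * frameInterval
  a <- total * e + stats::rnorm(nFrames, 0, noiseSd)
  d <- total * (1 - e) + stats::rnorm(nFrames, 0, noiseSd)
  new("FretTrace", time = time, donor = d, acceptor = a,
      frameInterval = frameInterval, injectionTime = injectionTime,
      metadata = list(), stateTruth = character(0))
}

# A noiseless piecewise-constant FretTrace from (E value, n frames) steps.
stepTrace <- function(eLevels, lengths, total = 1000, frameInterval = 0.1,
                      injectionTime = NA_real_) {
  e <- rep(eLevels, lengths)
  n <- length(e)
  new("FretTrace", time = (seq_len(n) - 1) * frameInterval,
      donor = total * (1 - e), acceptor = total * e,
      frameInterval = frameInterval, injectionTime = injectionTime,
      metadata = list(), stateTruth = character(0))
}

# Segment a trace with the default three levels.
segmentDefault <- function(trace, halfWidth = 0.12, minDwell = 3) {
  segmentStates(computeTraceFret(trace),
                levelCenters = c(LOW = 0.2, MID = 0.6, HIGH = 0.8),
                halfWidth = halfWidth, minDwellFrames = minDwell,
                frameInterval = frameInterval(trace))
}
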