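## Shared fixtures for the test suite.  All data are built in code.

## Dipolar reference rates for tau_c = 10 ps, B0 = 9.4 T, r = 158 pm,
## evaluated independently with 30-digit arithmetic (mpmath) from the
## BPP spectral-density formulas; frozen here as the oracle.
REF_R1 <- 0.547958104712525
REF_R2 <- 0.548685263969439

## Relaxation-free single-pool system (pure rotations).
rotationOnlySystem <- function() {
  spinSystem(r1A = 0, r2A = 0, pA = 0)
}

## Single-pool water system with the default dipolar rates.
waterSystem <- function() twoPoolSystem(0)

## Net rotation matrix of a packet on an isolated spin (no relaxation).
netRotation <- function(packet) {
  sys <- rotationOnlySystem()
  sapply(1:3, function(i) {
    m <- rep(0, 6)
    m[3 + i] <- 1
    utils::tail(propagate(sys, packet, mInit = m), 1)[, 5:7]
  })
}

## Rotation angle (deg) of a 3x3 rotation matrix.
rotationAngleDeg <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

## Forward model of the dual +Z/-Z steady-state decay (Eq. of the fit).
dualDecayForward <- function(times, si0, r, ss) {
  E <- exp(-r * times)
  list(plus = si0 * E + ss * si0 * (1 - E),
       minus = -si0 * E + ss * si0 * (1 - E))
}

## Small phantom spec for fast map tests.
smallPhantomSpec <- function(noiseSd = 0, seed = 0L) {
  phantomSpec(grid = 48L, noiseSd = noiseSd, seed = seed)
}
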