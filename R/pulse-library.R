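#' @include AllClasses.R AllGenerics.R
NULL

## Internal waveform representation used during construction: a list with
## amp (Hz, >= 0), phiXY (rad, discrete transmitter-phase offsets including
## sign flips of the modulation), fm (rad/s, frequency modulation) and dt.
## The public Packet stores amp, fm and the *total* phase
## phase(t) = integral(fm) + phiXY, which is the exact phase-modulated
## equivalent of an amplitude/frequency-modulated pulse in the frame
## rotating at the carrier.

.wave <- function(amp, phiXY, fm, dt) {
  list(amp = amp, phiXY = phiXY, fm = fm, dt = dt)
}

## Midpoint-consistent running integral of the frequency modulation:
## phase accumulated up to the midpoint of sample i.
.fmPhase <- function(fm, dt) {
  if (!length(fm)) return(numeric(0))
  dt * (cumsum(fm) - fm / 2)
}

.waveToPacket <- function(w, peakHz, label) {
  new("Packet",
      amplitude = w$amp,
      phase     = .fmPhase(w$fm, w$dt) + w$phiXY,
      fm        = w$fm,
      dt        = w$dt,
      peakHz    = peakHz,
      label     = label)
}

.checkPositive <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L ||
        !is.finite(vals[[nm]]) || vals[[nm]] <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  invisible(TRUE)
}

## Default nominal peak RF amplitude (Hz) per RAFFn rank.  The rank-1 and
## rank-2 pulses use the base power; higher ranks use geometrically
## decreasing peaks spanning the published 625-245 Hz range.  Overridable
## through raffSpec()/rankPeakHz().

#' Default nominal peak power per RAFFn rank
#'
#' Nominal peak RF amplitudes used for RAFFn pulses of rank 1-5 when none
#' is given explicitly. Ranks 1-2 use the base 625 Hz; ranks 3-5 decrease
#' geometrically to 245 Hz at equal packet duration.
#'
#' @param rank Integer rank in 1..5.
#' @param base Base peak amplitude (Hz) for ranks 1-2.
#' @param top Peak amplitude (Hz) at rank 5.
#' @return Peak amplitude in Hz.
#' @export
rankPeakHz <- function(rank, base = 625, top = 245) {
  if (!rank %in% 1:5) stop("rank must be an integer in 1..5", call. = FALSE)
  ratio <- (top / base)^(1 / 3)
  peaks <- c(base, base, base * ratio, base * ratio^2, top)
  peaks[rank]
}

## ---- RaffSpec -----------------------------------------------------------

#' RAFFn pulse specification
#'
#' @slot rank Integer frame rank n in 1..5.
#' @slot tl Stretching factor of the packet (dimensionless).
#' @slot peakHz Nominal peak RF amplitude (Hz).
#' @slot samplesPerPacket Number of waveform samples of the tl = 1 packet.
#' @slot refPeakHz Base peak amplitude (Hz) defining the common packet
#'   duration (that of the rank-2, tl = 1 packet).
#'
#' @export
setClass("RaffSpec",
  representation(rank = "integer", tl = "numeric", peakHz = "numeric",
                 samplesPerPacket = "integer", refPeakHz = "numeric",
                 tlPowerScaling = "logical")
)

setValidity("RaffSpec", function(object) {
  msg <- character(0)
  if (!object@rank %in% 1:5) msg <- c(msg, "rank must be in 1..5")
  if (object@tl <= 0) msg <- c(msg, "tl must be positive")
  if (object@peakHz <= 0 || object@refPeakHz <= 0)
    msg <- c(msg, "peak powers must be positive")
  if (object@samplesPerPacket < 16L || object@samplesPerPacket %% 4L != 0L)
    msg <- c(msg, "samplesPerPacket must be >= 16 and divisible by 4")
  if (length(msg)) msg else TRUE
})

#' Create a RAFFn pulse specification
#'
#' @param rank Frame rank n (1-5).
#' @param tl Stretching factor; 1 is the original packet, values below 1
#'   compress and above 1 stretch the refocusing period.
#' @param peakHz Nominal peak RF amplitude in Hz; defaults to
#'   [rankPeakHz()] for the chosen rank.
#' @param samplesPerPacket Samples of the tl = 1 packet (default 128); the
#'   actual packet carries `round(samplesPerPacket * tl)` samples.
#' @param refPeakHz Base peak amplitude fixing the common packet duration.
#' @param tlPowerScaling When `TRUE` (default) the per-TL nominal peak power
#'   is `peakHz / tl`, which stretches the packet in time while preserving
#'   the 45-degree fictitious-field geometry and the 2-pi-per-element
#'   rotary-echo refocusing at every stretching factor. `FALSE` keeps the
#'   peak power fixed at `peakHz` and only slows the modulation functions
#'   (shape-invariant trajectory, but the composite packet then refocuses
#'   exactly only at tl = 1).
#' @return A [RaffSpec-class] object.
#' @examples
#' raffSpec(2, tl = 1.0)
#' @export
raffSpec <- function(rank, tl = 1.0, peakHz = rankPeakHz(rank),
                     samplesPerPacket = 128L, refPeakHz = 625,
                     tlPowerScaling = TRUE) {
  new("RaffSpec", rank = as.integer(rank), tl = as.numeric(tl),
      peakHz = as.numeric(peakHz),
      samplesPerPacket = as.integer(samplesPerPacket),
      refPeakHz = as.numeric(refPeakHz),
      tlPowerScaling = isTRUE(tlPowerScaling))
}

setMethod("show", "RaffSpec", function(object) {
  cat(sprintf("RaffSpec: rank %d, TL %.2f, peak %.0f Hz, %d samples/packet\n",
              object@rank, object@tl, object@peakHz, object@samplesPerPacket))
})

## ---- element functions --------------------------------------------------

## Duration of one element (quarter packet).  omega1max is the *nominal*
## peak amplitude in rad/s; the 4 pi / (2 * omega1max_eff) refocusing
## relation with the rank-2 effective field sqrt(2) * omega1max gives
## 2 * pi / (sqrt(2) * omega1max) per element, i.e. 1.13125 ms at 625 Hz.
.elementDuration <- function(peakHz, tl) {
  tl * 2 * pi / (sqrt(2) * 2 * pi * peakHz)
}

## Per-TL nominal peak power.  With scaling (default), the TL packet is the
## tl = 1 packet of a pulse at peak/tl: stretched in time by tl with the
## fictitious-field geometry and per-element refocusing intact.  Without
## scaling, the modulation argument is slowed to w1max*t/tl at fixed peak.
.effectivePeakTl <- function(peakHz, tl, scaling) {
  if (scaling) list(peakHz = peakHz / tl, tl = 1.0)
  else list(peakHz = peakHz, tl = tl)
}

## Evaluate the rank-n base element at local times tau in [0, Tel).
## Returns signed transverse field components (rad/s) and fm (rad/s).
.raffElementField <- function(rank, peakHz, tl, tau) {
  w1max <- 2 * pi * peakHz
  if (rank == 1L) {
    ## constant effective field tilted 45 deg: omega1 = delta = w1max/sqrt(2)
    n <- length(tau)
    return(list(fx = rep(w1max / sqrt(2), n), fy = rep(0, n),
                fz = rep(w1max / sqrt(2), n)))
  }
  if (rank == 2L) {
    arg <- w1max * tau / tl
    return(list(fx = w1max * sin(arg), fy = rep(0, length(tau)),
                fz = w1max * cos(arg)))
  }
  ## Ranks 3-5: numeric frame composition.  The top (rank n-1) frame field
  ## sweeps sub-adiabatically as A * (sin, 0, cos)(ws * tau); each step down
  ## adds the fictitious field ws * y-hat generated by the frame rotation
  ## and rotates by the accumulated tilt about y.  The result is rescaled so
  ## the first-frame peak amplitude equals the requested nominal peak.
  A  <- w1max
  ws <- w1max / tl
  th <- ws * tau
  fx <- A * sin(th); fy <- rep(0, length(tau)); fz <- A * cos(th)
  for (k in seq_len(rank - 2L)) {
    fy <- fy + ws
    cx <- cos(th); sx <- sin(th)
    fx2 <- fx * cx + fz * sx
    fz2 <- -fx * sx + fz * cx
    fx <- fx2; fz <- fz2
  }
  amp <- sqrt(fx^2 + fy^2)
  s <- w1max / max(amp)
  list(fx = s * fx, fy = s * fy, fz = s * fz)
}

## Signed field -> (amp >= 0, phiXY, fm)
.fieldToWave <- function(f, dt) {
  amp <- sqrt(f$fx^2 + f$fy^2)
  phi <- atan2(f$fy, f$fx)
  .wave(amp / (2 * pi), phi, f$fz, dt)
}

#' Base element of the RAFF2 pulse
#'
#' The single sub-adiabatic element P of the RAFF2 packet: amplitude
#' \eqn{\omega_1(t) = \omega_1^{max}\sin(\omega_1^{max} t/TL)} and frequency
#' modulation \eqn{\Delta\omega(t) = \omega_1^{max}\cos(\omega_1^{max} t/TL)}
#' with \eqn{\omega_1^{max} = 2\pi \cdot} `peakHz`, over the element duration
#' \eqn{TL \cdot 2\pi/(\sqrt{2}\,\omega_1^{max})} (1.13125 ms at 625 Hz,
#' TL = 1). The instantaneous effective field
#' \eqn{(\omega_1, 0, \Delta\omega)} has constant magnitude
#' \eqn{\omega_1^{max}}; in the second rotating frame the total field is
#' \eqn{\sqrt{1 + 1/TL^2}\,\omega_1^{max}}, i.e. the 45-degree fictitious
#' field geometry at TL = 1.
#'
#' @param peakHz Nominal peak RF amplitude (Hz) of the tl = 1 element.
#' @param tl Stretching factor (> 0).
#' @param nSamples Number of waveform samples (>= 4).
#' @param tlPowerScaling Scale the per-TL peak power as `peakHz / tl`
#'   (refocusing-preserving stretch, the default); see [raffSpec()].
#' @return A [Packet-class].
#' @examples
#' p <- raff2Element(625, tl = 1.0, nSamples = 32)
#' duration(p) * 1e3  # 1.13125 ms
#' @export
raff2Element <- function(peakHz, tl = 1.0, nSamples = 32L,
                         tlPowerScaling = TRUE) {
  .checkPositive(peakHz = peakHz, tl = tl)
  nSamples <- as.integer(nSamples)
  if (nSamples < 4L) stop("nSamples must be >= 4", call. = FALSE)
  Tel <- .elementDuration(peakHz, tl)
  dt <- Tel / nSamples
  tau <- (seq_len(nSamples) - 0.5) * dt
  eff <- .effectivePeakTl(peakHz, tl, tlPowerScaling)
  f <- .raffElementField(2L, eff$peakHz, eff$tl, tau)
  w <- .fieldToWave(f, dt)
  ## fold negative-lobe sign flips into the transmitter phase
  .waveToPacket(w, eff$peakHz, sprintf("raff2-element TL%.2f", tl))
}

## Assemble the composite P, P(pi)^-1, P(pi), P^-1 packet from an element
## waveform sampled on a single uniform grid spanning the four elements.
## elemFun(tau) must return the signed field at local element times tau.
.assemblePacket <- function(elemFun, Tel, nTotal, peakHz, label) {
  dt <- 4 * Tel / nTotal
  t <- (seq_len(nTotal) - 0.5) * dt
  elem <- pmin(floor(t / Tel), 3)            # element index 0..3
  tau <- t - elem * Tel
  reversed <- elem %in% c(1, 3)              # P(pi)^-1 and P^-1
  piShift  <- elem %in% c(1, 2)              # P(pi)^-1 and P(pi)
  tauEff <- ifelse(reversed, Tel - tau, tau)
  f <- elemFun(tauEff)
  ## time reversal with negated frequency modulation
  f$fz[reversed] <- -f$fz[reversed]
  amp <- sqrt(f$fx^2 + f$fy^2) / (2 * pi)
  phiXY <- atan2(f$fy, f$fx) + ifelse(piShift, pi, 0)
  new("Packet",
      amplitude = amp,
      phase     = .fmPhase(f$fz, dt) + phiXY,
      fm        = f$fz,
      dt        = dt,
      peakHz    = peakHz,
      label     = label)
}

#' RAFF2 composite packet
#'
#' Builds the four-element composite refocusing packet
#' \eqn{P\,P_\pi^{-1}\,P_\pi\,P^{-1}} from the base element: the second and
#' fourth elements are time-reversed with negated frequency modulation, and
#' the middle two carry a \eqn{\pi} transmitter-phase shift. The packet
#' carries `round(samplesPerPacket * tl)` samples rounded to a multiple of 4
#' so all four elements share one symmetric sample grid (128 at TL = 1), and
#' lasts
#' `tl` times 4.525 ms at the 625 Hz nominal peak.
#'
#' @param spec A [RaffSpec-class] with `rank = 2` (see [raffSpec()]).
#' @return A [Packet-class].
#' @examples
#' pk <- raff2Packet(raffSpec(2, tl = 1.0))
#' duration(pk) * 1e3  # 4.525 ms
#' nSamples(pk)        # 128
#' @export
raff2Packet <- function(spec) {
  stopifnot(is(spec, "RaffSpec"))
  validObject(spec)
  if (spec@rank != 2L)
    stop("spec rank must be 2; use raffnPacket() for other ranks",
         call. = FALSE)
  Tel <- .elementDuration(spec@peakHz, spec@tl)
  eff <- .effectivePeakTl(spec@peakHz, spec@tl, spec@tlPowerScaling)
  nTotal <- 4L * max(1L, as.integer(round(spec@samplesPerPacket * spec@tl / 4)))
  .assemblePacket(
    function(tau) .raffElementField(2L, eff$peakHz, eff$tl, tau),
    Tel, nTotal, eff$peakHz,
    sprintf("raff2 TL%.2f", spec@tl))
}

#' RAFFn composite packet (ranks 1-5)
#'
#' Rank 1 is a constant-amplitude off-resonance element with
#' \eqn{\omega_1 = \Delta\omega = \omega_1^{max}/\sqrt{2}} (45-degree
#' effective field); rank 2 delegates to [raff2Packet()]; ranks 3-5 are
#' produced by a recursive frame construction in which the rank-(n-1)
#' effective-field trajectory is sine/cosine modulated in the rank-(n-1)
#' rotating frame and transformed back to first-frame amplitude and phase
#' by composing the frame rotations sample by sample. All ranks share the
#' packet duration of the rank-2 packet at the reference peak power, and
#' the nominal peak amplitude decreases with rank (see [rankPeakHz()]).
#'
#' @param spec A [RaffSpec-class] (see [raffSpec()]).
#' @return A [Packet-class].
#' @examples
#' pk5 <- raffnPacket(raffSpec(5))
#' max(amplitude(pk5)) < 625
#' @export
raffnPacket <- function(spec) {
  stopifnot(is(spec, "RaffSpec"))
  validObject(spec)
  if (spec@rank == 2L) return(raff2Packet(spec))
  ## common duration: that of the rank-2 packet at the reference peak
  Tel <- .elementDuration(spec@refPeakHz, spec@tl)
  eff <- .effectivePeakTl(spec@peakHz, spec@tl, spec@tlPowerScaling)
  nTotal <- 4L * max(1L, as.integer(round(spec@samplesPerPacket * spec@tl / 4)))
  .assemblePacket(
    function(tau) .raffElementField(spec@rank, eff$peakHz, eff$tl, tau),
    Tel, nTotal, eff$peakHz,
    sprintf("raff%d TL%.2f", spec@rank, spec@tl))
}

## ---- trains -------------------------------------------------------------

#' Assemble a pulse train from a packet
#'
#' A "pulse" in the train count convention is half a four-element packet
#' (two elements), so 32 pulses of the TL = 1 RAFF2 packet irradiate for
#' 32 x 2.2625 ms = 72.4 ms. Weighting k applies the packet waveform up to
#' the sample reaching `nPulses[k]` half-packets.
#'
#' @param packet A [Packet-class].
#' @param nPulses Integer vector of pulse counts, non-negative, strictly
#'   ascending, starting at 0.
#' @return A [PulseTrain-class].
#' @examples
#' tr <- buildTrain(raff2Packet(raffSpec(2)), c(0, 8, 16, 24, 32))
#' prepDurations(tr) * 1e3
#' @export
buildTrain <- function(packet, nPulses) {
  stopifnot(is(packet, "Packet"))
  nPulses <- as.integer(nPulses)
  if (any(nPulses < 0L)) stop("pulse counts must be non-negative",
                              call. = FALSE)
  if (nPulses[1L] != 0L || (length(nPulses) > 1L && any(diff(nPulses) <= 0L)))
    stop("pulse counts must start at 0 and increase strictly", call. = FALSE)
  N <- nSamples(packet)
  if (N < 2L && max(nPulses) > 0L)
    stop("packet has too few samples to form a train", call. = FALSE)
  nHalf1 <- as.integer(ceiling(N / 2))       # first half-packet
  nHalf2 <- N - nHalf1                       # second half-packet
  cumS <- vapply(nPulses, function(k) {
    as.integer((k %/% 2L) * N + ifelse(k %% 2L == 1L, nHalf1, 0L))
  }, integer(1))
  new("PulseTrain", packet = packet, nPulses = nPulses,
      cumDurations = cumS * packet@dt, cumSamples = cumS)
}

## ---- comparison preparations -------------------------------------------

.sechBeta <- function(trunc = 0.01) acosh(1 / trunc)

## Hyperbolic-secant amplitude and tanh-integral frequency sweep on a
## midpoint grid; order 1 gives the classic HS1, order n flattens the
## amplitude plateau (HSn).
.hsField <- function(order, durationS, peakHz, R, nSamples, halfPassage = FALSE) {
  beta <- .sechBeta()
  dt <- durationS / nSamples
  if (halfPassage) {
    tau <- -1 + (seq_len(nSamples) - 0.5) / nSamples   # [-1, 0): sweep in
  } else {
    tau <- -1 + (2 * (seq_len(nSamples) - 0.5)) / nSamples
  }
  amp <- peakHz / cosh(beta * tau^order)
  ## frequency sweep proportional to the running integral of sech^2
  grid <- seq(-1, 1, length.out = 4096L)
  g <- 1 / cosh(beta * grid^order)^2
  Fg <- cumsum(c(0, (g[-1] + g[-length(g)]) / 2 * diff(grid)))
  Fg <- Fg - Fg[which.min(abs(grid))]        # F(0) = 0, odd in tau
  Ffun <- stats::approxfun(grid, Fg)
  bw <- R / durationS                        # full sweep bandwidth (Hz)
  fm <- 2 * pi * (bw / 2) * Ffun(tau) / Ffun(1)
  list(amp = amp, fm = fm, dt = dt)
}

#' Hyperbolic-secant adiabatic pulse (HS1/HS4)
#'
#' Amplitude \eqn{\omega_1(t) = \omega_1^{max}\,\mathrm{sech}(\beta\tau^n)}
#' with \eqn{\tau \in [-1, 1]} and truncation
#' \eqn{\mathrm{sech}(\beta) = 0.01}; the frequency sweep follows the
#' running integral of \eqn{\mathrm{sech}^2}, scaled so the total sweep
#' bandwidth times the duration equals the adiabaticity factor `R`.
#'
#' @param order Pulse order n, 1 or 4.
#' @param durationS Pulse duration (s).
#' @param peakHz Peak RF amplitude (Hz).
#' @param R Adiabaticity (bandwidth-duration) factor.
#' @param nSamples Number of waveform samples.
#' @return A [Packet-class].
#' @examples
#' hs <- hsPulse(1, 4525e-6, 2500, 20)
#' max(amplitude(hs))
#' @export
hsPulse <- function(order, durationS, peakHz, R = 20, nSamples = 256L) {
  if (!order %in% c(1, 4))
    stop("order must be 1 or 4", call. = FALSE)
  .checkPositive(durationS = durationS, peakHz = peakHz, R = R)
  h <- .hsField(order, durationS, peakHz, R, as.integer(nSamples))
  .waveToPacket(.wave(h$amp, rep(0, length(h$amp)), h$fm, h$dt), peakHz,
                sprintf("hs%d", order))
}

#' Continuous-wave spin-lock pulse
#'
#' Constant-amplitude on-resonance irradiation.
#'
#' @param powerHz RF amplitude (Hz).
#' @param durationS Duration (s); 0 gives an empty packet.
#' @param nSamples Number of samples (default resolves to <= 0.5 ms/sample).
#' @return A [Packet-class].
#' @export
cwSpinlock <- function(powerHz, durationS,
                       nSamples = max(1L, ceiling(durationS / 5e-4))) {
  .checkPositive(powerHz = powerHz)
  if (durationS < 0) stop("durationS must be non-negative", call. = FALSE)
  if (durationS == 0)
    return(new("Packet", dt = 1e-6, peakHz = powerHz, label = "cw"))
  n <- as.integer(nSamples)
  z <- rep(0, n)
  .waveToPacket(.wave(rep(powerHz, n), z, z, durationS / n), powerHz, "cw")
}

#' Adiabatic half-passage pulse
#'
#' The first half of an HS1 sweep, ending on-resonance at full amplitude;
#' rotates longitudinal magnetization into the transverse plane. With
#' `reverse = TRUE` the exact inverse (time-reversed, field negated)
#' pulse is returned, which restores magnetization to the z axis.
#'
#' @param durationS Duration (s).
#' @param peakHz Peak RF amplitude (Hz).
#' @param R Adiabaticity factor of the underlying full passage.
#' @param reverse Return the inverse (restoring) variant.
#' @param nSamples Number of samples.
#' @return A [Packet-class].
#' @examples
#' ah <- ahpPulse(4000e-6, 2500)
#' tail(amplitude(ah), 1)  # ends at full amplitude
#' @export
ahpPulse <- function(durationS, peakHz, R = 20, reverse = FALSE,
                     nSamples = 256L) {
  .checkPositive(durationS = durationS, peakHz = peakHz, R = R)
  h <- .hsField(1, durationS, peakHz, R, as.integer(nSamples),
                halfPassage = TRUE)
  amp <- h$amp; fm <- h$fm; phi <- rep(0, length(amp))
  if (reverse) {
    ## exact inverse: time-reversed, field negated (pi transmitter shift,
    ## negated sweep) plus the forward sweep's net FM phase as a global
    ## offset so the sample-wise fields are exactly the negated originals
    amp <- rev(amp)
    phi <- phi + pi + sum(fm) * h$dt
    fm <- -rev(fm)
  }
  .waveToPacket(.wave(amp, phi, fm, h$dt), peakHz,
                if (reverse) "ahp-reverse" else "ahp")
}

#' Hard pulse
#'
#' Constant amplitude, zero phase, zero frequency offset; used for B1
#' nutation mapping.
#'
#' @param powerHz RF amplitude (Hz).
#' @param durationS Duration (s); 0 gives an empty packet.
#' @param nSamples Number of samples.
#' @return A [Packet-class].
#' @export
hardPulse <- function(powerHz, durationS, nSamples = 16L) {
  .checkPositive(powerHz = powerHz)
  if (durationS < 0) stop("durationS must be non-negative", call. = FALSE)
  if (durationS == 0)
    return(new("Packet", dt = 1e-6, peakHz = powerHz, label = "hard"))
  n <- as.integer(nSamples)
  z <- rep(0, n)
  .waveToPacket(.wave(rep(powerHz, n), z, z, durationS / n), powerHz, "hard")
}

## ---- shape file I/O -----------------------------------------------------

#' Write a packet to a two-column shape file
#'
#' Plain-text shaped-pulse format: `#`-prefixed header lines carrying the
#' sample interval, the label and the nominal peak, followed by one line
#' per sample with amplitude (Hz) and phase (degrees).
#'
#' @param packet A [Packet-class].
#' @param path Output file path.
#' @param dialect Only `"two_column_text"` is supported.
#' @return `path`, invisibly.
#' @seealso [readShape()]
#' @export
writeShape <- function(packet, path, dialect = "two_column_text") {
  stopifnot(is(packet, "Packet"))
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dt_us=%.10g", packet@dt * 1e6),
    sprintf("# label=%s", packet@label),
    sprintf("# peak_hz=%.10g", packet@peakHz)
  ), con)
  if (nSamples(packet) > 0)
    writeLines(sprintf("%.10g %.10g", packet@amplitude,
                       packet@phase * 180 / pi), con)
  invisible(path)
}

#' Read a packet from a shape file
#'
#' Inverse of [writeShape()]. The frequency-modulation slot is
#' reconstructed from finite differences of the phase and is therefore
#' approximate near discrete phase jumps.
#'
#' @param path Shape file path.
#' @return A [Packet-class].
#' @export
readShape <- function(path) {
  if (!file.exists(path)) stop("shape file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getHdr <- function(key, default = "") {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) return(default)
    sub(paste0("^# ", key, "="), "", m[1L])
  }
  dt <- as.numeric(getHdr("dt_us", "1")) * 1e-6
  lab <- getHdr("label")
  peak <- as.numeric(getHdr("peak_hz", "0"))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    return(new("Packet", dt = dt, peakHz = peak, label = lab))
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  amp <- m[, 1L]
  phase <- m[, 2L] * pi / 180
  fm <- if (length(phase) > 1L) {
    c(diff(phase) / dt, (phase[length(phase)] - phase[length(phase) - 1L]) / dt)
  } else 0
  new("Packet", amplitude = amp, phase = phase, fm = fm, dt = dt,
      peakHz = max(peak, max(amp)), label = lab)
}
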