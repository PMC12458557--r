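#' Sampled RF waveform packet
#'
#' A `Packet` holds one sampled radiofrequency irradiation element or
#' composite packet: amplitude in Hz, total transmitter phase in radians
#' (the running integral of the frequency-modulation function plus discrete
#' phase offsets), and the frequency-modulation function itself in rad/s,
#' on a uniform time grid of spacing `dt`.
#'
#' @slot amplitude Numeric vector, RF amplitude samples (Hz, non-negative).
#' @slot phase Numeric vector, total RF phase samples (rad).
#' @slot fm Numeric vector, frequency modulation \eqn{\Delta\omega(t)} (rad/s).
#' @slot dt Sample spacing (s).
#' @slot peakHz Nominal peak RF amplitude (Hz) the waveform was designed for.
#' @slot label Free-text identifier.
#'
#' @export
setClass("Packet",
  representation(
    amplitude = "numeric",
    phase     = "numeric",
    fm        = "numeric",
    dt        = "numeric",
    peakHz    = "numeric",
    label     = "character"
  ),
  prototype(amplitude = numeric(0), phase = numeric(0), fm = numeric(0),
            dt = 1e-6, peakHz = 0, label = "")
)

setValidity("Packet", function(object) {
  msg <- character(0)
  n <- length(object@amplitude)
  if (length(object@phase) != n)
    msg <- c(msg, "amplitude and phase must have equal length")
  if (length(object@fm) != n)
    msg <- c(msg, "amplitude and fm must have equal length")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (n > 0 && any(object@amplitude < -1e-9))
    msg <- c(msg, "amplitude must be non-negative")
  if (n > 0 && length(object@peakHz) == 1L && object@peakHz > 0 &&
      max(object@amplitude) > object@peakHz * (1 + 1e-9))
    msg <- c(msg, "amplitude exceeds nominal peak power")
  if (length(msg)) msg else TRUE
})

#' Pulse train of repeated packets
#'
#' A `PulseTrain` applies one refocusing packet repeatedly. Following the
#' acquisition convention for these preparations, one "pulse" is half a
#' four-element packet (two elements), so a weighting with pulse count
#' \eqn{k} irradiates for \eqn{k \times} (packet duration)/2. The
#' cumulative preparation durations are the time axis of the relaxation fit.
#'
#' @slot packet The repeated [Packet-class].
#' @slot nPulses Integer vector of pulse counts per weighting (ascending,
#'   starting at 0; pulse = half packet).
#' @slot cumDurations Numeric vector of cumulative preparation durations (s).
#' @slot cumSamples Integer vector of cumulative waveform sample counts.
#'
#' @export
setClass("PulseTrain",
  representation(
    packet       = "Packet",
    nPulses      = "integer",
    cumDurations = "numeric",
    cumSamples   = "integer"
  )
)

setValidity("PulseTrain", function(object) {
  msg <- character(0)
  k <- length(object@nPulses)
  if (k < 1L) msg <- c(msg, "train needs at least one weighting")
  if (length(object@cumDurations) != k || length(object@cumSamples) != k)
    msg <- c(msg, "nPulses, cumDurations and cumSamples lengths must match")
  if (k >= 1L && object@nPulses[1L] != 0L)
    msg <- c(msg, "pulse counts must start at 0")
  if (k > 1L && any(diff(object@nPulses) <= 0L))
    msg <- c(msg, "pulse counts must be strictly increasing")
  if (k >= 1L && abs(object@cumDurations[1L]) > 1e-15)
    msg <- c(msg, "first cumulative duration must be 0")
  if (length(msg)) msg else TRUE
})

#' Two-pool spin system
#'
#' Physical parameters of a two-pool Bloch-McConnell system. Pool A is the
#' dilute (solute, e.g. protein -OH) pool, pool B the abundant water pool;
#' `pA = 0` reduces the model to plain single-pool Bloch dynamics.
#' Exchange rates obey detailed balance: `kAB = kEx * pB`, `kBA = kEx * pA`,
#' so `kAB * pA == kBA * pB`.
#'
#' @slot r1A,r2A Longitudinal/transverse relaxation rates of pool A (1/s).
#' @slot r1B,r2B Longitudinal/transverse relaxation rates of pool B (1/s).
#' @slot pA,pB Equilibrium pool fractions (sum to 1).
#' @slot deltaA,deltaB Pool off-resonance frequencies (rad/s).
#' @slot kEx Total exchange rate constant (1/s) partitioned by fractions.
#' @slot b0 Static field (T).
#'
#' @export
setClass("SpinSystem",
  representation(
    r1A = "numeric", r2A = "numeric",
    r1B = "numeric", r2B = "numeric",
    pA = "numeric", pB = "numeric",
    deltaA = "numeric", deltaB = "numeric",
    kEx = "numeric", b0 = "numeric"
  )
)

setValidity("SpinSystem", function(object) {
  msg <- character(0)
  rates <- c(object@r1A, object@r2A, object@r1B, object@r2B, object@kEx)
  if (any(!is.finite(rates)) || any(rates < 0))
    msg <- c(msg, "relaxation and exchange rates must be finite and >= 0")
  if (object@pA < 0 || object@pA > 1)
    msg <- c(msg, "pA must lie in [0, 1]")
  if (abs(object@pA + object@pB - 1) > 1e-12)
    msg <- c(msg, "pool fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Paired +Z / -Z signal decay curves
#'
#' Signal versus preparation duration for the two-acquisition protocol:
#' one acquisition starts with magnetization along +z, the second along -z.
#' Signals are the total longitudinal magnetization (summed over pools) at
#' the end of the preparation, so `siMinus` starts near \eqn{-M_0}.
#'
#' @slot times Preparation durations (s), starting at 0.
#' @slot siPlus,siMinus Signal samples for the +Z and -Z starts.
#'
#' @export
setClass("DecayCurve",
  representation(times = "numeric", siPlus = "numeric", siMinus = "numeric")
)

setValidity("DecayCurve", function(object) {
  msg <- character(0)
  n <- length(object@times)
  if (length(object@siPlus) != n || length(object@siMinus) != n)
    msg <- c(msg, "times, siPlus and siMinus must have equal length")
  if (n > 0 && abs(object@times[1L]) > 1e-15)
    msg <- c(msg, "times must start at 0")
  if (n > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Pixelwise relaxation maps
#'
#' Images of the fitted relaxation time constant T = 1/R (seconds), the
#' steady-state fraction SS, and the coefficient of determination, together
#' with the analysis mask. Non-converged pixels and pixels outside the mask
#' carry `NA` and are excluded from all downstream regional statistics.
#'
#' @slot tMap Matrix, relaxation time constant (s).
#' @slot ssMap Matrix, steady-state fraction.
#' @slot rsqMap Matrix, goodness of fit.
#' @slot mask Logical matrix.
#'
#' @export
setClass("RegionMaps",
  representation(tMap = "matrix", ssMap = "matrix", rsqMap = "matrix",
                 mask = "matrix")
)

setValidity("RegionMaps", function(object) {
  msg <- character(0)
  d <- dim(object@tMap)
  if (!identical(dim(object@ssMap), d) || !identical(dim(object@rsqMap), d) ||
      !identical(dim(object@mask), d))
    msg <- c(msg, "all maps and the mask must share dimensions")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (any(is.finite(object@tMap[!object@mask])))
    msg <- c(msg, "values outside the mask must be NA")
  if (length(msg)) msg else TRUE
})

#' Region-of-interest set
#'
#' Binary masks for the infarct (MI) sector, the remote myocardium and the
#' whole myocardium, drawn once (on one reference map) and propagated by
#' pixel index to every other method's map.
#'
#' @slot miMask,remoteMask,wholeMask Logical matrices of equal size.
#' @slot sourceMethod Label of the map the ROIs were drawn on.
#'
#' @export
setClass("RoiSet",
  representation(miMask = "matrix", remoteMask = "matrix",
                 wholeMask = "matrix", sourceMethod = "character")
)

setValidity("RoiSet", function(object) {
  msg <- character(0)
  d <- dim(object@miMask)
  if (!identical(dim(object@remoteMask), d) ||
      !identical(dim(object@wholeMask), d))
    msg <- c(msg, "all masks must share dimensions")
  if (any(object@miMask & object@remoteMask))
    msg <- c(msg, "MI and remote masks must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Synthetic cardiac phantom dataset
#'
#' A digital short-axis heart phantom: an annular myocardium with an
#' infarct sector and a remote sector, a blood-pool cavity and signal-free
#' background, plus (optionally) forward-simulated weighted image series
#' and the ground-truth region parameters used to generate them.
#'
#' @slot labelMap Integer matrix of region ids (0 background, 1 cavity,
#'   2 remote myocardium, 3 infarct sector).
#' @slot rois The derived [RoiSet-class].
#' @slot truth Data frame of per-region ground-truth `t_ms` and `ss`.
#' @slot geometry List with center, radii and sector extent.
#' @slot seriesPlus,seriesMinus Numeric arrays `nx x ny x nt` (may be empty
#'   until [synthesizeSeries()] is called).
#' @slot times Preparation durations (s) of the series.
#' @slot seed Integer seed the phantom was generated with.
#'
#' @export
setClass("PhantomDataset",
  representation(
    labelMap = "matrix", rois = "RoiSet", truth = "data.frame",
    geometry = "list", seriesPlus = "array", seriesMinus = "array",
    times = "numeric", seed = "integer"
  )
)

## ---- show methods -------------------------------------------------------

setMethod("show", "Packet", function(object) {
  n <- length(object@amplitude)
  cat(sprintf("Packet '%s': %d samples, dt = %.3f us, duration = %.4f ms\n",
              object@label, n, object@dt * 1e6, n * object@dt * 1e3))
  if (n > 0)
    cat(sprintf("  peak amplitude %.1f Hz (nominal %.1f Hz)\n",
                max(object@amplitude), object@peakHz))
})

setMethod("show", "PulseTrain", function(object) {
  cat(sprintf("PulseTrain of '%s': %d weightings, pulses %s\n",
              object@packet@label, length(object@nPulses),
              paste(object@nPulses, collapse = ", ")))
  cat(sprintf("  preparation durations %s ms\n",
              paste(sprintf("%.2f", object@cumDurations * 1e3),
                    collapse = ", ")))
})

setMethod("show", "SpinSystem", function(object) {
  cat(sprintf("SpinSystem at %.1f T\n", object@b0))
  cat(sprintf("  pool A (solute): p = %.3g, R1 = %.4g, R2 = %.4g 1/s, delta = %.4g rad/s\n",
              object@pA, object@r1A, object@r2A, object@deltaA))
  cat(sprintf("  pool B (water) : p = %.3g, R1 = %.4g, R2 = %.4g 1/s, delta = %.4g rad/s\n",
              object@pB, object@r1B, object@r2B, object@deltaB))
  cat(sprintf("  exchange kEx = %.4g 1/s\n", object@kEx))
})

setMethod("show", "DecayCurve", function(object) {
  cat(sprintf("DecayCurve: %d weightings, t = 0 .. %.2f ms\n",
              length(object@times), max(object@times) * 1e3))
})

setMethod("show", "RegionMaps", function(object) {
  cat(sprintf("RegionMaps %d x %d, %d fitted pixels (%d converged)\n",
              nrow(object@tMap), ncol(object@tMap), sum(object@mask),
              sum(is.finite(object@tMap))))
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet (drawn on '%s'): MI %d px, remote %d px, whole %d px\n",
              object@sourceMethod, sum(object@miMask),
              sum(object@remoteMask), sum(object@wholeMask)))
})

setMethod("show", "PhantomDataset", function(object) {
  cat(sprintf("PhantomDataset %d x %d (seed %d)\n",
              nrow(object@labelMap), ncol(object@labelMap), object@seed))
  cat(sprintf("  regions: background %d, cavity %d, remote %d, MI %d px\n",
              sum(object@labelMap == 0L), sum(object@labelMap == 1L),
              sum(object@labelMap == 2L), sum(object@labelMap == 3L)))
  if (length(object@times))
    cat(sprintf("  series: %d weightings, 0 .. %.1f ms\n",
                length(object@times), max(object@times) * 1e3))
})
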