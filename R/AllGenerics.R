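#' @include AllClasses.R
NULL

#' RF amplitude samples of a packet
#'
#' @param x A [Packet-class] object.
#' @return Numeric vector of RF amplitude samples in Hz.
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' Total RF phase samples of a packet
#'
#' The stored phase is the full transmitter phase: the running integral of
#' the frequency-modulation function plus any discrete phase offsets
#' (sign flips of the amplitude modulation and the \eqn{\pi} shifts of the
#' packet elements).
#'
#' @param x A [Packet-class] object.
#' @return Numeric vector of RF phase samples in radians.
#' @export
setGeneric("rfPhase", function(x) standardGeneric("rfPhase"))

#' Frequency-modulation samples of a packet
#'
#' @param x A [Packet-class] object.
#' @return Numeric vector, frequency modulation \eqn{\Delta\omega(t)} in rad/s.
#' @export
setGeneric("freqMod", function(x) standardGeneric("freqMod"))

#' Sample spacing of a packet
#'
#' @param x A [Packet-class] or [PulseTrain-class] object.
#' @return Sample interval in seconds.
#' @export
setGeneric("sampleInterval", function(x) standardGeneric("sampleInterval"))

#' Total duration
#'
#' @param x A [Packet-class] or [PulseTrain-class] object.
#' @return Duration in seconds (for a train, the longest weighting).
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Number of waveform samples
#'
#' @param x A [Packet-class] object.
#' @return Integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Preparation durations of a pulse train
#'
#' @param x A [PulseTrain-class] object.
#' @return Numeric vector of cumulative preparation durations in seconds,
#'   one per weighting; this is the time axis used for relaxation fitting.
#' @export
setGeneric("prepDurations", function(x) standardGeneric("prepDurations"))

#' Fitted relaxation time map
#'
#' @param x A [RegionMaps-class] object.
#' @return Matrix of relaxation time constants in seconds (NA outside the
#'   mask and at non-converged pixels).
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))

#' Fitted steady-state fraction map
#'
#' @param x A [RegionMaps-class] object.
#' @return Matrix of steady-state fractions.
#' @export
setGeneric("ssMap", function(x) standardGeneric("ssMap"))

#' Goodness-of-fit map
#'
#' @param x A [RegionMaps-class] object.
#' @return Matrix of coefficients of determination.
#' @export
setGeneric("rsqMap", function(x) standardGeneric("rsqMap"))

#' Analysis mask
#'
#' @param x A [RegionMaps-class] object.
#' @return Logical matrix marking fitted pixels.
#' @export
setGeneric("fitMask", function(x) standardGeneric("fitMask"))
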