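#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn amplitude RF amplitude of a packet (Hz).
#' @export
setMethod("amplitude", "Packet", function(x) x@amplitude)

#' @describeIn rfPhase Total RF phase of a packet (rad).
#' @export
setMethod("rfPhase", "Packet", function(x) x@phase)

#' @describeIn freqMod Frequency modulation of a packet (rad/s).
#' @export
setMethod("freqMod", "Packet", function(x) x@fm)

#' @describeIn sampleInterval Sample spacing of a packet (s).
#' @export
setMethod("sampleInterval", "Packet", function(x) x@dt)

#' @describeIn sampleInterval Sample spacing of a train's packet (s).
#' @export
setMethod("sampleInterval", "PulseTrain", function(x) x@packet@dt)

#' @describeIn duration Duration of a packet (s).
#' @export
setMethod("duration", "Packet",
          function(x) length(x@amplitude) * x@dt)

#' @describeIn duration Longest preparation duration of a train (s).
#' @export
setMethod("duration", "PulseTrain", function(x) max(x@cumDurations))

#' @describeIn nSamples Sample count of a packet.
#' @export
setMethod("nSamples", "Packet", function(x) length(x@amplitude))

#' @describeIn prepDurations Cumulative preparation durations of a train (s).
#' @export
setMethod("prepDurations", "PulseTrain", function(x) x@cumDurations)

#' @describeIn tMap Relaxation time map (s).
#' @export
setMethod("tMap", "RegionMaps", function(x) x@tMap)

#' @describeIn ssMap Steady-state fraction map.
#' @export
setMethod("ssMap", "RegionMaps", function(x) x@ssMap)

#' @describeIn rsqMap Goodness-of-fit map.
#' @export
setMethod("rsqMap", "RegionMaps", function(x) x@rsqMap)

#' @describeIn fitMask Analysis mask.
#' @export
setMethod("fitMask", "RegionMaps", function(x) x@mask)
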