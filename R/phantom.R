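#' @include AllClasses.R AllGenerics.R contrast.R
NULL

#' Digital short-axis cardiac phantom specification
#'
#' Geometry and ground truth of the synthetic phantom: an annular
#' myocardium (inner/outer radius) around a blood-pool cavity, with an
#' infarct sector of given angular extent; the rest of the annulus is the
#' remote myocardium and everything outside is signal-free background
#' (mimicking a fixed mouse heart immersed in a fluorinated, proton-free
#' fluid).
#'
#' @slot grid Image matrix size in pixels (square).
#' @slot center Annulus center (pixels, x then y).
#' @slot outerR,innerR Outer and inner myocardial radii (pixels).
#' @slot sectorStartDeg,sectorWidthDeg Infarct sector start angle and
#'   angular extent (degrees).
#' @slot regionParams Data frame with columns `region` ("mi", "remote",
#'   "cavity"), `t_ms` (ground-truth relaxation time, ms) and `ss`
#'   (steady-state fraction).
#' @slot noiseSd Additive noise SD relative to the unit initial signal.
#' @slot seed Integer seed.
#'
#' @export
setClass("PhantomSpec",
  representation(grid = "integer", center = "numeric", outerR = "numeric",
                 innerR = "numeric", sectorStartDeg = "numeric",
                 sectorWidthDeg = "numeric", regionParams = "data.frame",
                 noiseSd = "numeric", seed = "integer")
)

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (object@grid < 8L) msg <- c(msg, "grid must be at least 8 pixels")
  if (object@innerR >= object@outerR)
    msg <- c(msg, "innerR must be smaller than outerR")
  if (object@outerR >= object@grid / 2)
    msg <- c(msg, "outer radius must fit inside the grid")
  if (object@sectorWidthDeg <= 0 || object@sectorWidthDeg >= 360)
    msg <- c(msg, "sector extent must lie in (0, 360) degrees")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  need <- c("mi", "remote", "cavity")
  if (!all(need %in% object@regionParams$region))
    msg <- c(msg, "regionParams must cover regions mi, remote, cavity")
  if (length(msg)) msg else TRUE
})

#' Default ground-truth region parameters
#'
#' Relaxation times and steady-state fractions prescribed per phantom
#' region. The MI/remote ratio of 59.1/50.0 encodes an 18.2% relative
#' relaxation time difference; absolute values are plausible ex vivo
#' magnitudes and are configuration, not measured claims.
#'
#' @return Data frame with columns `region`, `t_ms`, `ss`.
#' @export
defaultRegionParams <- function() {
  data.frame(
    region = c("mi", "remote", "cavity"),
    t_ms = c(59.1, 50.0, 80.0),
    ss = c(0.15, 0.10, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Create a phantom specification
#'
#' @param grid Image size in pixels (default 192, matching a 192 x 192
#'   acquisition matrix).
#' @param center Annulus center; defaults to the image center.
#' @param outerR,innerR Myocardial radii in pixels.
#' @param sectorStartDeg,sectorWidthDeg Infarct sector placement (degrees).
#' @param regionParams Ground truth, see [defaultRegionParams()].
#' @param noiseSd Noise SD relative to unit signal (0.02 is SNR 50).
#' @param seed Integer seed.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(grid = 192L, center = (grid + 1) / 2 * c(1, 1),
                        outerR = grid * 0.21, innerR = grid * 0.125,
                        sectorStartDeg = -60, sectorWidthDeg = 120,
                        regionParams = defaultRegionParams(),
                        noiseSd = 0.02, seed = 0L) {
  new("PhantomSpec", grid = as.integer(grid), center = center,
      outerR = outerR, innerR = innerR,
      sectorStartDeg = sectorStartDeg, sectorWidthDeg = sectorWidthDeg,
      regionParams = regionParams, noiseSd = noiseSd,
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d, annulus r %.1f-%.1f px, MI sector %.0f deg, noise sd %.3f\n",
    object@grid, object@grid, object@innerR, object@outerR,
    object@sectorWidthDeg, object@noiseSd))
})

#' Generate the phantom label map and ROIs
#'
#' Builds the region-id image (0 background, 1 cavity, 2 remote
#' myocardium, 3 infarct sector) and derives the ROI masks: the MI mask is
#' the infarct sector, the remote mask the rest of the annulus, and the
#' whole-myocardium mask their union. Deterministic given the spec.
#'
#' @param spec A [PhantomSpec-class].
#' @return A [PhantomDataset-class] without image series (see
#'   [synthesizeSeries()]).
#' @examples
#' ph <- makePhantom(phantomSpec(grid = 64))
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n <- spec@grid
  x <- matrix(seq_len(n), n, n) - spec@center[1L]
  y <- matrix(seq_len(n), n, n, byrow = TRUE) - spec@center[2L]
  rad <- sqrt(x^2 + y^2)
  ang <- (atan2(y, x) * 180 / pi - spec@sectorStartDeg) %% 360
  lab <- matrix(0L, n, n)
  lab[rad < spec@innerR] <- 1L
  annulus <- rad >= spec@innerR & rad <= spec@outerR
  lab[annulus] <- 2L
  lab[annulus & ang < spec@sectorWidthDeg] <- 3L
  if (sum(lab == 2L) < 8L)
    warning("remote region nearly empty: sector extent leaves ",
            sum(lab == 2L), " remote pixels")
  rois <- new("RoiSet",
              miMask = lab == 3L, remoteMask = lab == 2L,
              wholeMask = lab == 2L | lab == 3L,
              sourceMethod = "raff2_tl1.0")
  truth <- spec@regionParams
  new("PhantomDataset",
      labelMap = lab, rois = rois, truth = truth,
      geometry = list(center = spec@center, outerR = spec@outerR,
                      innerR = spec@innerR,
                      sectorStartDeg = spec@sectorStartDeg,
                      sectorWidthDeg = spec@sectorWidthDeg),
      seriesPlus = array(numeric(0), c(0, 0, 0)),
      seriesMinus = array(numeric(0), c(0, 0, 0)),
      times = numeric(0), seed = spec@seed)
}

#' Default weighting time axis
#'
#' Preparation durations of the standard five-weighting train: 0, 8, 16,
#' 24 and 32 pulses of the tl = 1 packet (half-packet duration 2.2625 ms),
#' i.e. 0 to 72.4 ms.
#'
#' @param nPulses Pulse counts.
#' @param pulseDurationS Duration of one pulse (half packet), in seconds.
#' @return Durations in seconds.
#' @export
defaultWeightingTimes <- function(nPulses = c(0, 8, 16, 24, 32),
                                  pulseDurationS = 4.525e-3 / 2) {
  nPulses * pulseDurationS
}

.runWithSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Forward-simulate weighted image series for a phantom
#'
#' Per-pixel signals follow the dual steady-state decay model: with the
#' region's T and SS, \eqn{SI_{\pm}(t) = \pm e^{-t/T} + SS (1 - e^{-t/T})}
#' (unit initial signal); background pixels carry no signal. Independent
#' Gaussian noise of standard deviation `noiseSd` (relative to the unit
#' initial signal) is added per pixel and weighting; `rician = TRUE`
#' instead stores the magnitude of the complex noisy signal, emulating
#' magnitude reconstruction.
#'
#' @param dataset A [PhantomDataset-class] from [makePhantom()].
#' @param times Preparation durations (s), see [defaultWeightingTimes()].
#' @param noiseSd Noise standard deviation; 0 for noiseless series.
#' @param seed Integer seed for the noise.
#' @param rician Store magnitude-reconstructed signals.
#' @return The dataset with `seriesPlus`, `seriesMinus` and `times` filled.
#' @export
synthesizeSeries <- function(dataset, times = defaultWeightingTimes(),
                             noiseSd = 0.02, seed = dataset@seed,
                             rician = FALSE) {
  stopifnot(is(dataset, "PhantomDataset"))
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  lab <- dataset@labelMap
  n <- nrow(lab)
  nt <- length(times)
  truth <- dataset@truth
  regionOf <- c("cavity", "remote", "mi")    # labels 1, 2, 3
  tPix <- ssPix <- matrix(0, n, n)
  for (id in 1:3) {
    row <- truth[truth$region == regionOf[id], ]
    if (!nrow(row))
      stop("missing region parameters for '", regionOf[id], "'",
           call. = FALSE)
    tPix[lab == id] <- row$t_ms[1L] / 1e3
    ssPix[lab == id] <- row$ss[1L]
  }
  sig <- lab != 0L
  plus <- minus <- array(0, c(n, n, nt))
  for (k in seq_len(nt)) {
    E <- matrix(0, n, n)
    E[sig] <- exp(-times[k] / tPix[sig])
    rec <- ssPix * (1 - E)
    plus[, , k] <- ifelse(sig, E + rec, 0)
    minus[, , k] <- ifelse(sig, -E + rec, 0)
  }
  if (noiseSd > 0 || rician) {
    .runWithSeed(seed, {
      addNoise <- function(a) {
        if (rician) {
          re <- a + array(stats::rnorm(length(a), 0, noiseSd), dim(a))
          im <- array(stats::rnorm(length(a), 0, noiseSd), dim(a))
          sqrt(re^2 + im^2)
        } else {
          a + array(stats::rnorm(length(a), 0, noiseSd), dim(a))
        }
      }
      plus <- addNoise(plus)
      minus <- addNoise(minus)
    })
  }
  dataset@seriesPlus <- plus
  dataset@seriesMinus <- minus
  dataset@times <- times
  dataset
}

#' Generate a cohort of phantom subjects
#'
#' Draws per-subject ground-truth relaxation times around the spec values:
#' a shared log-normal scale factor with coefficient of variation
#' `betweenSubjectCv` (subject-to-subject physiology, common to all
#' regions, so regional contrast is preserved) plus an independent
#' per-region log-normal jitter with coefficient of variation `regionCv`.
#' Each subject's image series is synthesized with its own derived seed.
#'
#' @param spec A [PhantomSpec-class].
#' @param nSubjects Number of subjects (>= 1).
#' @param betweenSubjectCv Shared between-subject coefficient of variation.
#' @param regionCv Independent per-region coefficient of variation.
#' @param seed Integer master seed.
#' @param times Weighting time axis passed to [synthesizeSeries()].
#' @param synthesize Also synthesize the noisy image series.
#' @return List of [PhantomDataset-class] objects.
#' @export
phantomCohort <- function(spec, nSubjects = 10L, betweenSubjectCv = 0.05,
                          regionCv = 0.005, seed = 0L,
                          times = defaultWeightingTimes(),
                          synthesize = TRUE) {
  stopifnot(is(spec, "PhantomSpec"))
  nSubjects <- as.integer(nSubjects)
  if (nSubjects < 1L) stop("nSubjects must be >= 1", call. = FALSE)
  if (betweenSubjectCv < 0 || regionCv < 0)
    stop("coefficients of variation must be >= 0", call. = FALSE)
  sigmaOf <- function(cv) sqrt(log(1 + cv^2))
  sG <- sigmaOf(betweenSubjectCv)
  sR <- sigmaOf(regionCv)
  base <- makePhantom(spec)
  .runWithSeed(seed, {
    lapply(seq_len(nSubjects), function(i) {
      scale <- exp(stats::rnorm(1, -sG^2 / 2, sG))
      jitter <- exp(stats::rnorm(nrow(base@truth), -sR^2 / 2, sR))
      d <- base
      d@truth$t_ms <- base@truth$t_ms * scale * jitter
      d@seed <- as.integer((seed + i) %% .Machine$integer.max)
      if (synthesize)
        d <- synthesizeSeries(d, times = times, noiseSd = spec@noiseSd,
                              seed = d@seed)
      d
    })
  })
}
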