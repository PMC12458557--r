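#' @include AllClasses.R AllGenerics.R
NULL

#' Relaxation fit result
#'
#' Result of a nonlinear relaxation fit: initial signal, rate constant,
#' steady-state signal and fraction, goodness of fit and convergence flag.
#' The relaxation time constant is `1 / r` seconds.
#'
#' @slot si0 Initial signal amplitude.
#' @slot r Relaxation rate constant (1/s).
#' @slot sss Steady-state signal.
#' @slot ss Steady-state fraction `sss / si0`.
#' @slot rsq Coefficient of determination.
#' @slot converged Logical convergence flag; when `FALSE` the parameter
#'   values are diagnostics only and are excluded from maps.
#'
#' @export
setClass("FitResult",
  representation(si0 = "numeric", r = "numeric", sss = "numeric",
                 ss = "numeric", rsq = "numeric", converged = "logical")
)

setValidity("FitResult", function(object) {
  msg <- character(0)
  if (isTRUE(object@converged)) {
    if (object@r < 0) msg <- c(msg, "rate must be >= 0 when converged")
    if (is.finite(object@ss) && (object@ss < -1e-9 || object@ss > 1 + 1e-9))
      msg <- c(msg, "steady-state fraction must lie in [0, 1] when converged")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: R = %.6g 1/s (T = %.4g ms), SS = %.4g, R^2 = %.6f%s\n",
    object@r, 1000 / object@r, object@ss, object@rsq,
    if (object@converged) "" else "  [NOT CONVERGED]"))
})

.fitResult <- function(si0, r, sss, rsq, converged) {
  new("FitResult", si0 = si0, r = r, sss = sss,
      ss = if (abs(si0) > 0) sss / abs(si0) else NA_real_,
      rsq = rsq, converged = converged)
}

.rsq <- function(obs, fitted) {
  sst <- sum((obs - mean(obs))^2)
  if (sst <= 0) return(1)
  1 - sum((obs - fitted)^2) / sst
}

## Deterministic starting rate from a log-linear fit of the decaying part
## of |si| (offset-corrected by the late-time level).
.rateStart <- function(times, si, offset = 0) {
  y <- abs(si - offset)
  ok <- y > max(y) * 1e-6 & times >= 0
  if (sum(ok) < 2) return(1)
  co <- stats::coef(stats::lm(log(y[ok]) ~ times[ok]))
  max(1e-3, -co[[2L]])
}

#' Fit the dual +Z/-Z steady-state decay model
#'
#' Simultaneously fits both acquisitions of the paired protocol with the
#' shared-parameter model
#' \deqn{SI_{\pm}(t) = \pm SI_0\, e^{-R t} + S_{SS} (1 - e^{-R t}),}
#' i.e. exponential decay with recovery toward a common steady state
#' \eqn{S_{SS}}, by least squares over the concatenated curves. The
#' steady-state fraction is \eqn{SS = S_{SS}/SI_0}. By default the two
#' initial amplitudes are tied to a common magnitude `|SI0|`; with
#' `tieSi0 = FALSE` each curve gets its own initial amplitude.
#'
#' `siMinus` is the raw signed signal of the inverted acquisition (starting
#' near \eqn{-SI_0}). Magnitude-valued input for the -Z curve is accepted:
#' if no negative values are present the sign is restored ahead of the
#' zero crossing predicted by an initial fit.
#'
#' @param times Preparation durations (s), at least 3 including 0.
#' @param siPlus Signal of the +Z acquisition.
#' @param siMinus Signal of the -Z acquisition (signed or magnitude).
#' @param tieSi0 Tie the two initial amplitudes to one magnitude.
#' @return A [FitResult-class].
#' @examples
#' t <- seq(0, 0.144, length.out = 9)
#' si <- exp(-10 * t); ss <- 0.3 * (1 - exp(-10 * t))
#' fitDualDecay(t, si + ss, -si + ss)
#' @export
fitDualDecay <- function(times, siPlus, siMinus, tieSi0 = TRUE) {
  n <- length(times)
  if (n < 3L) stop("need at least 3 time points", call. = FALSE)
  if (length(siPlus) != n || length(siMinus) != n)
    stop("times and signals must have equal length", call. = FALSE)
  if (min(times) > 1e-12)
    stop("times must include 0", call. = FALSE)
  if (any(!is.finite(c(siPlus, siMinus))))
    stop("signals must be finite", call. = FALSE)
  ord <- order(times)
  times <- times[ord]; siPlus <- siPlus[ord]; siMinus <- siMinus[ord]
  if (max(abs(c(siPlus, siMinus))) <= 0)
    return(.fitResult(0, NA_real_, NA_real_, NA_real_, FALSE))

  si00 <- max(abs(siPlus[1L]), 1e-12)
  model <- function(p) {
    E <- exp(-p[["r"]] * times)
    if (tieSi0) {
      c(p[["si0"]] * E + p[["sss"]] * (1 - E),
        -p[["si0"]] * E + p[["sss"]] * (1 - E))
    } else {
      c(p[["si0"]] * E + p[["sss"]] * (1 - E),
        p[["si0m"]] * E + p[["sss"]] * (1 - E))
    }
  }
  fitOnce <- function(siMinusSigned) {
    sss0 <- max(0, mean(tail((siPlus + siMinusSigned) / 2,
                             max(2L, n %/% 3L))))
    r0 <- .rateStart(times, siPlus, offset = min(sss0, siPlus[1L] * 0.9))
    start <- if (tieSi0) c(si0 = si00, r = r0, sss = sss0)
             else c(si0 = si00, si0m = siMinusSigned[1L], r = r0, sss = sss0)
    lower <- if (tieSi0) c(0, 0, 0) else c(0, -Inf, 0, 0)
    upper <- if (tieSi0) c(Inf, 1e4, Inf) else c(Inf, Inf, 1e4, Inf)
    start <- pmin(pmax(start, lower), upper)
    obs <- c(siPlus, siMinusSigned)
    tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = function(p) obs - model(p),
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
      error = function(e) NULL)
  }

  magnitudeInput <- all(siMinus >= 0) && any(siPlus > 0) && any(siMinus > 0)
  if (magnitudeInput) {
    ## Magnitude -Z data: restore signs ahead of the zero crossing, then
    ## iterate restoration against the fitted crossing until stable.
    signs <- rep(-1, n)
    fit <- NULL
    for (iter in 1:4) {
      fit <- fitOnce(signs * siMinus)
      if (is.null(fit)) break
      p <- fit$par
      tZero <- if (p[["sss"]] > 1e-12 && p[["r"]] > 0)
        log((p[["si0"]] + p[["sss"]]) / p[["sss"]]) / p[["r"]] else Inf
      newSigns <- ifelse(times < tZero, -1, 1)
      if (identical(newSigns, signs)) break
      signs <- newSigns
    }
    siMinus <- signs * siMinus
  } else {
    fit <- fitOnce(siMinus)
  }
  if (is.null(fit))
    return(.fitResult(si00, NA_real_, NA_real_, NA_real_, FALSE))
  p <- fit$par
  conv <- fit$info %in% 1:4
  si0 <- p[["si0"]]
  sss <- min(p[["sss"]], si0)          # ss bounded to [0, 1]
  .fitResult(si0, p[["r"]], sss, .rsq(c(siPlus, siMinus), model(p)), conv)
}

#' Fit a monoexponential decay
#'
#' Fits \eqn{SI(t) = SI_0 e^{-R t}} by least squares; used for the
#' spin-lock, adiabatic and free-precession preparations whose maps are
#' computed without steady-state formation. Steady-state fields of the
#' result are zero.
#'
#' @param times Durations (s), at least 3 points.
#' @param si Signal samples.
#' @return A [FitResult-class]; `converged = FALSE` when the signal carries
#'   no decaying component (e.g. non-positive noise-only input).
#' @examples
#' t <- c(0, 18, 36, 54) * 1e-3
#' fitMonoexp(t, exp(-t / 0.040))
#' @export
fitMonoexp <- function(times, si) {
  n <- length(times)
  if (n < 3L) stop("need at least 3 time points", call. = FALSE)
  if (length(si) != n) stop("times and si must have equal length",
                            call. = FALSE)
  if (max(si) <= 0)
    return(.fitResult(max(si, 0), NA_real_, 0, NA_real_, FALSE))
  r0 <- .rateStart(times, si)
  start <- c(si0 = max(si), r = r0)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = c(0, 0), upper = c(Inf, 1e4),
                       fn = function(p) si - p[["si0"]] * exp(-p[["r"]] * times),
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(.fitResult(max(si), NA_real_, 0, NA_real_, FALSE))
  p <- fit$par
  fitted <- p[["si0"]] * exp(-p[["r"]] * times)
  .fitResult(p[["si0"]], p[["r"]], 0, .rsq(si, fitted), fit$info %in% 1:4)
}

#' Fit a B1 nutation curve
#'
#' Fits \eqn{|SI| = |SI_0 \cos(2\pi b_1 t)|} to hard-pulse nutation data
#' acquired on a uniform duration grid, returning the B1 amplitude in Hz.
#' A coarse grid search over candidate frequencies seeds a nonlinear
#' refinement, which keeps the fit deterministic.
#'
#' @param durations Pulse durations (s), at least 5 on a uniform grid.
#' @param si Magnitude signal samples.
#' @param bMax Largest B1 candidate considered (Hz).
#' @return Fitted B1 in Hz.
#' @examples
#' d <- seq(0, 1e-3, by = 0.125e-3)
#' fitB1Nutation(d, abs(cos(2 * pi * 620 * d)))
#' @export
fitB1Nutation <- function(durations, si, bMax = 2000) {
  n <- length(durations)
  if (n < 5L) stop("need at least 5 durations", call. = FALSE)
  if (length(si) != n) stop("durations and si must match", call. = FALSE)
  dg <- diff(sort(durations))
  if (max(dg) - min(dg) > 1e-9 * max(dg))
    stop("durations must form a uniform grid", call. = FALSE)
  if (stats::sd(si) < 1e-9 * max(abs(si), 1e-12))
    stop("signal carries no identifiable nutation", call. = FALSE)
  ord <- order(durations)
  durations <- durations[ord]; si <- abs(si[ord])
  sse <- function(b) {
    basis <- abs(cos(2 * pi * b * durations))
    a <- sum(basis * si) / max(sum(basis^2), 1e-12)
    sum((si - a * basis)^2)
  }
  bGrid <- seq(10, bMax, by = 2)
  b0 <- bGrid[which.min(vapply(bGrid, sse, numeric(1)))]
  opt <- stats::optimize(sse, interval = c(max(1, b0 - 10), b0 + 10))
  opt$minimum
}

#' Fit relaxation maps pixel by pixel
#'
#' Runs the dual steady-state fit ([fitDualDecay()]) or the
#' monoexponential fit ([fitMonoexp()]) independently at every pixel
#' inside the mask, and assembles T = 1/R (seconds), steady-state fraction
#' and goodness-of-fit images. Non-converged pixels are set to `NA` and
#' excluded from all downstream regional statistics.
#'
#' @param seriesPlus Numeric array `nx x ny x nt`, the +Z weighted series.
#' @param seriesMinus Matching -Z series for `model = "dual"`, or `NULL`
#'   for `model = "mono"`.
#' @param times Preparation durations (s), length `nt`.
#' @param mask Logical matrix `nx x ny`.
#' @param model `"dual"` or `"mono"`.
#' @return A [RegionMaps-class].
#' @export
fitMap <- function(seriesPlus, seriesMinus = NULL, times, mask,
                   model = c("dual", "mono")) {
  model <- match.arg(model)
  d <- dim(seriesPlus)
  if (length(d) != 3L) stop("seriesPlus must be a 3D array", call. = FALSE)
  if (d[3L] != length(times))
    stop("times must match the number of weightings", call. = FALSE)
  if (!identical(dim(mask), d[1:2]))
    stop("mask dimensions must match the image plane", call. = FALSE)
  if (model == "dual") {
    if (is.null(seriesMinus))
      stop("model = 'dual' needs seriesMinus", call. = FALSE)
    if (!identical(dim(seriesMinus), d))
      stop("seriesPlus and seriesMinus dimensions must match", call. = FALSE)
  }
  tM <- ssM <- rsqM <- matrix(NA_real_, d[1L], d[2L])
  idx <- which(mask, arr.ind = TRUE)
  for (px in seq_len(nrow(idx))) {
    i <- idx[px, 1L]; j <- idx[px, 2L]
    fit <- if (model == "dual") {
      tryCatch(fitDualDecay(times, seriesPlus[i, j, ], seriesMinus[i, j, ]),
               error = function(e) NULL)
    } else {
      tryCatch(fitMonoexp(times, seriesPlus[i, j, ]),
               error = function(e) NULL)
    }
    if (!is.null(fit) && isTRUE(fit@converged) && is.finite(fit@r) &&
        fit@r > 0) {
      tM[i, j] <- 1 / fit@r
      ssM[i, j] <- fit@ss
      rsqM[i, j] <- fit@rsq
    }
  }
  new("RegionMaps", tMap = tM, ssMap = ssM, rsqMap = rsqM,
      mask = mask)
}
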