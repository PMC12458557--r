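test_that("RAFF2 base element has the prescribed duration, peak and geometry", {
  el <- raff2Element(625, tl = 1.0, nSamples = 32)
  expect_equal(duration(el) * 1e3, 4.525483 / 4, tolerance = 1e-6)
  ## peak of the sine modulation, up to midpoint-sampling resolution
  expect_equal(max(amplitude(el)), 625, tolerance = 2e-3)
  ## effective field (w1, 0, dw) has constant magnitude w1max at every sample
  eff <- sqrt(amplitude(el)^2 + (freqMod(el) / (2 * pi))^2)
  expect_equal(eff, rep(625, 32), tolerance = 1e-12)

  ## tl = 2 element duration scales linearly (2.2625 ms)
  el2 <- raff2Element(625, tl = 2.0, nSamples = 32)
  expect_equal(duration(el2), 2 * duration(el), tolerance = 1e-12)

  expect_error(raff2Element(-625, 1), "positive")
  expect_error(raff2Element(625, 0), "positive")
})

test_that("RAFF2 packet duration, sample count and peak follow the TL grid", {
  pk <- raff2Packet(raffSpec(2, tl = 1.0))
  expect_equal(duration(pk) * 1e3, 4.525, tolerance = 2e-4)
  expect_identical(nSamples(pk), 128L)
  for (tl in seq(0.6, 2.0, by = 0.2)) {
    p <- raff2Packet(raffSpec(2, tl = tl))
    ## duration = TL x 4.525 ms, exact to one sample spacing
    expect_equal(duration(p), tl * 4 * 2 * pi / (sqrt(2) * 2 * pi * 625),
                 tolerance = 1e-12)
    ## samples: round(128 TL) snapped to the element-symmetric multiple of 4
    expect_identical(nSamples(p), 4L * as.integer(round(128 * tl / 4)))
    expect_lte(abs(nSamples(p) - round(128 * tl)), 2L)
    ## per-TL nominal peak power peak/TL, reached up to sampling resolution
    expect_equal(max(amplitude(p)), 625 / tl, tolerance = 2e-3)
  }
})

test_that("packet element order is P, P-pi-inverse, P-pi, P-inverse", {
  pk <- raff2Packet(raffSpec(2, tl = 1.0))
  a <- amplitude(pk)
  e <- split(a, rep(1:4, each = 32))
  ## fourth element is the time-reverse of the first
  expect_equal(e[[4]], rev(e[[1]]), tolerance = 1e-12)
  expect_equal(e[[2]], rev(e[[3]]), tolerance = 1e-12)
  f <- split(freqMod(pk), rep(1:4, each = 32))
  expect_equal(f[[4]], -rev(f[[1]]), tolerance = 1e-12)
  ## pi transmitter shift on the third element (P-pi) relative to the first
  ## (P): identical modulation, phase offsets differing by exactly pi
  raw <- raffmap:::.fmPhase(freqMod(pk), sampleInterval(pk))
  off <- rfPhase(pk) - raw
  d <- (off[65:96] - off[1:32] - pi) %% (2 * pi)
  expect_true(all(pmin(d, 2 * pi - d) < 1e-9))
})

test_that("full RAFF2 packet refocuses isolated-spin magnetization at every TL", {
  for (tl in c(0.6, 1.0, 1.4, 2.0)) {
    R <- netRotation(raff2Packet(raffSpec(2, tl = tl)))
    expect_lt(rotationAngleDeg(R), 1, label = sprintf("net rotation TL %.1f", tl))
  }
})

test_that("RAFFn packets cover ranks 1-5 with shared duration and falling peak", {
  expect_error(raffSpec(6), "rank")
  expect_error(raffSpec(0), "rank")
  pk2 <- raffnPacket(raffSpec(2))
  expect_equal(amplitude(pk2), amplitude(raff2Packet(raffSpec(2))))

  pk1 <- raffnPacket(raffSpec(1))
  ## 45-degree tilt: constant amplitude and offset w1max/sqrt(2),
  ## effective field magnitude 625 Hz
  expect_equal(range(amplitude(pk1)), rep(625 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(sqrt(amplitude(pk1)^2 + (freqMod(pk1) / (2 * pi))^2),
               rep(625, nSamples(pk1)), tolerance = 1e-12)

  dRef <- duration(raff2Packet(raffSpec(2)))
  for (rk in c(1L, 3L, 4L, 5L)) {
    p <- raffnPacket(raffSpec(rk))
    expect_equal(duration(p), dRef, tolerance = 1e-12)
  }
  pk5 <- raffnPacket(raffSpec(5))
  expect_lt(max(amplitude(pk5)), max(amplitude(pk2)))
  expect_equal(max(amplitude(pk5)), 245, tolerance = 1e-6)
})

test_that("pulse trains follow the half-packet count convention", {
  pk <- raff2Packet(raffSpec(2, tl = 1.0))
  tr <- buildTrain(pk, c(0, 8, 16, 24, 32))
  expect_length(prepDurations(tr), 5L)
  expect_identical(prepDurations(tr)[1L], 0)
  expect_equal(diff(prepDurations(tr)), rep(8 * duration(pk) / 2, 4),
               tolerance = 1e-12)
  ## 32 pulses x half-packet duration reconciles the 72.32 ms train ceiling
  expect_equal(max(prepDurations(tr)), 32 * duration(pk) / 2,
               tolerance = 1e-12)
  expect_equal(max(prepDurations(tr)) * 1e3, 72.4, tolerance = 1e-3)

  tr0 <- buildTrain(pk, 0L)
  expect_identical(prepDurations(tr0), 0)

  expect_error(buildTrain(pk, c(0, 8, 8)), "strictly")
  expect_error(buildTrain(pk, c(8, 16)), "start at 0")
  expect_error(buildTrain(pk, c(0, -4)), "non-negative")
})

test_that("HS pulses have sech amplitude, symmetric envelope and R-scaled sweep", {
  hs1 <- hsPulse(1, 4525e-6, 2500, 20)
  expect_equal(duration(hs1) * 1e6, 4525, tolerance = 1e-9)
  expect_equal(max(amplitude(hs1)), 2500, tolerance = 1e-3 * 2500)
  ## sech is even: amplitude symmetric about the midpoint
  expect_equal(amplitude(hs1), rev(amplitude(hs1)), tolerance = 1e-9)
  ## truncation level sech(beta) = 0.01, up to midpoint-sampling resolution
  expect_equal(min(amplitude(hs1)) / 2500, 0.01, tolerance = 0.05)
  ## full sweep bandwidth R / Tp
  expect_equal(diff(range(freqMod(hs1))) / (2 * pi), 20 / 4525e-6,
               tolerance = 1e-2)

  hs4 <- hsPulse(4, 4525e-6, 2500, 20)
  ## order 4 flattens the plateau: larger amplitude integral at equal peak
  expect_gt(sum(amplitude(hs4)), 1.5 * sum(amplitude(hs1)))
  expect_error(hsPulse(2, 1e-3, 2500, 20), "order")
})

test_that("CW, AHP and hard pulses match their stated shapes", {
  cw <- cwSpinlock(1250, 54e-3)
  expect_equal(duration(cw), 54e-3, tolerance = 1e-12)
  expect_true(all(amplitude(cw) == 1250))
  expect_true(all(freqMod(cw) == 0))

  expect_identical(nSamples(hardPulse(625, 0)), 0L)
  hd <- hardPulse(625, 1e-3)
  expect_true(all(amplitude(hd) == 625) && all(rfPhase(hd) == 0))

  ah <- ahpPulse(4000e-6, 2500)
  expect_equal(duration(ah), 4e-3, tolerance = 1e-12)
  ## half passage ends on-resonance at full amplitude
  expect_equal(utils::tail(amplitude(ah), 1), 2500, tolerance = 2500 * 1e-3)
  expect_lt(abs(utils::tail(freqMod(ah), 1)) / max(abs(freqMod(ah))), 0.01)
})

test_that("reverse AHP restores magnetization brought down by the forward AHP", {
  sys <- waterSystem()
  ah <- ahpPulse(4000e-6, 2500)
  down <- utils::tail(propagate(sys, ah), 1)[, 5:7]
  expect_lt(abs(down[3]), 0.05)          # near-complete excitation
  up <- utils::tail(propagate(sys, ahpPulse(4000e-6, 2500, reverse = TRUE),
                              mInit = c(0, 0, 0, down)), 1)[, 5:7]
  expect_gt(up[3], 0.99)
})

test_that("shape files round-trip amplitude and phase", {
  pk <- raff2Packet(raffSpec(2, tl = 1.0))
  path <- withr::local_tempfile(fileext = ".txt")
  writeShape(pk, path)
  lines <- readLines(path)
  expect_identical(sum(!grepl("^#", lines)), 128L)
  back <- readShape(path)
  expect_equal(amplitude(back), amplitude(pk), tolerance = 1e-6)
  expect_equal(rfPhase(back), rfPhase(pk), tolerance = 1e-6)
  expect_equal(sampleInterval(back), sampleInterval(pk), tolerance = 1e-9)

  ## empty packet -> header-only file
  empty <- hardPulse(625, 0)
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeShape(empty, path2)
  expect_true(all(grepl("^#", readLines(path2))))
  expect_identical(nSamples(readShape(path2)), 0L)
  expect_error(readShape(withr::local_tempfile()), "not found")
})

test_that("Packet validity catches inconsistent waveforms", {
  expect_error(new("Packet", amplitude = c(1, 2), phase = 0, fm = c(0, 0),
                   dt = 1e-6, peakHz = 10, label = ""), "equal length")
  expect_error(new("Packet", amplitude = -1, phase = 0, fm = 0,
                   dt = 1e-6, peakHz = 10, label = ""), "non-negative")
  expect_error(new("Packet", amplitude = 20, phase = 0, fm = 0,
                   dt = 1e-6, peakHz = 10, label = ""), "peak")
})
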