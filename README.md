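# raffmap

Rotating-frame MR relaxometry with RAFFn pulse trains, in R.

After myocardial infarction, the infarct scar and the remote myocardium
differ in their macromolecular environment, and rotating-frame relaxation
time constants (T1ρ, T2ρ, T_RAFFn) pick up that difference without
contrast agents. RAFF — Relaxation Along a Fictitious Field — measures
relaxation during sub-adiabatic sine/cosine amplitude- and
frequency-modulated irradiation whose effective field is stationary in a
higher-rank rotating frame; stretching the refocusing packet (the TL
factor) retunes the preparation's sensitivity to slow molecular dynamics
and chemical exchange. `raffmap` is for MR physicists and methods
developers who want a self-contained, scriptable implementation of that
entire measurement chain at desk scale.

The package provides:

* **Pulse construction** — RAFF2 composite packets P Pπ⁻¹ Pπ P⁻¹ with
  stretching factors TL 0.6–2.0 (4.525 ms × TL at the 625 Hz nominal
  peak), RAFFn ranks 1–5 via a recursive frame construction, CW
  spin-lock, adiabatic HS1/HS4 (R = 20), AHP and hard pulses; pulse
  trains counted in half-packets; two-column text shape files.
* **Spin dynamics** — two-pool Bloch–McConnell propagation (matrix
  exponential or adaptive ODE) with dipolar R1/R2 from a rotational
  correlation time (BPP), detailed-balance exchange, and the paired
  +Z/−Z acquisition protocol.
* **Fitting** — simultaneous fit of both acquisitions with steady-state
  formation,

  SI±(t) = ±SI0·e^(−Rt) + S_SS·(1 − e^(−Rt)),  SS = S_SS/SI0,

  plus monoexponential and B1-nutation fits, pixel-by-pixel map
  computation (T = 1/R), and NIfTI/TSV I/O.
* **Contrast analysis** — ROI propagation by pixel index and the
  relative relaxation time difference,
  RRTD = (T_MI − T_remote)/T_remote · 100%.
* **Synthetic phantom** — a digital short-axis mouse-heart phantom
  (annular myocardium, infarct sector, cavity, signal-free background)
  with prescribed per-region T and SS, seeded noise, and cohort
  generation, so the full pipeline runs without any external data.

## Worked example

```r
library(raffmap)

## the original RAFF2 packet
pk <- raff2Packet(raffSpec(2, tl = 1.0))
pk
#> Packet 'raff2 TL1.00': 128 samples, dt = 35.355 us, duration = 4.5255 ms
#>   peak amplitude 624.8 Hz (nominal 625.0 Hz)

## simulate the paired-acquisition decay for the fibronectin two-pool system
sys <- twoPoolSystem(1.2e-6)                   # 1.2e-6 mol/l vs 80 mol/l water
fit <- relaxationFromSim(simulateDecay(sys, buildTrain(pk, seq(0L, 64L, 2L))))
fit
#> FitResult: R = 0.548443 1/s (T = 1823 ms), SS = 0.2166, R^2 = 1.000000

## phantom -> maps -> regional contrast, at SNR 50
d <- synthesizeSeries(makePhantom(phantomSpec()), noiseSd = 0.02, seed = 1)
maps <- fitMap(d@seriesPlus, d@seriesMinus, d@times, d@rois@wholeMask)
contrastRecord(maps, d@rois, method = "raff2_tl1.0", subject = "s01")
#>   subject      method  t_mi_ms t_remote_ms rrtd_pct n_px_mi n_px_remote
#> 1     s01 raff2_tl1.0 59.16841    49.99756  18.3426    1098        2190
```

The packet lasts 4.525 ms (128 samples) as designed; the simulated
relaxation rate sits between the dipolar R1 = 0.5480 and R2 = 0.5487 1/s
(the 45° trajectory average) with a steady-state fraction of 0.22; and
the fitted phantom maps return the prescribed regional relaxation times
(59.1 / 50.0 ms ground truth) and an RRTD of 18.3% against the
prescribed 18.2%, within noise at SNR 50.

A command-line front end with subcommands `pulse`, `simulate`,
`phantom`, `fit`, `rrtd` and `run` is installed at
`inst/scripts/raffmap`; `run` consumes a YAML configuration
(see `defaultConfig()`) and writes maps, contrast tables and a manifest
recording the configuration hash and seed.

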