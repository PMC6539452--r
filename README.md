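# xfct

Simulation and quantitative reconstruction for benchtop **X-ray fluorescence
computed tomography (XFCT)** of gadolinium nanoparticle contrast, with a
fan-beam tube source, a single rectangular pinhole collimator and a linear
photon-counting detector read out in three energy bins.

XFCT images the distribution of a high-Z element (here Gd, K-edge 50.2 keV)
by stimulating its K-shell fluorescence (Kα1 = 42.98 keV, Kα2 = 42.28 keV)
with a filtered 140 kVp beam and counting the emitted photons through a
pinhole. Because soft tissue emits no fluorescence, the contrast is
background-free — but the raw middle-bin (39–45 keV) counts are dominated by
Compton scatter, and the recovered pixel values are quantitative only after
the scatter background is removed and both the incident and the emitted
photon attenuation are corrected. This package implements that full chain
for researchers studying quantitative nanoparticle imaging at desk scale:

* **Physics** — Klein–Nishina differential cross-section
  `f_KN(E, θ) = 2π r₀² sinθ (1/(1+α(1−cosθ)))² ((1+cos²θ)/2)
  (1 + α²(1−cosθ)²/((1+cos²θ)(1+α(1−cosθ))))` with `α = E/m₀c²`;
  embedded NIST-style mass-attenuation tables (water, PMMA, cortical bone,
  Gd, NaGdF₄, Cu) with log-log interpolation split at the K edge; analytic
  filtered tube spectra.
* **Scatter correction** — the side-band estimate
  `Sca₃₉₋₄₅ = ((r₃₉₋₄₅/r₃₃₋₃₉)·Ns₃₃₋₃₉ + (r₃₉₋₄₅/r₄₅₋₅₁)·Ns₄₅₋₅₁)/2`,
  where `r(i) = ∫ I₀(E) f_KN(E, θᵢ) dE` over each bin at the pixel's
  representative scatter angle, and `N_XRF = Ns₃₉₋₄₅ − Sca₃₉₋₄₅`.
* **Reconstruction** — MLEM,
  `fⱼ ← (fⱼ/Σᵢaᵢⱼ) Σᵢ aᵢⱼ gᵢ/(Σⱼ′aᵢⱼ′fⱼ′)`, with the system matrix
  `aᵢⱼ = Ω_B→p · exp(−∫_AB μ(E_inc)dl) · exp(−∫_BC μ(E_xrf)dl)` built from
  the pinhole response function and Siddon ray tracing; the attenuation maps
  come from a transmission-CT slice (filtered backprojection) via
  three-material decomposition (NaGdF₄ / bone / water).
* **Study tools** — digital calibration and mouse-like slice phantoms with
  ground truth, Poisson-noise multi-bin sinogram simulation,
  least-squares concentration calibration, CNR and Rose-criterion (CNR > 4)
  detectability analysis.

Default geometry follows the bench device: pinhole 75 mm from the rotation
centre, detector 63.5 mm behind the pinhole, 256 pixels of 0.5 mm × 2 mm, a
0.5 mm × 2 mm aperture, 45 projections at 10 s each (7.5 min per slice).

## Worked example

Simulate the six-insertion calibration phantom (0–20 mg/mL Gd in PMMA),
scatter-correct, reconstruct the transmission slice, run the quantitative
MLEM pipeline and report calibration and detectability metrics:

```r
library(xfct)
cfg <- read_run_config(NULL)        # defaults: 45 views, 128 x 128 / 0.5 mm
rep <- run_pipeline(cfg, "demo")
```

`demo/report.txt` from this run:

```
seed: 1
MLEM iterations: 100
calibration: slope 2.266e+05, intercept -1.342e+04, r-square 0.9996
insertion concentrations (true -> recovered mg/mL):
    0.0 ->   0.11   CNR(XFCT)   0.02   CNR(CT)  -0.71
    2.0 ->   1.91   CNR(XFCT)   6.81   CNR(CT)   0.12
    5.0 ->   4.95   CNR(XFCT)  18.29   CNR(CT)   1.05
   10.0 ->  10.15   CNR(XFCT)  37.93   CNR(CT)   2.88
   15.0 ->  14.77   CNR(XFCT)  55.37   CNR(CT)   4.53
   20.0 ->  20.12   CNR(XFCT)  75.56   CNR(CT)   6.07
detectability limit (Rose, CNR > 4): XFCT 1.16 mg/mL, CT 13.62 mg/mL
```

Reading it: the recovered per-insertion means are linear in the true Gd
concentration (r² = 0.9996; the slope converts image units to mg/mL), each
insertion's contrast-to-noise ratio grows with concentration much faster in
the fluorescence image than in the transmission image, and extrapolating the
CNR lines to the Rose threshold puts the detectability limit near 1 mg/mL
for XFCT versus >10 mg/mL for transmission CT at this (deliberately
low-dose) transmission fluence. Mouse-like slices with inhomogeneous organ
hotspots are available via `mouse_slice_phantom("liver" | "kidney" |
"leg_tumor")`.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/xfct.R pipeline --config run.yaml --out out_dir
```

with subcommands `simulate | correct | recon-ct | recon-xfct | calibrate |
pipeline` and flags `--config`, `--seed`, `--out`, `--resume`.

## Vignette

`vignettes/quantitative-xfct.Rmd` documents the forward model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic phantoms do and do not share with real bench data, and the
numerical choices inside the reconstruction chain.
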