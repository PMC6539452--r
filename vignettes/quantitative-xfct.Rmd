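---
title: "Quantitative pinhole XFCT: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative pinhole XFCT: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xfct)
```

## The imaging problem

X-ray fluorescence CT recovers the spatial distribution of a high-Z
contrast element — here gadolinium, delivered as NaGdF~4~ nanoparticles —
inside a slice of a small object. A filtered 140 kVp fan beam irradiates the
slice; photons above the Gd K edge (50.2 keV) photo-ionize K shells, and the
refilled vacancies emit Kα fluorescence at 42.98 / 42.28 keV. A tungsten
pinhole projects the slice onto a linear photon-counting detector whose
three energy bins (33–39, 39–45, 45–51 keV) record, respectively: scatter,
fluorescence plus scatter, and scatter. Rotating the object through 45
views at 10 s each gives a 45 × 256 three-bin sinogram per slice in 7.5
minutes.

Pixel values of the reconstruction are proportional to Gd concentration
only after two corrections: removal of the Compton background under the
fluorescence peak, and compensation of the attenuation suffered by both the
incident beam on its way *in* and the Kα photons on their way *out*. The
package implements the whole chain — forward simulation, correction,
reconstruction, calibration — so that the closed loop can be tested
quantitatively against known digital ground truth.

## Forward model

For every view the object is rotated (equivalently, the apparatus is
rotated about the fixed object); the incident beam is modelled as a
parallel fan in the slice plane. For a voxel at B with concentration
$c_j$ (mg/mL):

$$\bar n_{\mathrm{fluo}}(i) = \sum_j \Phi\,\tau\,s^2\,\omega_K\,10^{-3}c_j\;
  e^{-\int_{A B}\mu(E_{\mathrm{inc}})\,dl}\;\Omega_{B\to p}\;
  e^{-\int_{B C}\mu(E_{\mathrm{xrf}})\,dl}$$

with $\Phi$ the source fluence (photons mm^-2^ s^-1^), $\tau$ the exposure,
$s$ the voxel side, $\omega_K$ the K fluorescence yield and
$\Omega_{B\to p}$ the pinhole response (below). Scatter in bin $b$ adds

$$\bar n_{b}(i) = \sum_j \Phi\,\tau\,s^2\,\kappa\,10^{-3}\rho_j\,
  e^{-\int_{A B}\mu(E_{\mathrm{inc}})\,dl}\, w_b(\theta_j)\,
  \Omega_{B\to p}\, e^{-\int_{B C}\mu(E_b)\,dl},$$

where $w_b(\theta) = \int_b I_0(E) f_{KN}(E,\theta)\,dE$ is the
Klein–Nishina-weighted spectral integral over the bin, $\theta_j$ the angle
between the beam and the voxel-to-pinhole direction, $\rho_j$ the bulk
density (a water-equivalent electron-density weight) and $\kappa$ a scatter
amplitude. Counts are Poisson. Assumptions worth stating explicitly:

* **single effective incident energy** $E_{\mathrm{inc}}$ for the incident
  attenuation path — the fluence-weighted mean of the spectrum above the K
  edge (≈ 79 keV for 140 kVp + 0.4 mm Cu). The system matrix makes the same
  assumption, so simulator and reconstructor are consistent by
  construction; with a real polychromatic beam this is an approximation.
* **single scatter** with one representative angle per voxel; no multiple
  scatter, no Rayleigh scattering, no detector charge sharing. The bins are
  ideal (perfectly sharp edges).
* **2D slice transport**: the 2 mm detector/aperture height enters only
  through the aperture solid angle, never as an image dimension.

The simulator keeps its noiseless fluorescence-only and scatter-only
components in the returned object; correction and reconstruction tests use
them as oracles.

## Pinhole response and ray tracing

The ideal (infinitely thin) rectangular aperture of width $w_a$ = 0.5 mm
and height $h_a$ = 2 mm sits 75 mm from the rotation centre; the detector
line lies 63.5 mm behind it. A point source at axial distance $t_v$ from the
aperture plane subtends the solid-angle fraction
$\Omega = w_a h_a \cos\theta / (4\pi r^2)$, and its penumbra on the detector
is a rectangle of width $w_a (t_v + L_2)/t_v$ centred on the geometric image
point; each pixel receives $\Omega$ times its 1-D overlap fraction with the
penumbra. Summed over pixels this conserves the aperture solid angle
exactly, a property the test suite asserts together with a Monte-Carlo
ray-sampling check. Collimator penetration and finite pinhole thickness are
not modelled.

Line integrals through voxel grids use an exact incremental (Siddon-style)
traversal in C++; maps are in cm^-1^, coordinates in mm. The traversal is
additive under segment splitting to 1e-9 relative and matches dense midpoint
sampling to better than 0.1 %.

## Scatter correction

The middle-bin scatter is estimated from the side bins as
$\widehat{Sca} = \tfrac12\big((r_2/r_1)\,Ns_1 + (r_2/r_3)\,Ns_3\big)$
with per-pixel weights $r_b = w_b(\theta_i)$. The representative angle
$\theta_i$ of pixel $i$ is evaluated where the pixel's sight line through
the pinhole crosses the incident-beam midline — a single angle per pixel.
$I_0(E)$ is taken as the *source* spectrum, as written; whether object
attenuation should harden it first is left to the user (the bin ratios
change only mildly). Corrected projections are clamped at zero before MLEM:
negative excursions are Poisson artifacts, and MLEM requires nonnegative
data. The correction inherits two systematic residuals from its own
approximations — bin-dependent exit attenuation and the angle spread along
each sight line — which the test suite bounds at the few-percent level on
noiseless simulations.

## Reconstruction chain

1. **Transmission slice.** A 180-view parallel-beam scan at the 65 kVp +
   0.1 mm Cu effective energy is reconstructed by Ram–Lak filtered
   backprojection (exact band-limited real-space kernel, frequency-domain
   convolution with zero padding to the next power of two, linear-interpolated
   backprojection). 180 views are used even though the fluorescence scan has
   45: the bench transmission scan likewise used an order of magnitude more
   projections, and the attenuation map is an input, not the quantity under
   test.
2. **Uncorrected MLEM** with the vacuum (pinhole-response-only) matrix
   locates the Gd.
3. **Three-material decomposition.** Bone is segmented by thresholding the
   attenuation map at the midpoint between water and cortical bone at the
   transmission energy (the bench threshold is unstated; the midpoint is the
   natural default). Soft tissue becomes water with a water-equivalent
   density that reproduces the measured attenuation voxel-by-voxel — this
   handles PMMA, which attenuates ~10 % more than water, without a dedicated
   PMMA class. Gd density comes from the uncorrected image scaled by a
   provisional calibration slope when a calibration is available; otherwise
   the Gd term is omitted (its contribution to μ is second-order below
   ~20 mg/mL).
4. **System matrix and final MLEM.** $a_{ij} = \Omega_{B\to p}
   e^{-\int\mu(E_{\mathrm{inc}})}e^{-\int\mu(E_{\mathrm{xrf}})}$ with
   $E_{\mathrm{xrf}}$ = 42.98 keV (Kα1; Kα2 differs negligibly in μ).
   Entries below 1e-8 of the maximum are dropped; the matrix is stored
   sparse (about 2 × 10^6^ nonzeros at 45 views × 256 pixels × 128²). The
   decomposition → matrix → MLEM loop runs once by default, matching the
   single sequential pass of the bench procedure (`n_outer` raises it).
5. **Calibration.** Ordinary least squares of per-insertion ROI means
   against known concentrations; the image is converted to mg/mL by
   subtracting the intercept and dividing by the slope.

MLEM starts from a uniform positive image (the conventional choice), runs a
fixed 100 iterations by default (no count is stated for the bench
reconstructions; 100 is a standard plateau for 45-view pinhole data, and an
optional early stop on relative image change < 1e-4 is available), freezes
zero-sensitivity voxels at zero, and floors the forward projection at 1e-12
to guard empty rays. Nonnegativity and a non-decreasing Poisson
log-likelihood are asserted in the tests.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| pinhole_to_center / pinhole_to_detector | 75 / 63.5 | mm | bench layout; FOV = 151 mm > 50 mm |
| detector_pixels × pixel_width | 256 × 0.5 | –, mm | linear CZT array |
| aperture width × height | 0.5 × 2 | mm | rectangular tungsten pinhole |
| n_views × exposure | 45 × 10 | –, s | 7.5 min per slice; 360° assumed (the rotation stage spins fully) |
| bins | 33–39 / 39–45 / 45–51 | keV | Kα lines fall in the middle bin; Kβ (in 45–51) is deliberately not counted |
| source_fluence | 1e8 | mm^-2^ s^-1^ | calibrated once so the default phantom peaks near 10³ middle-bin counts |
| scatter_scale | 2.5 | – | puts middle-bin scatter at the order of the fluorescence peak, as in raw bench data |
| fluorescence yield ω~K~ | 0.93 | – | standard literature value for Gd; absolute scale is removed by calibration |
| spectrum | 140 kVp + 0.4 mm Cu | – | Kramers' law × Cu transmission; a `{"mode": "mono"}` config selects a monoenergetic beam |
| transmission scan | 180 views, 2e4 counts/ray, 65 kVp + 0.1 mm Cu | – | low-power imaging chain; its dose is orders of magnitude below the XFCT dose |
| grid | 128 × 128 × 0.5 | mm | 64 mm field around the 48 mm phantom |
| MLEM n_iter / n_outer | 100 / 1 | – | see above |
| bone threshold | (μ~water~+μ~bone~)/2 at E~CT~ | cm^-1^ | decomposition default |
| ROI radius | 2.4 | mm | sampling discs inside the 4 mm insertions |
| Rose threshold | 4 | – | CNR > 4 deems a feature detectable |

The source-to-centre distance and fan angle of the bench device are not
published; the incident beam is modelled as parallel (at ≥ 75 mm source
distance the divergence across a ≤ 50 mm object is a secondary effect), and
the nominal `source_to_center = 500` mm in the geometry object is
documentation only.

## Phantoms: what they emulate and what they do not

`calibration_phantom()` is a PMMA cylinder (radius 24 mm) with six 4 mm
water-filled insertions at 0, 2, 5, 10, 15, 20 mg/mL Gd on a 15 mm ring —
concentrations chosen to bracket the low-mg/mL detectability regime and the
~20 mg/mL stock solution (the exact bench insertion values are published
only graphically). `mouse_slice_phantom()` builds an elliptical water body
with a bone disc and one or two radially tapered hotspots peaking at the
in-vivo organ uptakes (liver 7.94, kidney 2.51, hind-leg tumor 7.13 mg/mL).
Dissolved NaGdF~4~ mass follows from the Gd concentration through the
stoichiometric mass fraction 157.25/257.24, with additive solution
densities; rasterization antialiases disc edges by 4 × 4 subsampling and
conserves total Gd mass to < 1 %.

What passing closed-loop tests therefore demonstrate: the correction and
reconstruction chain is consistent and quantitative *under its own forward
model*. What they do not demonstrate: robustness to detector charge
sharing, multiple scatter, beam hardening of the scatter ratios, anatomical
complexity, or motion — none of which the simulator produces. In
particular, absolute detectability limits depend on the (unpublished)
absolute photon economy of the bench device; only orderings and linearity
carry over.

## Attenuation data

Mass-attenuation tables are plain-CSV fixtures on a coarse 20–150 keV grid
in the NIST style: water, PMMA and cortical bone carry standard reference
values; elemental Gd is reconstructed around its 50.2396 keV K edge with an
E^-3^ photoelectric model anchored at the edge (adequate for a
self-consistent simulate/reconstruct loop; users needing reference-grade Gd
coefficients should substitute their own table); NaGdF~4~ is the
stoichiometric mixture of the Gd table with a water-like light-element
complement. Interpolation is log-log and never crosses the K-edge
discontinuity — the edge is represented by bracketing grid points at 50.2
and 50.3 keV.

## Numerical conventions

* Voxel centres at `origin + (index − 1/2)·pixel_size`; world origin at the
  rotation centre; μ in cm^-1^, lengths in mm (optical depth = μ · mm/10).
* View *k* rotates the object by `k · 360°/n_views`; internally the
  apparatus is counter-rotated in the object frame so that attenuation maps
  are never resampled.
* Sub-seeds: the fluorescence and transmission simulations consume
  `seed·1000 + 1` and `seed·1000 + 2`, so noiseless outputs are
  seed-independent and noisy outputs are reproducible bit-for-bit.
* Negative corrected projections → 0; negative calibrated concentrations
  are preserved in arrays (clamp only for display).
* CNR uses the background mean and sample SD pooled over all background-ROI
  pixels (the bench formula is unstated; this is the standard
  Rose-criterion form with the n−1 SD convention).
* Test problem sizes: the property suite runs on 32–64-voxel grids with
  16–24 views; the closed-loop calibration study runs at the full
  128 × 128 / 45-view / 100-iteration setting with source fluence raised to
  6e8 mm^-2^ s^-1^ (peak middle-bin counts above 5000), which is also what
  `scripts/acceptance.R` executes.

## Known limitations

Single-scatter, parallel-beam, 2D; ideal pinhole and detector; effective-
energy attenuation instead of full spectral transport; Gd attenuation table
approximate below/above the edge; no regularized or penalized-likelihood
variants; no 3D cone-beam reconstruction (the transmission step is a 2D
FBP stand-in for the volumetric scan that provides attenuation maps on the
bench device).
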