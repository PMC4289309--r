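---
title: "Optics and depth calibration for objective-based SPR imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optics and depth calibration for objective-based SPR imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprcal)
```

## The measurement problem

Surface plasmon resonance imaging (SPRI) through a high-NA objective maps
refractive-index changes within the evanescent field above a thin gold
film, with enough lateral resolution to resolve focal adhesions and other
subcellular structure without labels. Quantitative interpretation of such
images needs three calibrations: the reflectance-versus-angle response of
the optical stack (to place the operating point and convert camera counts
to reflectivity), the anisotropic lateral point spread function (plasmons
propagate micrometers along one axis), and the *detectable* penetration
depth of the evanescent field — how far from the surface an object of
cell-like refractive index can sit and still rise above the noise floor.

`sprcal` implements the full quantitative chain: complex-index multilayer
Fresnel optics, back-focal-plane (BFP) illumination geometry, evanescent
field theory, a synthetic image generator for reference microspheres and
point sources, and the bead-based image-analysis pipeline that turns a
bright-field / SPR image pair into a measured detection depth.

## Thin-film model

Reflectance is computed with the standard characteristic-matrix
(transfer-matrix) solution for stratified media with complex relative
permittivities, for both polarizations (`stack_reflectance()`). Conventions:

* absorbing convention `Im(eps) >= 0`; all complex square roots are taken
  on the branch `Im >= 0` so evanescent fields decay away from each
  interface;
* angles are in degrees in the incidence medium; the entry layer must be
  transparent;
* interior layer thicknesses are in nm; the first and last layers are
  semi-infinite.

The test suite checks this implementation against a second, independently
coded interface-recursion solution on random 3-5 layer stacks (agreement
better than 1e-10), against the two-medium closed forms, and for energy
conservation on lossless stacks.

### Gold optical constants

The package ships the Johnson & Christy (1972) tabulation of gold as its
default metal (`gold_dispersion()`), with n and k interpolated linearly in
wavelength (interpolating the *index*, not the permittivity — the choice
matters at the fourth decimal). Any tabulation can be substituted through
`dispersion_table()` or the plain-text stack config. This choice is
load-bearing: published gold tables disagree enough in the visible that
the 620 nm coupling minimum of the glass(1.78)/45 nm gold/water stack
moves by roughly ±1-2 degrees and the penetration depths by 10-20 percent
across tables. With Johnson & Christy the minimum computes to ≈55.0° and
the 620 nm plasmon propagation length `1/(2 Im k_sp)` to ≈2.8 μm;
quantities derived from the table should always be reported together with
the table used. The ~1 nm chromium adhesion layer under the gold is
ignored, consistent with a three-layer treatment of the sensor.

```{r}
stack <- spr_stack(620)
spr_minimum_angle(stack)
propagation_length(620, dielectric_lookup(gold_dispersion(), 620), 1.333^2)
```

### Penetration depth convention

`penetration_depth()` evaluates the closed form
\[
L_p = \frac{\lambda}{2\pi}
      \left|\frac{\mathrm{Re}(\varepsilon_m)+\varepsilon_d}
                 {\varepsilon_d^2}\right|^{1/2},
\]
and the package treats \(L_p\) as the 1/e length of the plotted intensity
profile \(I(z) = e^{-z/L_p}\): no extra factor of two is applied anywhere.
One consequence deserves emphasis. In the thin-film model the first-order
reflectivity response to a semi-infinite index step held at gap distance
\(z\) decays as \(e^{-2z/L_p}\), not \(e^{-z/L_p}\): the closed form above
is an amplitude decay length, and the response follows the local
*intensity*. The simulator's property tests assert the factor-2 form
(verified to a few percent for index steps up to 0.01 above water); users
comparing measured bead contrast decay against theory should be aware
which convention a quoted \(L_p\) uses. The depth-calibration experiment
below is unaffected: its noise calibration is defined on the rendered
image, not on either exponential form.

At the red end of gold's plasmonic window the depths grow quickly:

```{r}
penetration_depth_curve(c(480, 515, 550, 590, 620, 670))
```

At 480 nm gold is barely plasmonic (`Re(eps)` only just below
`-eps_water`), so \(L_p\) is a few tens of nm and the resonance dip is
shallow and broad; results at that wavelength are the most
table-dependent and noise-sensitive.

## Back focal plane geometry

Radial position in the objective pupil encodes the incidence angle. The
mapping used is the Abbe sine relation normalized to the periphery angle,
\(r/R = \sin\theta / \sin\theta_{max}\) — nearly linear in \(\theta\) over
the pupil, which is why a linear description is often quoted; the sine
form was chosen as the physically grounded one. The periphery angle
`max_angle_deg` defaults to 60° and is deliberately decoupled from the
NA/n limit (≈68° for NA 1.65 in n 1.78), since the usable aperture edge
is an instrument property. Azimuth is measured from the +x axis (the
polarization axis), counter-clockwise in physical coordinates.

The imaging operating point is placed slightly shallow of the reflectance
minimum, at `operating_reflectance = 0.1` by default, so that index
increases produce a linear positive ΔR response. Where the dip never
reaches 0.1 (gold below ~520 nm) `operating_angle()` falls back to the
minimum itself and flags it (`at_minimum = TRUE`).

`fit_fresnel_scan()` normalizes raw BFP scan counts to reflectivity units
by least squares over three free parameters — gold thickness, intensity
scale, angle offset — mirroring how measured scans are reduced; the fit
is invariant to intensity rescaling, and recovers a 45 nm film to ±2 nm
from scans with 1 percent noise.

## The synthetic scene generator

`render_bead_scene()` / `make_bead_dataset()` emulate the reference
experiment: polymer microspheres (Sephacryl n = 1.345, silica 1.42, PMMA
1.48, polystyrene 1.59 — cell-like indices) resting on the 45 nm gold
film under water, imaged in p- and s-polarization plus bright field.

* **Bead optics.** Each pixel under the bead is modeled as the four-layer
  stack glass / gold / water gap \(z(\rho) = r_1 - \sqrt{r_1^2-\rho^2}\) /
  semi-infinite bead material (ray-local approximation: the curved bead
  surface is treated as a flat slab above each pixel). Scattering and
  curvature corrections are out of scope; the model reproduces the
  saturating contrast of high-index beads and the background exactly for
  index-matched beads.
* **PSF.** Separable anisotropic kernel: Gaussian of FWHM 0.30 μm along
  x (perpendicular to plasmon propagation) and, along y, the same
  Gaussian convolved with a one-sided exponential tail of length
  0.4539 μm — the value solved numerically (`solve_psf_decay()`) so a
  point source measures 0.60 μm FWHM along y, the measured anisotropy of
  the instrument class. The propagation tail is assigned to the y image
  axis as a labeling convention; only the anisotropy ratio matters to the
  analysis.
* **Illumination and noise.** A smooth low-order polynomial field (mean
  1, ±10 percent) multiplies both polarization frames; Gaussian noise of
  sd `noise_sigma/sqrt(frames_to_average)` is added in reflectance units
  inside that multiplication, so p/s division cancels the inhomogeneity
  in signal and noise alike. The s-polarized frame is a static reference
  for the whole acquisition series and is modeled as heavily
  frame-averaged, i.e. noise-free. Shot-noise statistics are not
  modeled. Renders are bit-reproducible under a fixed seed.

What passing tests on these scenes do *not* show: performance on real
images with gold roughness, coverslip inhomogeneity, diattenuation at
high NA (not corrected here), coherent artifacts of short illumination
arcs, or scattering by non-spherical objects.

## The depth-measurement pipeline

The per-bead pipeline (`measure_bead()`) follows the reference image
-analysis routine:

1. divide the p- by the s-polarized image (`normalize_ps()`);
2. convert to ΔR by subtracting the mean of the background annulus
   (`to_delta_R()`); the annulus is the bead ROI circle dilated by
   `dilation_um = 10` (diameter dilation, i.e. radius +5 μm);
3. estimate the background sd σ over the annulus
   (`background_sigma_annulus()`);
4. count all ROI pixels with ΔR above `k σ` (`k = 3`; no
   connected-component filtering) and convert the count to the
   circle-equivalent radius \(r_2\) (`bead_radius_from_threshold()`);
5. measure \(r_1\) from the bright-field dark ring centerline with
   sub-pixel parabolic refinement (`brightfield_radius()`);
6. invert the resting-sphere chord geometry,
   \(d = r_1 - \sqrt{r_1^2 - r_2^2}\) (`depth_from_radii()`), evaluated
   in the cancellation-free form \(r_2^2/(r_1 + \sqrt{r_1^2-r_2^2})\).

The frequently quoted relation \(r_1^2 = r_2^2 + (r_2 - d)^2\) is not the
chord of a surface-resting sphere — for small observed chords it has no
real solution — so the package implements the geometrically consistent
form above, which is the exact inverse of the forward chord
\(r_2 = \sqrt{d(2r_1 - d)}\) (round-trip tested to 1e-12 relative).
FWHM estimation (`fwhm_from_profile()`) takes its baseline as the median
of the profile's outer quartiles, a choice this package makes explicit
since peak-width measurement needs *some* baseline rule.

ROI selection is manual in practice; the pipeline accepts a
config-supplied circle, or `detect_bead_roi()` provides a coarse
brightest-blob fallback that is flagged as automatic. In the packaged
studies the ROI circle is centered on the known bead position with a 3 μm
margin beyond the expected footprint, emulating the manual choice.

## Calibrated noise and the 1/e detection limit

The central claim the synthetic experiment restates is that the
theoretical 1/e depth \(L_p\) acts as the practical detection limit for
bead material. The study condition is a noise level *calibrated* so that
the pipeline's 3σ threshold cuts the bead footprint off at gap distance
\(L_p\). `calibrate_noise_sigma()` defines this by expected count: it
solves for σ such that
\(\sum_i \Phi\big((v_i - 3\sigma)/\sigma\big) = \pi \rho_{L_p}^2 / A_{px}\),
where \(v_i\) are the noise-free processed ΔR values in the analysis ROI
and \(\rho_{L_p}\) is the chord radius at depth \(L_p\). In the noise-free
limit this is plain count matching at the footprint edge; the expectation
form additionally accounts for blurred-skirt pixels fluctuating across
the threshold, which matters when the PSF is not small against the
footprint (the 480 nm / small-\(L_p\) corner). The acceptance study then
runs the full pipeline — including its own annulus σ estimate — over 4
bead indices × 3 radii (2.85, 3.05, 30 μm) × 6 wavelengths × 10 noise
seeds and requires the recovered depth to agree with \(L_p\) within 15
percent per condition (and per seed at 620 nm), to be uniform across bead
sizes, and to increase monotonically with wavelength.

Problem sizes: small-bead scenes are 420×420 px at 0.05 μm/px and
large-bead scenes 672×672 px at 0.1 μm/px — fields just large enough to
hold the dilated annulus (and, for the 30 μm bead, the bright-field
ring), with the finer sampling for small beads keeping the smallest
footprints (≈120 px at 480 nm) countable. The deterministic scene is
rendered once per condition and shared across noise seeds.

## Known limitations

* Everything tied to the metal's optical constants inherits the spread
  between published gold tables; report the table.
* The four-layer ray-local bead model omits Mie scattering, coherence and
  speckle; it is a contrast model, not a full electromagnetic solution.
* Diattenuation between p and s at high NA — which in practice requires
  normalizing to a Fresnel fit rather than raw p/s division — is not
  modeled.
* The 3σ count statistic has a positive soft-edge bias whenever the PSF
  width is comparable to the footprint; the expected-count calibration
  makes the synthetic study consistent, but real measurements in that
  regime (short \(L_p\), small beads) carry the same sensitivity.
* Linescan classification is a fixed-threshold labeler; it does not
  segment cells.
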