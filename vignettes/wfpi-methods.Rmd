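---
title: "Methods: phase recovery from two defocused pupil images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase recovery from two defocused pupil images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how `wfpi` estimates an ocular wavefront from two
defocused intensity images, which choices were genuinely open, why they
were made, and what the in-silico validation does and does not demonstrate.

## Physical model and assumptions

A wavefront `W(x, y)` (optical path difference, micrometres) at the pupil
plane displaces each geometric ray laterally by `±Δz ∇W` at the two
capture planes `±Δz`. The package works entirely in this geometric-optics
regime: intensity is transported, not diffracted. That is adequate when
`Δz` is small compared with the Rayleigh range of the aberration scales of
interest, which holds for the millimetre-scale `Δz` and the
several-micrometre, millimetre-correlated phase structure the instrument
class targets. Wave-optical propagation, speckle (the instruments use
incoherent light precisely to avoid it), scattering, and eye motion are
out of scope.

Both images are assumed bias-subtracted and flat-fielded, co-registered,
and sampled on a common grid with pixel pitch `s` in the pupil plane
(`pupil_pixel_size()` converts a sensor pitch through the magnification).

## The estimator

### Directional cumulative-profile matching

For each of `k` angles uniformly covering `(−π/2, π/2]`, a family of
parallel lines covers the grid, one line per unit intercept along the
minor axis. Lines with `|tan α| ≤ 1` are parameterized along x, steeper
lines along y; this avoids the tangent singularity and keeps sampling
steps bounded. Along each line, both images are sampled bilinearly at unit
major-axis steps and accumulated into monotone profiles. Profile pairs are
normalized to a common total (the plane-2 profile is rescaled to the
plane-1 total; flux can genuinely leave a line between planes, and the
rescaling keeps the inversion defined at every level — which of the
possible normalizations the original instrument uses is not documented, so
per-line normalization is this package's documented choice). The matched
displacement at each sample is found by monotone linear inversion at the
sample's mid-mass level; flat (zero-flux) stretches invert to their
midpoint, and samples whose local flux falls below `eps_rel` (default
`1e-6`) of the line total are discarded as low-confidence.

Two discretization details matter:

* **What the displacement means.** Cumulative matching measures the
  transport of flux *along the line*, i.e. the projection of the local
  2-D ray displacement onto the line direction — not the motion of image
  features. The per-angle reading is therefore `(δ·û) cos α` in abscissa
  units for x-parameterized lines (`(δ·û) sin α` in ordinate units for
  y-parameterized ones).
* **Where it applies.** The displacement between the plane-1 and plane-2
  positions of the same flux belongs to the mid-plane (pupil) coordinate,
  so each sample is deposited by bilinear splatting at the midpoint of the
  matched pair, weighted by its local flux.

Per pixel, the projections from all angles are combined by weighted least
squares of the model `p(α) = φ_h cos α + φ_v sin α` with precision weights
`cos²α` / `sin²α`; this is the cos/sin-weighted angular sum with its
uniform gain fixed analytically rather than by a separate calibration
constant. A pixel is kept only when its accumulated angular weight and the
conditioning of its 2×2 normal matrix show both directions are genuinely
constrained. The null case is exact: identical images give identically
zero gradients.

`k = 120` is the default (the precision of the method saturates around
that value for the grid sizes used here — the test suite checks `k = 120`
versus `240`); the experiment harnesses use `k = 60` at 256² grids, where
the saturation has already set in.

### Rim handling

Within a band of roughly half the rim displacement, per-line readings are
dominated by the sliding of the pupil boundary along each chord — a real
transport, but not a valid sample of the displacement *field* (it can
exceed the field by the chord-obliquity factor `R²/L²`). The raw field is
therefore clamped at 1.5× its 95th percentile magnitude, and a guard band
of `ceil(cap/2) + 2` pixels is eroded from the pupil before integration.
The analysis circle additionally subtracts `rim_guard` (default 2 px) from
the inscribed radius.

### Model-based refinement

The single-pass matcher has a mild, smooth, geometry-dependent gain on
extended smooth fields (the same chord-obliquity effect, averaged over
angles). Rather than calibrating it empirically, the estimator removes it
by construction: the low-order part of the field is parameterized by the
gradients of the first 66 Zernike polynomials, the current coefficient
estimate is re-propagated through the forward model (mass-conserving
splats of a mid-plane flux template built from the data itself, so model
and data carry identical smoothing), and the difference between the
measured data and the measured model is fitted in coefficient space and
added back with damped steps (0.9, 0.7, then 0.5; `refine = 5` passes by
default). At the fixed point the matcher sees data and model identically,
so its bias cancels for any field the basis can represent, whatever its
exact form. The high-frequency residual of the raw measurement — which the
iteration cannot and should not touch — is clamped at 1.5× its 99th
percentile and re-attached unchanged. The polynomial field is evaluated
only over the dilated pupil support (Zernike gradients grow without bound
far outside the unit circle) and clamped to the same physical bound as the
raw field.

### Integration

The gradient field (metres of optical path per pixel step after
`φ' = s²/(2Δz) φ`) is integrated by Fourier-domain least squares on the
bounding box with iterative mask-constraint extension: gradients outside
the pupil are unknowns, replaced each round by the current estimate's own
gradients. Two numerical points:

* The spectral inverse uses the centred-difference response `i sin ω` on
  the even mirror extension of the grid, and the extension gradients are
  computed with the *same* operator on the mirror torus. With that
  consistency the solve-then-differentiate step is a non-expansive
  projection and the iteration converges monotonically; with ordinary
  one-sided border differences it slowly diverges.
* Iteration stops after 50 rounds or when the masked solution changes by
  less than `1e-6` relative RMS; the best iterate by in-mask gradient
  residual is returned, along with that residual
  (`attr(phase, "grad_residual_rms")`).

Piston is removed (zero mean over the mask); tip/tilt are kept until the
analysis stage removes them explicitly. Degenerate inputs (masks under 16
pixels, disconnected masks, pixel-unit fields) are rejected.

### Analysis

`analyze_eye()` mirrors standard aberrometry reporting: the largest circle
inscribed in the pupil mask (distance-transform maximum, row-major
tie-break) defines the fitting domain; piston/tip/tilt are removed; the
first 66 OSA polynomials are fitted by ordinary least squares on the pixel
samples (common aberrometry practice; no quadrature weights); band RMS
values are root-sum-squares over j = 3–5 / 6–14 / 15–65; the refraction
uses the standard second-order power-vector conversion with the sphere
reported as the spherical equivalent `M` itself — half the cylinder is
deliberately *not* folded into the sphere, so spherical and cylindrical
errors stay separable. Cylinders are reported minus-sign by convention;
`as_plus_cylinder()` does the full prescription transposition (including
the `M − C/2` sphere arithmetic) for comparison against plus-cylinder
trial lenses. The difference between the measured map and its 66-term fit
is returned with its RMS — on real eyes this is where structure beyond the
clinical basis lives. `highpass()` subtracts a mask-aware normalized
Gaussian blur (`sigma` in pixels, default 0.5; the instrument literature
leaves the unit unstated, and pixels make the filter resolution-honest).

## The simulator

`sim_config()` defaults mirror the bench geometry this package emulates:
plane separation `2Δz = 13.33` mm, pupil diameters of a few millimetres,
and a pupil filling 78% of the grid side (256² default, pitch derived).
The illumination is a uniform disk with a 2 px raised-cosine rim. A
multiplicative band-limited texture is available (`texture_contrast`), but
the default is uniform: cumulative matching reads density transport, so
texture adds per-chord normalization noise without adding signal — the
opposite of feature-tracking methods.

Ground-truth generators: `phase_from_refraction()` (exact second-order
inverse of the refraction conversion), `random_dm_phase()` (OSA j = 3…65
coefficients, standard-normal with a mild `1/(n+1)` radial-order taper —
a deformable mirror drives low orders more strongly than high — rescaled
so the pupil peak-to-valley is exact), and `pattern_phase()` (white noise
through a difference-of-Gaussians band-pass centred near a configurable
correlation length, default 0.5 mm — the fine-structure scale is not
quantified in the instrument literature — rescaled into a requested
peak-to-valley band). Phase maps extend 4 px past the pupil by polynomial
continuation so rim rays carry defined gradients.

`propagate()` transports each illumination pixel by `±Δz ∇W/s²` and
deposits it bilinearly; flux is conserved exactly, and displacements
leaving the grid raise an error rather than silently clipping.
`add_noise()` draws `Poisson(values × photon_scale)/photon_scale` plus
Gaussian read noise, clamped at zero.

What the simulator does *not* emulate: retinal scattering and the
double-pass point-spread function, accommodation and eye motion between
frames, Badal defocus servo behaviour, detector nonlinearity, and
wave-optical diffraction. Passing the in-silico experiments therefore
shows the algorithmic chain is correct and well-conditioned at bench
geometry — not that a physical instrument built to this recipe would meet
the same numbers on real eyes.

## Experiment harnesses and problem sizes

`run_experiment()` reproduces the calibration/validation designs
end-to-end: a 13-step defocus series over ±6 D on a 7 mm pupil, the
twelve trial-cylinder combinations (+0.50…+3.00 D × 90/45/22°), a
deformable-mirror style validation (40 random 66-term maps, 5 per
peak-to-valley amplitude 0.35…2.8 µm, 4 mm pupil — a scaled-down stand-in
for the original 800-map bench run), and a noise-driven repeatability
harness reporting total and band RMS spreads in mean ± SD / range form.
All harnesses run at 256² grids with `k = 60` and `refine = 5`; these
sizes were chosen as the smallest at which the angular saturation and
guard-band behaviour match the larger-grid regime, and they keep a full
experiment in the minutes range on one CPU. `scripts/acceptance.R` runs
the three noise-free experiments from a single seed and writes their
summary statistics as JSON.

## Known limitations

* Near the pupil rim (the guard band) the per-line transport reading is
  not a field sample; the reconstruction inside the eroded pupil is
  unaffected, but the outermost annulus of the wavefront is not reported.
* The refinement corrects gain only within the span of the 66-term
  gradient basis; structure beyond it retains the raw matcher's local
  gain, which is the dominant error term for the highest-amplitude
  random-map tests.
* The difference-map texture analysis assumes the fine structure is weak
  relative to the low-order field (hundreds of nanometres against
  micrometres); strongly scattering or discontinuous media violate the
  transport model itself.
* Only OSA single indexing is supported (no Noll/Fringe), and refraction
  is reported at the pupil plane (no vertex-distance transposition).
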