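---
title: "Spiral bright-field tomography: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiral bright-field tomography: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spiraltomo)
```

## The problem

Fluorescence light sheet microscopy (SPIM) images only what is labeled; the
surrounding anatomy of a living, translucent specimen such as a zebrafish
embryo is invisible. A SPIM instrument, however, already contains everything
needed for label-free optical projection tomography (OPT): a rotation stage,
a fast camera, and an LED backlight for transmission imaging. The catch is
the detection lens: at NA 0.3 the depth of field is only about 15 µm, far
less than the 0.1–1 mm depth of the specimen, so a single transmission image
is not a usable parallel projection.

This package implements the computational side of the solution:

1. **Spiral acquisition (simulated).** The specimen rotates continuously
   while being translated through the focal plane, so each of the 360 view
   angles is revisited once per rotation at a different focal depth —
   typically 20 rotations × 360 angles = 7200 frames.
2. **Extended depth of field (EDoF).** The ~20 through-focus frames of each
   angle are fused into one projection by high-pass-weighted averaging,
   reducing the data by the factor `n_rotations` (20×).
3. **Filtered back-projection (FBP).** After flat-field correction and log
   conversion, each image row yields a sinogram that is inverted slice by
   slice into an isotropic 3D attenuation volume. The rotation-axis position
   is found automatically by maximizing reconstruction variance.
4. **Registration.** Fluorescence SPIM stacks are placed into the
   tomographic frame (a single 1D unknown), spherical landmarks (eye
   lenses) are detected by Hough voting, time-lapse volumes are registered
   rigidly onto the anatomy, and organ volumes can be measured by seeded
   region growing.

Because no external data can be assumed, the package ships a full forward
simulator; every downstream stage is tested against phantoms with known
ground truth.

## The forward model

### Geometry

The rotation axis is the vertical camera axis y; detection looks along z;
transverse slices are (x,z) planes. Voxel and pixel centres sit at integer
0-based coordinates, and the axis crosses x = (width−1)/2 + `axis_offset_x`.
Angles increase counter-clockwise viewed from +y, fixing the sinogram
handedness: an off-axis feature at radius r and phase φ traces
x(θ) = r·cos(θ + φ) about the axis column.

### Image formation

Illumination is modeled as an ideal parallel beam; refraction and scattering
are ignored. This matches the inversion model (a parallel-beam inverse Radon
transform), and is the same approximation the reconstruction itself makes.
A transmission frame at angle θ and focal position f is

  I = dark + (background − dark) · V(x,y) · exp(−D(x,y)) + ε,

with V an optional vignetting field, ε Gaussian read noise (sCMOS proxy;
Poisson shot noise is out of scope), and D the blurred optical depth: the
rotated attenuation volume is partitioned into z-slabs of thickness δz/2
(Nyquist with respect to the blur scale), each slab's line-integral
contribution is blurred with an isotropic Gaussian of width

  σ(d) = σ₀ · max(1, |d| / δz)   [pixels],

where d is the slab's distance from the focal plane, δz ≈ 15 µm is the
depth of field, and σ₀ ≈ 1 px. The linear growth of blur with defocus is the
standard geometric-optics approximation; the instrument's actual PSF is not
modelled. Setting `sigma0 = 0` (or δz = ∞) recovers an exact Beer–Lambert
line-integral camera — with the in-focus blur σ₀ never falling below 1 px,
this is the only configuration in which −ln((I−dark)/(background−dark))
reproduces `project_attenuation()` to machine precision, and it is what the
round-trip tests use.

Two numerical shortcuts keep the 7200-frame × 256² simulation near the
minutes scale of the real acquisition, both documented because they are
approximations of the stated blur model:

* **Half-octave σ quantization.** Slab σ values are snapped to the grid
  σ₀·2^(j/2) (≤ 19% width error); slabs sharing a level are summed before a
  single blur, which is exact by linearity of convolution.
* **Decimated heavy blur.** For σ ≥ 2.5 px the slab is block-averaged by
  d = ⌈σ/2.5⌉, blurred at the variance-matched reduced width
  √(σ² − (d²−1)/12)/d, and bilinearly upsampled. Near-focus slabs — the ones
  that carry the EDoF weighting — are always blurred exactly.

Rotation resampling is bilinear per y-slice with zero outside the volume.
The simulator emits frames lazily in angle-major order (all rotations of an
angle consecutively) so that only one angle group is ever in memory; the
per-frame acquisition index preserves the true spiral order and grouping is
order-invariant, which the tests exercise with shuffled streams.

## Extended depth of field

The published processing is described only as "high-pass filtering and a
weighted average" (details in an unavailable supplement), so the filter here
is an explicit substitution from the standard focus-measure family: the
weight of frame i at a pixel is the squared difference-of-Gaussian high-pass
response (`hp_sigma` = 2 px) smoothed at `smooth_sigma` = 4 px, plus a floor
ε = 10⁻³ × the group-mean response. The floor makes fusion degenerate to the
plain mean where no frame has contrast; because ε is proportional to the
mean response, fusion commutes exactly with global intensity scaling, and
because weights are non-negative, every fused pixel is a convex combination
of the frames. When correction frames are supplied, fusion operates on
corrected transmittance (the original description leaves the processing
order open; this
choice makes the weights insensitive to illumination gradients). The
streaming implementation accumulates Σwx, Σw, Σx per angle and finalizes a
group the moment its `n_rotations`-th frame arrives, so the streaming and
batch paths run literally the same accumulator code and agree bit for bit.

## Reconstruction

Corrected transmittance is converted to optical depth by −ln before
inversion. The original description never mentions taking the logarithm,
but FBP requires
line integrals and the projections are explicitly interpreted as line
integrals of attenuation; a `log_transform = FALSE` escape hatch reconstructs
corrected intensity for comparison.

Filtering uses the exact discrete ramp kernel (h(0) = 1/4,
h(odd n) = −1/(π²n²)) evaluated by FFT with zero-padding to the next power
of two, with optional Shepp-Logan and Hamming windows; back-projection uses
linear interpolation. All 360° of data are used without 180° folding, since
opposing views differ under defocus asymmetry; reconstructing from a
uniformly-spaced 180° subset is supported, and a full turn equals the mean
of its two half-turns by linearity. Slices are width × width with the axis
at the centre; division by the pixel size gives attenuation in 1/µm.

The rotation axis is found by scanning candidate offsets (±20 px in 1 px
steps by default), reconstructing a small set of sample rows at each, and
maximizing the mean image variance — the sharpest reconstruction marks the
true axis. The discrete maximum is refined by a parabolic fit through its
neighbours. Two departures from a literal reading of the protocol, both
because the original search parameters are unpublished: the five sample rows
are spaced evenly across *content-bearing* rows (rows whose projections
exceed 5% of the global maximum) rather than the full field of view, and a
maximum on the scan boundary is refused with advice to widen the range. The
variance metric is only locally unimodal: far from the axis, strongly
ghosted reconstructions can raise the variance again, so the search range
must bracket the true offset (its stated precondition).

## Registration

**SPIM-to-tomography alignment.** The two modalities share the detector, so
x and y are inherently aligned and only the stack's z origin relative to
the rotation axis is unknown. Following the two-view protocol, stacks at θ
and θ+90° are compared: the rotated stack is axis-permuted so its stack-z
axis maps onto the reference's x axis, and a single 1D normalized
cross-correlation scan recovers the offset with parabolic sub-voxel
refinement. One deliberate deviation: the axis offset is a property of the
shared translation stage and displaces the reference stack along z *and*
the permuted stack along x by the same amount, so the implementation
compensates both with the single scan parameter. A consequence is that the
recovered offset is independent of which view is called the reference
(swapping the inputs returns the same value, not its negation); the tests
assert this order invariance. Correlation peaks below 0.2 are refused as
insufficient mutual structure.

**Sphere landmarks.** Eye lenses are detected by a spherical Hough vote:
voxels whose gradient magnitude exceeds half the 98th-percentile vote along
their inward gradient direction at each candidate radius, and scores are
vote counts normalized by the sphere surface 4πr². The volume is smoothed
with a σ = 1 voxel Gaussian first — on crisp synthetic volumes the discrete
gradient directions otherwise quantize to the 26 lattice directions and the
votes stop converging. The original detector is cited to prior work and not
described; any detector meeting the stated recovery precision is acceptable,
and this one recovers phantom sphere centres to well under a voxel.

**Time-lapse registration.** Two eye centres fix four of the six rigid
degrees of freedom; the rotation about the inter-eye axis is unconstrained.
The third constraint is a dorsal-direction hint, by default the direction
from the eye midpoint to the volume's intensity centroid (the body mass
sits dorsally of the eye axis in this geometry); how this ambiguity was
resolved originally is not documented. The transform maps eye midpoint to eye
midpoint and eye axis to eye axis, so eye-distance growth leaves it rigid
with a per-eye residual of half the distance mismatch. Time points whose
landmark detection fails are flagged and passed through untransformed.

**Segmentation.** Seeded region growing accepts 26-connected voxels while
the local gradient stays below a threshold. The gradient is measured as the
discrete directional derivative along each step rather than the central
difference magnitude at the voxel: this places the region boundary exactly
on the intensity edge (a central-difference criterion systematically erodes
the region by the stencil width) and prevents diagonal leaks across thin
gradient shells. A threshold of zero therefore keeps only the seed, and the
mask is independent of the seed's position within a homogeneous region.

## The synthetic world, and what a green test establishes

Generator defaults follow the published acquisition: NA 0.3 and δz = 15 µm,
20 rotations at 1°/frame (7200 frames, 360 projections, reduction factor
20), ~500 µm of focal travel, SPIM z-spacing 2 µm. Values the source leaves
open were fixed once at realistic levels: sample-side pixel pitch 2.5 µm
(≈ 0.65 mm field of view at 256 px), background/dark 3000/100 counts with
read noise σ = 20 counts, tissue attenuation 0.002–0.012 µm⁻¹ (weak body,
strong lens), and the demonstration phantom is an ellipsoidal "head" with
two strongly attenuating, fluorescent eye spheres.

The simulator deliberately omits refraction, scattering, shot noise,
chromatic effects and the instrument's true PSF. Green tests therefore
establish that the *algorithms* are correct against their own stated forward
model — chord-length projections, disk reconstructions within a few percent,
sub-pixel axis recovery, sub-voxel landmark localization — not that the
model captures every physical effect in a living embryo. Runtime envelopes
mirror the real instrument's scale: the full 7200-frame × 256² simulation
plus fusion runs in ~3 minutes on a single CPU of this reference container
(the real acquisition takes < 2 minutes).

## Numerical choices and degenerate inputs

* Gaussian kernels are truncated at 3.5σ and renormalized at borders, so
  constants are preserved exactly and focus weights of flat images vanish
  (to squared machine precision).
* Transmittance is floored at 10⁻⁶ before the log; fully opaque pixels
  saturate instead of producing infinities.
* FFT padding for the ramp filter is ≥ 2× the detector width, eliminating
  circular-convolution wrap.
* Frame TIFFs are 16-bit (rounded, clamped); projections, volumes and masks
  are float32/uint8 multi-page TIFFs with JSON sidecars rather than TIFF
  tags, for toolchain portability. The minimal TIFF reader/writer is
  implemented in the package because the installed R stack has no TIFF
  package; files are baseline little-endian TIFF readable by Fiji or
  tifffile.
* All randomness (read noise, correction-frame noise) derives from one seed
  through per-angle substreams, so streams are reproducible regardless of
  consumption order and the whole pipeline is byte-deterministic.

## Known limitations

Cone-beam effects, iterative reconstruction, ring-artifact removal,
deformable registration, multiview deconvolution and tiled acquisitions are
out of scope. The EDoF filter and the segmentation/eye-detection procedures
are reconstructions of supplementary-only methods and may differ from the
original in parameters while meeting the same stated behavior.
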