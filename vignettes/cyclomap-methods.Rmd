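---
title: "Methods: cylindrical initial models, docking and ring geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cylindrical initial models, docking and ring geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclomap)
```

This vignette records the model choices behind each module: what is
computed, which parameters matter, what the synthetic generators do and do
not emulate, and where the design was genuinely open. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The Fourier sweep and its assumptions

The initial-model generator assumes that a single 2D class average is a
*side view*: a projection along a direction perpendicular to the particle
long axis. Under the projection-slice theorem, its 2D Fourier transform is
then a central slice of the particle's 3D transform containing the axial
frequency axis. Rotating (sweeping) this slice about that axis produces
the transform of the *rotationally averaged* particle — the best
cylindrically symmetric approximation obtainable from one view, and a
deliberately self-consistent, low-bias reference for 3D classification.

Implementation choices:

* **Mirror symmetrization** (`symm_params(mirror_symmetrize = TRUE)`). The
  swept spectrum is a function of in-plane radius only, so it can satisfy
  Friedel symmetry — and hence invert to a real volume — only if the slice
  is even in the in-plane frequency. We therefore average the image with
  its mirror about the long axis first. This is forced by mathematics, not
  taste: without it the imaginary residue of the inverse transform is
  reported and the result is a warning, not silent data loss.
* **Interpolation.** The radial profile is sampled at integer Fourier-pixel
  radii and evaluated at arbitrary radii by *linear interpolation between
  adjacent samples*; radii beyond the sampled support are zero, and the
  unpaired Nyquist planes are zeroed to keep the spectrum strictly
  Hermitian. Linear interpolation convolves the radial spectrum with a
  one-pixel triangle kernel, which multiplies real-space features at
  radius r by roughly sinc²(πr/L) (L = box edge). The error is therefore a
  *padding* question: with the particle radius below ~0.15 L the
  round-trip error against both the analytic phantom and an independent
  inverse-Abel oracle is below 5% NRMS, and a 37° real-space rotation
  changes the output by < 2% RMS (both measured in the test suite at
  96–128-voxel boxes). Heavier padding reduces it further.
* **Centering.** Alignment uses the centre of mass and principal axis of
  the median-subtracted, positivity-clamped image; rotation/shift are
  applied in one bilinear resampling pass and recorded in attributes.
  Near-constant images cannot be centred; `make_initial_model` warns and
  sweeps them as-is (the result is a featureless artifact by
  construction).
* **Band limiting.** Both the input (default 120 Å) and the finished model
  (120 Å) are low-pass filtered, mirroring the practice of handing heavily
  band-limited references to classification so that the reference cannot
  imprint high-resolution features.

## Filters and resolution arithmetic

The low-pass transfer function is 1 up to the cutoff frequency and falls
as a half-cosine over an `edge_width` of 3 Fourier pixels (a standard
soft edge; upstream processing suites do not publish their window, so the shape is
a documented package choice). DC is
passed exactly, so the mean is preserved. Note that a soft-edged filter is
*not* strictly idempotent: reapplying it attenuates the edge band again
(by up to 25% in amplitude). The tests therefore assert the exact form of
idempotence that does hold — content strictly inside the passband is
untouched, the stopband is annihilated — rather than a loose RMS bound.

Nyquist arithmetic is the identity `resolution = 2·pixel_size / fraction`;
at 1.8 Å/pixel a quarter of Nyquist is 14.4 Å.

## Simulated density and docking

Atoms are single isotropic Gaussians, σ = resolution/(π√2) (Fourier
amplitude halved at 1/resolution), amplitude ∝ atomic mass, each kernel
discretely normalized so total density equals total mass exactly. The
σ-constant is exposed because commonly used implementations of this
conversion do not publish their constant; scattering-factor form factors,
CTF and B-factors are out of scope.

Docking scores are plain normalized cross-correlation with whole-box
statistics, computed over all translations by FFT (validated against
direct-space computation to 1e-6). The orientation grid is cos β-uniform
in zyz Euler angles; everything is deterministic and ties break
lexicographically. Local refinement runs coordinate-wise golden-section
searches on the angles and parabolic sub-voxel interpolation on the shift,
and a refined candidate is never allowed to score below the grid candidate
it started from (the final score re-renders the probe at the fractional
pose). Multi-copy fitting masks each placed copy at its rendered half-max
isosurface dilated 2 voxels with a 2-voxel cosine edge, then refits;
clashes are atom pairs closer than 2 Å, counted by spatial hashing. The angular step, scoring variant and refinement protocol are explicit
arguments rather than hidden defaults.

## Ring geometry

The conformational metric fits a total-least-squares plane through six
anchor points (one per subunit; by default the subunit COM, optionally the
centroid of a stored residue selection standing in for the nucleotide
pocket — bound-nucleotide positions are the natural anchors when present).
Azimuths are measured about the anchor centroid in the fitted plane; the
six adjacent gaps sum to 360° exactly, the opening angle is the largest
gap, and axial displacements are signed distances to the plane. A closed
planar hexamer reads 60°; the closed and open nucleotide states of
such hexamers typically read near 58° and 81°, so the 60° consistency
check is built into the planar phantom test.

One subtlety is worth recording: for an *open* ring, anchors at constant
radius about the ring centre do not have their centroid at that centre, so
"gap about the centroid" and "gap about the ring centre" differ by a few
degrees. The package measures about the centroid (robust when no symmetry
axis is known). The phantom generator therefore defines its ground truth
in the same frame: anchor radii are minimally perturbed (least squares) so
the centroid falls on the axis, and the natural linear rise ramp is
replaced by its constrained projection with zero in-plane moments — the
fitted plane then stays exactly perpendicular to the axis and the
programmed (gap, rise) pair is exactly what the measurement recovers,
which the 5×5 sweep test checks to (0.5°, 0.5 Å).

Map-space morphology metrics binarize at a stated threshold (default 0.5 ×
the relevant maximum — the deposition contour levels are unpublished, so
every extent output carries its threshold): per-slab COM bending curves
with a chord-deviation bend score, caliper section diameters (centre
distances plus half a pixel footprint along the caliper direction), lumen
diameters as equivalent-circle diameters of the enclosed background
component containing the axis, axial extent including the footprint of the
outermost occupied sections, and a gate state that calls a region "open"
only if an axis-containing background channel runs through every section
(slice-wise openness of an axis-containing lumen implies 3D continuity).

## FSC machinery

Shells are 1 Fourier pixel wide, DC excluded; the correlation is the real
part of the normalized cross-spectrum per shell. Resolution is the first
downward crossing of the threshold (0.143 for half maps), linearly
interpolated. Soft masks binarize at a fraction of the maximum, dilate,
and fall off as a cosine of the Euclidean distance (computed by an exact,
range-clamped separable distance transform); mask parameters are attached
to the mask object so any reported resolution can carry them. No
phase-randomization mask-bias correction is implemented — at the 15–21 Å
scale this package targets, mask bias is small, but masked resolutions
should be quoted with their mask parameters.

## What the synthetic generators do and do not emulate

The hexamer phantom reproduces the *geometry* of an elongated AAA+
protease: overall length 230 Å, head 143 Å across, a short 93 Å trimeric
neck, three pairs of tiered leg blobs, six rigid chiral 8-blob pseudo
subunits on a ring with programmable conformation, and an axial gate that
is capped in the planar state and open in the lock-washer state. Extreme
blobs are placed so their half-maximum touches the nominal envelope,
making designed lengths recoverable at the 0.5 threshold. It does **not**
emulate: realistic protein texture (a flag can swap in a rendered crystal
structure if one is locally available, but nothing downloads), the narrow
15 Å channel inside the blob-built neck (the neck channel of the phantom
is wider; dedicated annulus phantoms test the lumen metrics at exactly
15 Å), CTF, ice, or beam-induced motion. A green test therefore
establishes the correctness of the *measurement machinery* on known
geometry, not performance on experimental micrographs.

Projection sets define SNR as signal variance over noise variance inside
the particle support (pixels above 5% of the projection maximum) — whole
frame SNR would depend on the padding. Half-map pairs colour independent
Gaussian noise per shell to a designed SSNR, making FSC = SSNR/(SSNR+1) a
closed-form oracle; the designed 0.143 crossing is recovered within one
shell in the acceptance suite. Generators are pure functions of
(spec, seed).

## Known limitations

* The Fourier sweep inherits the radial-interpolation smoothing described
  above; it is accurate for generously padded boxes and degrades gracefully,
  never catastrophically, for tight ones.
* Whole-box NCC is global: for a small probe in a large map the scores are
  far from 1 even for perfect fits (the six-copy tests assert recovery of
  the poses, not absolute score values).
* `read_structure` handles fixed-column PDB and the common mmCIF
  atom_site loop only; exotic CIF quoting is not supported.
* Masked FSC carries mask bias (no phase randomization); resolutions from
  masked maps are comparable only at matched mask parameters.
* Checks against deposited experimental maps are not run in this
  repository (downloads would be required); the geometry machinery they
  would exercise is covered by the phantom sweeps.
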