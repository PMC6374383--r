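---
title: "Methods: serial-section reconstruction and label-retention quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial-section reconstruction and label-retention quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iftomo)
```

## The problem

Immunofluorescence tomography reconstructs a tissue volume by physically
cutting plastic-embedded tissue into thin serial sections (2 µm), immuno-staining
and imaging each section in 2-D, and computationally reassembling the ordered
images into a 3-D volume. The axial resolution of the reconstruction is the
physical section thickness; the lateral resolution is the camera pixel pitch
(0.44 µm with a 20x objective). Because sections land on slides with arbitrary
in-plane shifts and rotations, and large sections are acquired as overlapping
mosaic tiles, the computational pipeline has four stages: tile stitching,
rigid slice-to-slice registration on the DAPI channel, volume assembly with
anisotropic voxels, and 3-D quantification of cell sub-populations.

The biological readout this package targets is label retention. In the
H2B-GFP/K5tTA pulse-chase system, epithelial nuclei express a histone-bound
GFP during the pulse; during the doxycycline chase the label is diluted by
50% at each cell division, so retained intensity indexes quiescence:

$$I(k) = I_0 \cdot 0.5^{\,k}$$

after $k$ divisions. On the 8-bit imaging scale, label-retaining cells (LRCs)
are graded **low** $[0, 100)$, **mid** $[100, 200)$ and **high** $[200, 255]$.
The bins are half-open with the top bin closed because the high class is
defined as "200 and above"; the same convention is applied at the 100
boundary. `classify_bin()` maps every representable 8-bit value to exactly one
bin.

## The synthetic phantom

Real reconstructions cannot be regenerated without the original slides, so
every stage is validated against a synthetic serial-section phantom
(`generate_phantom()`) with complete ground truth. The phantom emulates:

* a 3-D tissue of spherical nuclei (solid spheres, optional 1-px linear rim
  falloff) placed by rejection sampling so that no two nuclei touch — not just
  in 3-D, but after slab projection: cells whose z ranges come within two slab
  thicknesses of touching must also be separated laterally, because the
  26-connectivity labeling links adjacent z layers;
* per-cell division counts (uniform integers `0..divisions_max`) and the GFP
  dilution law above, plus per-cell DAPI brightness drawn from a range, the
  way chromatin density varies between real nuclei — constant-brightness
  phantoms are *easier* for segmentation but *harder* (and unrealistic) for
  registration, because identical round blobs are interchangeable;
* physical sectioning at 2 µm: each section is the maximum-intensity
  projection of the analytic nucleus profile through its slab, matching
  widefield imaging of a section thin enough that every nucleus is in focus;
* per-section rigid misplacement (uniform within a configured range, rotation
  about the image centre, section 1 unperturbed as reference), rendered
  analytically in the misplaced frame so no interpolation error enters the
  ground truth;
* 10%-overlap mosaic tiling with optional integer jitter of the true tile
  origins;
* additive constant background and additive Gaussian noise, then 8-bit
  quantization (round half up, clip). Poisson noise, optics (PSF, depth
  blur), bleaching and section folds are deliberately out of scope.

Defaults are the acquisition values above (2 µm, 0.44 µm, 10% overlap,
initial intensity 255) plus realism choices made once: nucleus radii
3–4.5 µm (typical epithelial nuclei), DAPI brightness 150–230, background 5,
noise SD 3, misalignment up to ±5 px / ±2°. The GFP background of fully
diluted cells is not a measured quantity and is exposed as a parameter.

Because the generator is analytic, two regimes are useful. The *default*
regime (soft nucleus rims, noise, background) stresses registration and
stitching realistically. The *analytic* regime (`edge_softness_px = 0`,
`noise_sd = 0`, `background_level = 0`, no misalignment) makes rasterization
exactly invertible — every in-nucleus voxel carries the exact quantized cell
intensity — so segmentation and binning can be compared with the truth table
*exactly*, not approximately. With a soft rim the per-object **mean** intensity
(the binning statistic) is geometrically diluted below the cell's true value,
which is one reason mean-based grading of real data is an interpretation, not
ground truth. The truth-table oracle applies the same round-half-up
quantization as rasterization before binning, since that is part of the
stated generation model (a cell at true intensity 0.996 quantizes to 1 and is
correctly counted as a faint LRC).

Passing phantom tests therefore shows the pipeline is internally correct under
its own acquisition model; it does not certify performance on real tissue with
optical blur, staining variation, debris or touching nuclei.

## Registration

`register_pair()` finds the rigid transform (translation + rotation about the
image centre, degrees counter-clockwise, 0-based pixel coordinates) mapping
one DAPI image onto another:

1. both images are Gaussian-smoothed (σ = 1 px);
2. rotation is scanned coarsely at 0.5° steps over the configured range; for
   each candidate angle the translation is found at the peak of the **exact
   masked normalized cross-correlation surface**, computed with FFTs over a
   zero-padded grid so the mean/variance statistics at each shift use only the
   genuinely overlapping pixels (Padfield-style masked NCC). Whitened phase
   correlation (`phase_correlate()`) is provided as a fast path but is not
   used in the search: normalizing the cross-power spectrum amplifies
   high-frequency noise and fails outright at realistic noise levels, whereas
   the NCC surface degrades gracefully;
3. candidate placements must share at least `overlap_ratio` (default 0.5) of
   the image area. This guard matters for fields of look-alike nuclei, where
   a small spurious overlap can correlate strongly under a wrong
   correspondence;
4. the best angle is refined locally (golden-section/parabolic), translation
   refined to sub-pixel by quadratic peak interpolation, and finally
   (tx, ty, θ) are polished jointly by box-constrained L-BFGS-B on the
   continuous correlation objective;
5. the score is the peak correlation; below `confidence_floor` (0.1) the pair
   is flagged and contributes the identity — recorded, never dropped. Re-probe
   fusion (`fuse_reprobe()`) treats a flagged registration as an error
   instead, because silently misaligned channel fusion would corrupt
   co-localization.

The model is rigid only: sections are physical slices of one block and no
deformable correction is attempted. Stacks are aligned by consecutive-pair
chaining from a reference section (`align_stack()`), so per-pair errors
accumulate as a random walk along the stack; the joint polish step keeps the
per-pair error small enough that 50-section stacks stay within a few pixels
end-to-end.

Chaining has one genuine failure mode: a consecutive pair that shares only a
handful of look-alike nuclei can register to a wrong correspondence that
*out-scores* the true pose — no pairwise metric can rescue it, because the
information simply is not in the pair. Redundant skip-edges (registering
section `i` against `i - 2`) do not help either: sections 4 µm apart share
even less content and mismatch far more often. What does work is exploiting
two things the pair does not have: a known property of the acquisition — each
section's absolute misplacement is bounded (the collection geometry limits
how far a section can land from its nominal pose) — and the aggregate content
of the stack. When `max_abs_translation` / `max_abs_rotation` are supplied,
`align_stack()` checks every chained absolute translation against the bound
(plus a 5 px drift allowance; rotation is not used for triggering because
rotational drift, unlike a correspondence jump, approaches its bound slowly).
A wrong pairwise link offsets the entire downstream block by one rigid
transform, so the first violating section marks the broken link. Candidate
corrections come from registering the next few raw sections directly against
the last in-bounds aligned section under the absolute bound; a correction is
accepted only when two independent candidates agree (wrong correspondences
rarely agree with each other) or a single candidate is unambiguous, and it is
then applied to the whole downstream block, preserving the block's good
relative transforms exactly. When no trustworthy correction exists — content
this sparse sometimes admits none — the chain is left as estimated and the
broken link stays flagged for manual review rather than being silently
"fixed". Without the bound the aligner is plain chaining.

A `running_mean` reference mode (register each section against the mean of
the previously aligned `k` sections) is implemented as an option; with sparse
nuclear content it performs *worse* than chaining, because nuclei persist
only a few sections and the averaged reference shares little content with the
incoming section — it is therefore off by default. Interpolation is bilinear,
applied exactly once per section from the absolute transform, out-of-bounds
filled with 0.

## Stitching

Tiles are laid out row-major; the tile size is the smallest integer `w` with
`cols·w − (cols−1)·overlap·w ≥ width`, origins spread evenly from 0 to
`width − w` (so a 100-px section in a 1×2 grid at 10% overlap gives 53-px
tiles with the second origin at 47). `estimate_offset()` refines a pair's
relative offset by direct normalized cross-correlation over integer offsets
within a search radius, with quadratic sub-pixel interpolation; the
confidence is the peak correlation, invariant to affine intensity rescaling.
A flat (zero-variance) overlap cannot be refined and falls back to the
nominal offset with confidence 0 and a warning. `refine_layout()` places each
tile against its left and top neighbours, resolving conflicts by
confidence-weighted averaging, with tile 1 pinned at the origin and refined
origins clamped to the search radius. Stitching is translation-only (tiles
come from one motorized scan of one section); blending is either `overwrite`
or `feather` (linear distance-to-border ramp, weights normalized to 1), both
of which reproduce the source exactly when tiles are exact crops placed at
their true offsets. Blending happens in floating point and is re-quantized
(round half up) once at the end. Illumination correction and lens distortion
are out of scope.

## Volume and quantification

`assemble()` stacks aligned sections along z with axis order fixed as
(channel, z, y, x) in every contract; the z voxel size is the section
thickness, so the axial extent is always `n_sections × thickness` (379
sections at 2 µm span 758 µm). No isotropic resampling is done — the axial
resolution *is* the section thickness and is preserved. Storage is one
multi-page TIFF per channel plus a JSON sidecar (`volume.json`) for geometry;
the round-trip is bit-exact for 8- and 16-bit data, and a missing sidecar
degrades to unknown voxel size with a warning.

`segment_nuclei()` binarizes the chosen channel (foreground strictly above
the threshold; fixed value for reproducibility or Otsu's method on the
histogram, since the acquisition protocol names no specific algorithm),
labels 3-D connected components under 26-connectivity (compiled flood fill),
and discards components smaller than `min_volume_voxels` — by default the
voxel volume of a sphere of the smallest configured nucleus radius, which
suppresses noise specks deterministically. Raising the threshold never
increases foreground voxels, but the *object count* is not monotone (objects
can split), which is why the three-threshold mean (`multi_threshold_count()`,
arithmetic mean of the counts at three increasing thresholds) is the more
stable cell-number estimate. The three threshold values are explicit inputs;
the protocol that motivates the average does not state them.

Per-object intensity is the **mean** over the object's voxels (stable under
noise; the maximum would be exact on hard-edged phantoms but fragile on real
data). An object is an LRC when its mean label-channel intensity reaches
`lrc_floor` (default 1, i.e. any signal above a zero background); the
positivity criterion before binning is genuinely unspecified in the source
protocol, so it is a parameter. Percentages are reported as nearest-integer
(round half up) of the LRC total — the worked example 20/31/40 of 91 gives
22/34/44 — with raw fractions alongside. Conservation (bins sum to the LRC
total, which never exceeds the nucleus total) is asserted in every report.
Touching nuclei are not split (no watershed in this version); the phantom's
placement rule generates non-touching nuclei, and this is a documented
limitation for dense real tissue.

## Numerical choices

* 8-bit quantization is round-half-up then clip — deterministic and
  independent of the platform's banker's rounding.
* 0-based pixel coordinates, origin at the top-left pixel centre, x = column,
  y = row; rotation about the image centre `((W−1)/2, (H−1)/2)`; angles in
  degrees counter-clockwise. Composition and inversion of transforms are
  closed-form and exact (`compose(T, inverse(T))` is the identity to 1e−9 or
  better).
* FFT pad sizes are rounded up to 2-3-5-smooth integers; a prime-sized FFT in
  R is quadratic and an order of magnitude slower.
* Micrometre positions map to pixel coordinates as `x/pixel_size − 0.5`
  (pixel j covers `[j·px, (j+1)·px)`).
* Degenerate inputs are defined, not accidental: zero-variance images are an
  error for registration, a warned nominal fallback for tile offsets; an
  all-background channel yields zero objects; an LRC total of zero reports
  zero percentages with a flag rather than dividing by zero.

## Problem sizes used in the tests

The validation suite runs entirely on phantoms generated at test time:
registration recovery uses 50 sections of 128×128 px with 80 nuclei,
misplacements up to ±15 px / ±5° and noise SD at 5% of the 8-bit range;
stitching exactness uses 2×2 and 8×8 tilings of a 256×256 px section;
quantification equivalence uses 200 non-touching nuclei with division counts
0–8 in a 110×110×60 µm volume. These sizes exercise every code path at
full algorithmic fidelity while keeping a complete validation run in the
minutes range on a single CPU; all of them scale linearly if larger phantoms
are wanted.

## Known limitations

* Rigid alignment only; compressed, folded or missing sections are not
  modelled or corrected, and a complete ordered section set is required.
* No optics simulation in the phantom; tests cannot reveal sensitivity to
  depth blur or chromatic shift.
* Mean-intensity binning under-grades objects with soft rims (see above).
* Stitching assumes a connected tile graph and translation-only offsets.
* Drift over very long stacks is bounded but not eliminated; a global
  (bundle-adjusted) alignment is out of scope.
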