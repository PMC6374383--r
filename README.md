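# iftomo

3-D reconstruction and quantification for **immunofluorescence tomography**:
tissue embedded in plastic is physically cut into 2 µm serial sections, each
section is immuno-stained and imaged in 2-D (0.44 µm pixels, mosaic tiles at
10% overlap for large sections), and the ordered images are computationally
reassembled into a volume whose axial resolution is the section thickness.
`iftomo` implements the computational half of that workflow for R users:

* **stitching** — mosaic tiles placed on their nominal grid, offsets refined
  by normalized cross-correlation, feather or overwrite blending;
* **registration** — rigid (translation + rotation) slice-to-slice alignment
  on the DAPI channel via an exact masked-NCC search with sub-pixel
  refinement, consecutive-pair chaining, and optional repair of broken links
  using a known bound on per-section misplacement; re-probed imaging rounds of
  the same section are fused on DAPI so a section can carry more than four
  fluorescent channels;
* **volume assembly** — anisotropic voxels (x, y = pixel pitch; z = section
  thickness), per-channel multi-page TIFF storage with a JSON geometry
  sidecar;
* **quantification** — 3-D nucleus segmentation (thresholding + 26-connected
  components), grading of label-retaining cells (LRCs) by GFP intensity, and
  object counting averaged over three thresholds.

The biological readout is H2B-GFP label retention: nuclear GFP halves with
every cell division,

```
I(k) = I0 * 0.5^k
```

so after a chase period the retained 8-bit intensity indexes quiescence.
LRCs are graded **low** [0, 100), **mid** [100, 200) and **high** [200, 255];
per-bin percentages are reported against the LRC total (the published
hair-follicle example — 20 high, 31 mid, 40 low of 91 LRCs among 654 nuclei —
gives 22% / 34% / 44%).

A synthetic serial-section **phantom generator** with complete ground truth
(nucleus positions, division counts, true intensities, per-section rigid
misplacements, true tile origins) makes every stage testable without real
slides; see `vignette("iftomo-methods")` for the model, its assumptions and
its limits.

## Worked example

Simulate a small tissue (30 nuclei, 10 sections of 2 µm, per-section
misplacement up to ±5 px / ±2°), align, assemble and quantify:

```r
library(iftomo)

cfg <- list(seed = 7L, log_level = "quiet",
            phantom = list(n_cells = 30L, tissue_extent = c(88, 88, 20),
                           misalignment_range = c(5, 5, 2)),
            register = list(max_rotation = 4))
res <- run_pipeline(cfg, output_dir = "demo_out")
res$volume
res$report
```

```
if_volume: 2 channel(s) [DAPI, GFP], 10 x 200 x 200 (z,y,x) voxels
  voxel size 0.44 x 0.44 x 2 um (x,y,z); z extent 20 um
cell_count_report: 30 nuclei, 30 LRCs
  low     21  (70%)
  mid      3  (10%)
  high     6  (20%)
```

All 30 simulated nuclei were found after alignment; every nucleus carries
some GFP (division counts 0–6, so even the most-divided cells retain
255 × 0.5⁶ ≈ 4 intensity units, above the default LRC floor of 1), and the
low/mid/high split reflects how many divisions each cell went through: the
6 high-graders are the undivided cells, the 3 mid-graders divided once, and
the 21 low-graders divided twice or more. The
written artifacts under `demo_out/` include the aligned sections, the volume
(`vol/channel_*.tif` + `volume.json`), the per-object table
(`report/objects.csv`), the summary (`report/summary.json`) and `run.json`
with the resolved configuration and seed — identical config and seed
reproduce every file bit for bit.

Stage functions are usable on their own (`generate_phantom()`,
`tile_section()`, `estimate_offset()`, `stitch()`, `register_pair()`,
`align_stack()`, `fuse_reprobe()`, `assemble()`, `segment_nuclei()`,
`classify_bin()`, `count_subpopulations()`, `multi_threshold_count()`), and a
thin command-line wrapper with subcommands `simulate`, `stitch`, `align`,
`assemble`, `quantify` and `run` is installed at
`system.file("cli", "iftomo.R", package = "iftomo")` (exit codes: 0 ok,
2 validation error, 3 stage failure).

### Configuration schema

`run_pipeline()` and the CLI take a nested YAML/JSON configuration whose
fields mirror the function defaults; unknown keys are rejected before any
work starts, and the resolved configuration is written to `run.json` next to
the outputs. `default_config()` returns the full tree:

| key | meaning |
| --- | --- |
| `seed` | drives every stochastic step; same config + seed = identical output |
| `log_level` | `info` or `quiet` |
| `input_dir` | section directory when `stages.simulate` is off |
| `output_dir` | artifact directory |
| `stages.{simulate,stitch,align,assemble,quantify}` | stage toggles |
| `phantom.*` | all [`phantom_config()`] parameters (tissue extent, cells, radii, thickness 2, pixel 0.44, dilution, noise, misalignment, tiling) |
| `stitch.{blend,search_radius,channel}` | mosaic reassembly |
| `register.*` | all [`align_stack()`] parameters (channel DAPI, rotation/translation bounds, confidence floor 0.1, optional absolute misplacement bound) |
| `quantify.*` | segmentation channel/threshold, min object volume, LRC channel/floor, bin edges `0,100,200,255`, optional three thresholds for the averaged count |

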