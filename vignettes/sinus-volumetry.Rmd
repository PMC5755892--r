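---
title: "Automated maxillary sinus volumetry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated maxillary sinus volumetry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

The maxillary sinuses are the paired air cavities in the maxillary bone.
Their total volume, and the split of that volume into air and
*involvement* (mucosal thickening, cysts, retained fluid), is a clinically
useful quantification of sinus disease: it correlates with rhinosinusitis
severity better than categorical radiological scores, and it is the
quantity of interest when tracking treatment response or planning sinus
floor elevation. Manual slice-by-slice tracing on CT is the reference
standard but takes a radiologist on the order of two hours per exam;
`sinusvol` implements a fully automated alternative that runs in a few
seconds per exam and reports per-sinus total, air, and involvement
volumes in cm^3^, together with the surface mesh and a label map for
review.

# The segmentation model

The pipeline is deliberately per-slice: CT exams of the paranasal sinuses
are reconstructed with sub-millimetre in-plane resolution and the sinus
appears as a bone-enclosed low-attenuation region on every axial slice
through it. Each slice is processed as

1. **Bone thresholding.** Voxels with HU ≥ 150 are marked as bone
   (`threshold_bone()`). On the Hounsfield scale, air is ≈ −1000 HU, soft
   tissue and sinus involvement fall between roughly −200 and +80 HU, and
   mineralised bone lies well above +150 HU, so this threshold isolates
   the bony sinus walls while removing mucosa, fluid and soft tissue.
2. **Morphological opening.** The bone mask is opened with a disk of
   radius 2 px and connected components below 20 mm² are discarded
   (`morphological_open()`). At ≈ 0.3 mm pixels the disk is ≈ 0.6 mm,
   large enough to erase noise speckle and thin artefactual bridges but
   far smaller than any sinus wall. Opening removes structure; it cannot
   close gaps. A closing step would be the natural complement for
   dehiscent walls, but the cleaned mask is used only as a flooding
   barrier, so small wall gaps are already tolerated by the watershed
   ridge structure.
3. **Watershed partition.** The slice's HU image, smoothed by a Gaussian
   with σ = 1 px, is treated as a topographic surface and flooded from
   its minima (`watershed_partition()`, implemented in C++). Air
   cavities are deep basins; bone walls are the ridges between them. The
   cleaned bone mask is imposed as barrier pixels that flood last and
   attach to an adjacent basin, so the output is a *complete partition*:
   every pixel gets exactly one basin label.
4. **Rule-based selection.** Per-basin geometric features — area,
   centroid, solidity, side of the sagittal midline — feed a small rule
   system (`select_sinus_basins()`) that encodes where and what a
   maxillary sinus is: area within [50, 3000] mm², centroid within a
   lateral band of 5–45% of the image width from its side's edge (this
   excludes both the image border and midline structures such as the
   nasal cavity), centroid within 25–85% of the image height, and
   solidity ≥ 0.6. When both sides survive, two symmetry rules apply:
   area ratio ≤ 3 and mirrored-centroid distance ≤ 15 mm.
5. **Propagation.** The pipeline is seeded on the middle slice of the
   stack (searching outward over ±25% of the stack if the middle slice
   yields nothing) and walks upward and downward, independently per side
   (`propagate_sinus()`). On each new slice a basin must pass the
   per-side rules *and* overlap the previous accepted slice with Dice
   ≥ 0.3; the walk stops at the first failing slice. The result is a
   contiguous 3D region per sinus.
6. **Air/involvement banding.** Region voxels with HU in [−1200, −200]
   are air; voxels in (−200, 150) are involvement; voxels at or above the
   bone threshold (intruding septa) or below −1200 (artefact) are
   excluded (`classify_air_involvement()`). Volumes are voxel counts
   times the voxel volume, so total = air + involvement exactly.

## Numerical choices worth knowing about

* **Flooding with basin merging.** Plain regional-minima flooding
  over-segments a noisy image: at 15 HU noise each cavity would fragment
  into many shallow basins and no candidate would ever satisfy the area
  rules. The flood therefore merges any basin whose *dynamics* (saddle
  height above its minimum) is below 100 HU into its deeper neighbour,
  which is the flooding-order equivalent of imposing h-minima markers
  with h = 100 HU. Noise pools (depth ~tens of HU) merge away; cavities
  (walls rise ≳ 1500 HU above the floor) always survive. The value is a
  parameter (`merge_depth_hu`), safe anywhere between ~3× the noise SD
  and a few hundred HU.
* **Band conventions.** The bone threshold is a closed lower bound
  (HU = 150 is bone); the air band is closed at both ends; involvement is
  the open interval between the air band and the bone threshold. These
  choices make the three classes a deterministic partition of the
  region.
* **Tie-breaking.** Among equal-area surviving basins the smallest basin
  id wins; ids are assigned in flooding order, which is deterministic.
  The whole pipeline contains no randomness: a fixed input and parameter
  set give a bit-identical label map on every run.
* **Solidity on a raster.** Solidity is the pixel count of the region
  over the number of lattice points inside its convex hull, clamped to 1,
  so a convex raster region scores exactly 1 regardless of resolution.
* **Stopping rule.** The walk stops at the *first* slice without an
  acceptable basin — no gap tolerance. A single corrupted slice therefore
  truncates the region; in practice the accepted-slice Dice floor of 0.3
  is loose enough that this has not been observed on phantoms at
  realistic noise.

# The synthetic phantom

There is no public reference dataset for this task, so validation runs
against a parametric phantom (`phantom_spec()`, `generate_phantom()`)
with analytically known truth. It emulates the features the pipeline
actually keys on: two ellipsoidal air cavities (HU −1000) with 1.5 mm
bone shells (HU 700) embedded in soft tissue (HU 40), an optional
mucosal lining modelled as the shell between the cavity ellipsoid and an
inner ellipsoid with semi-axes reduced by the lining thickness (HU 30),
an optional dependent fluid layer filling the lowest fraction of the
cavity's slices, a midline low-HU decoy channel standing in for the
nasal cavity (so the lateral-band rule is genuinely exercised), additive
Gaussian HU noise, and anisotropic spacing of (0.5, 0.35, 0.35) mm on an
80 × 256 × 256 grid.

Default cavity semi-axes are (14, 20, 11.5) mm — about 13.5 cm³ per
sinus, inside the 10–25 cm³ range reported for adults. The validation
cohort (`cohort_specs()`) draws per-axis scale factors from ±15%,
centre jitter of (1, 3, 2) mm, lining thickness from 0.5–2.5 mm and
fluid fraction from 0–0.25, giving truth volumes spanning roughly
8–20 cm³. Rotation is restricted to the slice axis so the fluid cap
volume stays closed-form.

What the phantom does *not* emulate: the scanner point-spread function
(phantom edges are hard, so partial-volume voxels are rare), beam
hardening and streaks, anatomical wall complexity (the ostium, septa,
dental roots), and true pathological texture. Passing the phantom suite
therefore demonstrates the correctness of the algorithm's logic and its
noise robustness, not clinical-grade accuracy on patients; on real exams
the published comparison against manual tracing is the relevant
evidence, and the agreement module exists to reproduce exactly that
analysis on any paired dataset.

# Agreement statistics

`summarize_cohort()` reports, per quantity (total and air-free): the
mean ± SD unsigned percent difference with the reference volume in the
denominator; ordinary least squares of automated (y) on reference (x);
R² as the squared Pearson correlation; and Bland–Altman bias
(automated − reference) with limits of agreement bias ± 1.96 × SD of the
differences (sample SD, n − 1; the multiplier is a parameter, 2.0 being
the other common convention — at two decimal places the two are not
distinguishable on this data). Sinuses are treated as independent
observations, two per exam. The published per-patient table behind the
original validation is not redistributable, so `synthetic_s1_pairs()`
deterministically constructs a synthetic 60-sinus table whose exact
sample statistics round to the published summary values; it exercises
the machinery end-to-end and is labelled synthetic everywhere.

# Problem sizes used in the checks

The test suite exercises the full pipeline on 40 × 128 × 128 phantoms
(≈ 2 s per exam) and reserves the full 80 × 256 × 256 grid for the
30-exam validation cohort, which also backs `scripts/acceptance.R`
(≈ 6 s per exam, a few minutes in total). Voxelisation-error properties
are checked at default spacing and at half spacing on reduced grids
chosen so the half-spacing volume stays ≈ 12M voxels.

# Known limitations

* Per-slice logic: a sinus whose cross-section vanishes on an
  intermediate slice (rare, but possible with severe septation) is
  truncated at that slice.
* The rule thresholds are tuned for adult maxillary sinuses on
  paranasal-protocol reconstructions; other sinuses or paediatric
  anatomy need different `rule_params()`.
* DICOM support covers explicit-VR little-endian single-frame CT only;
  enhanced multi-frame objects must be converted to NIfTI first.
* The surface mesh is the exact voxel boundary (watertight, and its
  divergence-theorem volume equals the voxel-count volume exactly);
  an optional Laplacian smoothing pass exists for display, and
  measurements never come from the mesh.
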