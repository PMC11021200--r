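---
title: "Volumetric quantification for cleared-tissue light-sheet imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric quantification for cleared-tissue light-sheet imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clearvol)
```

## The problem

Whole-body immunolabeling and solvent clearing make an entire mouse
transparent enough for light-sheet microscopy, producing anisotropic 3D
stacks that cover the full animal. Typical downstream questions are
volumetric and spatial: how large are labeled objects such as
micrometastases and tertiary lymphoid structures (TLS), how are they
distributed over organs, how close is each object to its neighbors of the
same or the other class, how dense is a filamentous network such as the
PGP 9.5⁺ enteric plexus, and how deep does an antibody or dye actually
penetrate the tissue.

`clearvol` implements this quantification chain as reusable, tested code:
connected-component labeling and morphometry in physical units,
nearest-neighbor and per-region spatial statistics, skeleton-based filament
density, voxel colocalization, and axial staining profiles — plus a
synthetic phantom generator with exact ground truth, so the whole chain is
verifiable without any microscope data.

## Geometry conventions

All volumes are dense 3D arrays in **(z, y, x)** order with per-axis
physical spacing in µm. The default spacing, `(10, 6.5, 6.5)` µm, mirrors a
whole-body light-sheet acquisition: a 10 µm z-step with finer lateral
sampling, so anisotropy is exercised everywhere rather than treated as a
special case. Voxel indices are 0-based in physical formulas and a voxel's
physical position is its **center**, `origin + index * spacing` with the
default origin at `spacing / 2`. Volumes are reported in mm³
(1 mm³ = 10⁹ µm³) and distances in µm, converted to mm only at reporting
time, matching the units used in whole-body tumor studies.

## Connected components and morphometry

`label_components()` partitions the foreground under 6-, 18- or
26-adjacency with a single raster pass and union-find (path compression),
then renumbers components in first-voxel raster order so labels are
deterministic across platforms. The default connectivity is 26, the common
convention for blob-like objects in 3D; the flag exists because published
pipelines rarely state their choice and library defaults differ.

`measure_objects()` derives per-object voxel count, physical volume
(`count × voxel volume`), the **unweighted centroid of voxel centers** (the
annotations, not the intensities, define the object), the physical bounding
box, a border flag (objects touching the volume face are kept and flagged,
never silently dropped), and the organ region containing the centroid.
Centroid containment is this package's explicit operationalization of
"which organ does an object belong to" — boundary-straddling objects count
once, in the region their centroid falls in.

The test suite validates the partition itself against an independent
breadth-first flood-fill oracle on hundreds of random volumes at all three
connectivities, checks voxel-count conservation exactly, and checks
anisotropy behavior (stretching one axis scales volumes and that centroid
coordinate linearly).

## Nearest-neighbor statistics

All distances are **centroid-to-centroid Euclidean distances in µm**;
surface-to-surface distances would need the full label geometry and are out
of scope. `nn_distances()` evaluates all pairs with vectorized arithmetic;
at whole-body object counts (10³–10⁴) this is fast in R, and it is by
construction identical to the brute-force definition the tests use as an
oracle, so no spatial index is needed or used. Ties break toward the lower
target id; a missing neighbor (empty target class, or a single object
compared with itself) yields a missing distance, which summaries exclude
and count — never impute.

`region_summary()` reports per-region counts, densities
(count / region volume) and class fractions, always including a "none"
region for centroids outside every named region so nothing vanishes
silently. `density_correlation()` (Pearson or Spearman, via
`stats::cor.test`) quantifies co-distribution of two classes across
regions, e.g. TLS density tracking metastasis density.

`colocalization_ratio()` is the fraction of one mask's foreground voxel
centers lying within a physical tolerance of the other mask's foreground.
Tolerance 0 is plain voxel overlap; positive tolerances use an exact
anisotropic Euclidean distance transform (separable lower-envelope
algorithm, implemented in C++), so the ratio is exact rather than an
approximation by structuring elements, and is monotone in the tolerance.

## Filament density

Interactive filament tracing is replaced by an algorithmic chain:

1. `sample_subvolumes()` draws non-overlapping cubic subvolumes (default
   five cubes of 200 µm edge, the protocol used for enteric plexus
   quantification) uniformly at random among fully-inside positions.
   Sampling is done over the set of currently valid cube corners, with a
   bounded number of restarts when a greedy partial layout blocks
   completion; an explicit error reports the achievable maximum when the
   request cannot be met.
2. `skeletonize_mask()` thins the mask to a one-voxel-thick centerline by
   sequential deletion of *simple points* — voxels whose removal provably
   preserves 26-connectivity of the foreground and 6-connectivity of the
   background in their 3×3×3 neighborhood — excluding curve endpoints,
   cycling through six directional sub-iterations. A sub-iteration only
   considers voxels with background on the sub-iteration side and
   foreground on the opposite side; structures already one voxel thick
   along an axis are therefore never candidates in that axis, which
   prevents the classic failure mode where sequential deletion "unzips" a
   thin ribbon end-to-end. Component counts are preserved exactly.
3. `skeleton_length()` sums physical edge weights of a minimum spanning
   structure (via `igraph::mst`) over the skeleton's 26-neighbor graph,
   per component. The spanning structure avoids double-counting the chord
   edges that 26-adjacency introduces along digital curves. For networks
   with cycles this undercounts each independent cycle by exactly one
   voxel-step edge — a small, deterministic bias that is identical across
   compared conditions, which is what matters for condition contrasts. The
   recovery tests quantify it: straight tubes recover within 5%, a 45°
   staircase within 10%, collinear voxel lines exactly.

Density is centerline length per cube volume, reported in µm/µm³ and
mm/mm³. `plexus_density_report()` summarizes conditions as mean ± s.d. and
compares two conditions with the unpaired t-test, more with one-way ANOVA,
and one with an explicit "no test" notice.

## Staining profiles and penetration depth

`axial_profile()` reduces a volume to one mean intensity per slice along a
chosen axis, optionally inside an ROI, with depth measured from the chosen
entry surface (slice centers at `(i − 0.5) × spacing`). Penetration depth
is defined as the **contiguous above-threshold run from the entry
surface**: the largest depth d such that every slice at depth ≤ d stays at
or above the threshold. Published figures plot "penetration depth" without
an operational definition; contiguity matches the physical notion of a
staining front, and it makes the quantity monotone in the threshold. A
missing (empty-ROI) slice breaks the run: an unverifiable slice is not
counted as stained. Because gray-value thresholds for dye quantification
are never published, the threshold is always an explicit input.

Group comparisons default to the classical pooled-variance two-sided
unpaired t-test, with Welch available (`var_equal = FALSE`) since imaging
group variances often differ. One-way ANOVA is exposed alongside because
multi-condition figures in this field are sometimes annotated with ANOVA
while methods sections cite t-tests; both routes are available and tested
(for two groups, F = t²). The degenerate zero-variance case is defined
explicitly: equal means give t = 0, p = 1; unequal means give ±Inf, p = 0.

## The phantom generator

`generate_object_phantom()` emulates exactly the statistical structure the
analysis assumes, nothing more:

- **Two object classes** (metastases, TLS) as voxelized axis-aligned
  ellipsoids (a voxel belongs to an object iff its center lies inside),
  the simplest shape with a closed-form volume for recovery tests. Radii
  get mild log-normal aspect jitter at exact total volume.
- **Log-normal volumes.** Published whole-body tumor data report a mean
  micrometastasis volume of 0.066 mm³ with >80% below 0.02 mm³; a
  log-normal fit of those two numbers gives a median near 0.002 mm³ with
  log-sd ≈ 2.6. The generator keeps that median as its default but
  moderates the log-sd to 0.6, because the fitted tail implies objects
  larger than any desk-scale test grid: truncating them at placement would
  silently distort the very volume distribution the tests check. TLS
  default to a median of 0.0015 mm³ (log-sd 0.5), markedly smaller than
  metastases, as observed in vivo.
- **Organ regions** as axis-aligned slabs along y (named after the
  configured priors); region priors default to the reported organ
  distribution of micrometastases, 62% lung / 19% gut / 19% elsewhere.
  Each object's region is drawn **once** from the prior — retries only
  redraw size and position within that region — so the realized region
  counts are an unbiased multinomial sample and recovery tests can use
  exact binomial intervals.
- **Spatial coupling.** With a finite `coupling_scale_um`, each TLS center
  is drawn at an exponentially distributed distance (mean = the scale) in
  a uniform random direction from a randomly chosen metastasis, emulating
  the observed clustering of TLS near metastases; `"uncoupled"` placement
  uses the TLS region prior instead. The exponential is a one-parameter
  choice that makes "characteristic distance" literal.
- **Separation guarantee.** Same-class ellipsoids are rejected until their
  bounding spheres are separated by at least two voxel diagonals, so
  voxelized objects of one class can never touch under any connectivity —
  component-count recovery then isolates labeling correctness from
  generator ambiguity. Overcrowding fails loudly, naming the class.
- **Imaging model.** Intensity channels are the annotation at unit
  amplitude, attenuated by `exp(−λ · depth)` along a chosen axis and
  perturbed by seeded Gaussian noise, clipped at zero. This reproduces in
  closed form the depth-dependent signal loss that penetration-depth
  profiling quantifies.

`generate_filament_phantom()` builds a cubic lattice of tubes (nodes at a
configurable pitch, centered in the grid) with exact total centerline
length; `dropout_fraction` removes whole edges independently at random,
emulating the sparser network of germ-free animals. Degenerate lattices are
valid: a pitch comparable to the grid extent yields a single straight tube
of known length, which the skeleton tests exploit.

Everything is a pure function of the configuration including its seed;
per-stage sub-seeds are derived deterministically so partial reruns
reproduce bit-identically.

**What the phantoms do not emulate** — and hence what passing tests do not
show about real data: optical blur and anisotropic PSFs, tile seams and
stitching artifacts, intensity inhomogeneity other than axial attenuation,
realistic organ shapes (regions are slabs), touching or overlapping
same-class objects (real metastases can merge), and annotation noise (the
generator's annotations are perfect). Results on real volumes inherit the
quality of the segmentation that produces the annotations.

## File formats

Volumes travel as multi-page TIFF (one page per z-slice, z ascending, rows
= y) with a JSON sidecar carrying spacing, origin, kind and region names;
readers refuse to guess a missing voxel size. Label volumes round-trip
exactly; intensity volumes are stored as 32-bit samples with a recorded
affine rescaling and round-trip to about 10⁻⁹ of the value range, far below
any microscope's dynamic range. Tables are CSV at full double precision
with missing values as empty fields, never sentinel numbers.

## Numerical choices and degenerate inputs

- Otsu thresholds are computed on a fixed 256-bin histogram of finite
  values, making them bit-reproducible across platforms; a constant volume
  is an error that points to the fixed-threshold mode.
- Nearest-neighbor ties break toward the lower target id; label ids are
  raster-deterministic; cube sampling and all phantom stages derive
  sub-seeds from the run seed.
- The colocalization tolerance comparison uses an exact distance transform
  with a 10⁻¹² relative cushion against floating-point noise at the
  boundary.
- Empty inputs are contracts, not crashes: empty masks label to zero
  components, an empty object table summarizes to zero counts, a missing
  target class yields missing distances with reported exclusion counts,
  and a single condition yields summaries with an explicit "no test"
  notice.

## Validation problem sizes

The automated suite validates the chain at deliberately modest sizes: 16³
volumes (hundreds of them) for the labeling oracle, ~10⁶-voxel grids for
phantom recovery, 200-point sets for the nearest-neighbor oracle, 20 seed
pairs for the coupling and dropout contrasts, and a 64³ golden pipeline run
checked hash-identical across reruns. These sizes were chosen so the full
suite runs in well under a minute of compute per module while still
exercising every code path at realistic anisotropy; all statistics scale
to full-body volumes limited only by memory.

## Known limitations

- Skeleton length systematically undercounts one voxel-edge per
  independent cycle (documented above); between-condition contrasts are
  unaffected, absolute lattice lengths carry a small negative bias.
- No watershed separation of touching objects, no edge-effect correction
  for organ boundaries in nearest-neighbor statistics (border objects are
  flagged so callers can exclude them), no out-of-core processing.
- Thresholding is global (fixed or Otsu); no background subtraction or
  flat-field correction.
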