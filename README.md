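# clearvol

Volumetric quantification for whole-body light-sheet microscopy of cleared
tissue.

Tissue clearing with whole-body immunolabeling turns an entire mouse into a
single anisotropic 3D image stack. The questions asked of such data are
spatial and volumetric: how many labeled objects (micrometastases, tertiary
lymphoid structures) are there, how large are they, in which organs do they
sit, how far is each object from its nearest neighbor of the same or the
other class, how dense is a filamentous network such as the enteric nerve
plexus, and how deep does a stain actually penetrate. `clearvol`
implements this quantification chain as a tested R package, together with
a synthetic phantom generator carrying exact ground truth so every stage is
verifiable without microscope data.

## What it computes

For a binary annotation volume with voxel spacing $(s_z, s_y, s_x)$ µm:

- **Connected components** under 6/18/26-adjacency (union-find, raster
  deterministic labels), per-object voxel count, physical volume
  $V = n \cdot s_z s_y s_x / 10^9$ mm³, centroid
  $\bar{c} = \frac{1}{n}\sum_i c_i$ (unweighted mean of voxel centers, µm),
  bounding box, border flag, organ region by centroid containment.
- **Nearest-neighbor statistics** between object classes:
  $d_i = \min_j \lVert \bar{c}_i - \bar{c}_j \rVert_2$ within or across
  classes, volume–distance joins (metastasis volume vs distance to nearest
  TLS), per-region counts, densities and fractions, and the Pearson or
  Spearman correlation of two classes' densities across regions.
- **Filament density**: random non-overlapping cubic subvolumes (default
  five 200 µm cubes), topology-preserving 3D thinning to a one-voxel
  skeleton, centerline length as the physical weight of a per-component
  minimum spanning structure over the 26-neighbor graph, density in
  mm/mm³, and condition comparison (t-test / ANOVA).
- **Colocalization**: fraction of one mask's foreground within a physical
  tolerance of another's, via an exact anisotropic Euclidean distance
  transform.
- **Penetration depth**: per-slice mean intensity profiles along an axis
  and the contiguous above-threshold depth from the entry surface; for an
  exponentially attenuated signal $I_0 e^{-\lambda d}$ this recovers
  $\ln(I_0/T)/\lambda$ to within one slice.
- **Phantoms**: two coupled object classes with log-normal volumes and
  organ-region priors (defaults 62% lung / 19% gut / 19% other), filament
  lattices of known centerline length with edge dropout, and an imaging
  model with depth attenuation and seeded noise.

## Worked example

```r
library(clearvol)

# a reproducible end-to-end run on a generated phantom
manifest <- run_pipeline(default_pipeline_config(seed = 1),
                         out_dir = "run1")
s <- manifest$summary
s$n_metastases                        # 25
s$n_tls                               # 18
round(s$nn_met_to_tls_mm$median, 4)   # 0.0634  (median metastasis -> nearest-TLS, mm)
round(unlist(s$region_fractions$metastasis), 2)
#  lung   gut other  none
#  0.64  0.16  0.20  0.00
round(s$density_correlation$estimate, 3)  # 0.842 (TLS vs metastasis density across regions)
round(s$metastasis_volume$mean, 6)    # 0.000701 mm^3 mean metastasis volume
```

The run directory contains every intermediate as TIFF (+ JSON geometry
sidecar) and CSV, a `summary.json` with the quantities above, and a
`manifest.json` with MD5 hashes of all outputs: re-running with the same
seed reproduces every hash.

The same stages are scriptable individually via the thin CLI in
`inst/cli/clearvol.R` (`run`, `simulate`, `label`, `measure`, `spatial`,
`coloc`, `profile`, `filaments`, `compare`), e.g.

```sh
Rscript inst/cli/clearvol.R label --in mask.tif --connectivity 26 --out labels.tif
```

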