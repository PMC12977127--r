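# foliakit

Surface–volume atlasing tools for densely folded cortices such as the human
cerebellum, whose leaf-like folia and subfolia demand surface meshes far
finer than standard MRI voxels.

Given a closed, labeled triangular mesh of a cortex, the package

- **voxelizes** it with generalized winding numbers (per-triangle signed
  solid angles, Van Oosterom formula), labels shell voxels with the mode of
  their contained vertices, and fills the interior;
- runs the **volumetric atlas pipeline**: competitive expansion of cortical
  labels into the interior (7 iterations), white-matter assignment of the
  remaining core, volumetric mode smoothing (3 iterations, vertex-containing
  voxels frozen), white-matter re-expansion (4 iterations), a final
  one-step cortical expansion, and a surface–volume consistency pass after
  which every vertex label equals its containing voxel's label;
- subdivides the labeled surface into approximately **equal-area connected
  patches**: patch budgets apportioned to regions by area (largest
  remainder), random seeds repelled over the spherical representation for
  100 sweeps (each pointer moves to the same-region neighbor maximizing its
  minimum distance to the other pointers), multi-source breadth-first
  growth, mode smoothing, and iterative split/merge balancing (split above
  2x the mean area, merge below half, at most 5 operations per patch, then
  one forced pass);
- reconstructs an atlas-derived cortical sheet in **individual subject
  space** by two sequential diffeomorphic registrations (atlas labels to
  subject segmentation as blurred one-hot channels, then a virtual MRI of
  the atlas to the masked subject image), composing both fields and warping
  the atlas surface vertices;
- **evaluates** segmentations with DICE across configurable structural
  hierarchies (lobule / lobe / coarse), two-stage median-of-medians
  summaries, and classic max–min Hausdorff distances between a voxelized
  surface and filled label volumes.

Synthetic folded phantoms (`make_folded_phantom`), band-limited random
diffeomorphisms (`make_smooth_deformation`) and derived synthetic subjects
(`make_subject`) make every stage testable without any external data.
Readers and writers cover FreeSurfer binary surfaces and `.annot` files,
GIFTI, ASCII PLY, NIfTI-1, MGH/MGZ, FreeSurfer-style color LUTs, and
displacement fields as vector NIfTI.

## Worked example

```r
library(foliakit)

# a folded closed phantom standing in for a cerebellar cortex
phantom <- make_folded_phantom(base_radius = 15, fold_amplitude = 0.15,
                               mesh_subdivisions = 3, n_regions = 3)
phantom
#> <labeled_surface> 642 vertices, 1280 faces, 3 labels, spherical coords

mean_edge_length(phantom)          # mean inter-vertex spacing, mm
#> 2.493

region_area_fractions(phantom)
#>   label_id area_mm2  fraction
#> 1        1 1144.457 0.3393219
#> 2        2 1104.305 0.3274173
#> 3        3 1124.014 0.3332608

# surface -> consistent labeled volume (white matter id added automatically)
atlas <- run_atlas_volume_pipeline(phantom, pipeline_config(voxel_size = 1))
atlas$volume
#> <label_volume> 37 x 37 x 35, voxel size 1 x 1 x 1 mm
#>   labels: 0, 1, 2, 3, 5

# every vertex agrees with its containing voxel (postcondition; id 5 is the
# white matter core, background 0 never remains inside the surface)

# equal-area patch parcellation
parcellate(phantom, total_patches = 60, rng_seed = 7)
#> <parcellation> 24 patches over 3 regions; area CV 31.0%, range ratio 2.97
```

The patch count settles below the budget because undersized patches merge
during balancing; a full-scale 800-patch budget balances the same way to a
smaller set of roughly equal-area patches. The area CV
and max/min range ratio quantify how even the patch areas are.

For subject reconstruction, see `?arcus_reconstruct`: given a subject
lobular segmentation and MRI, it returns the warped atlas surface plus the
stage fields; on synthetic subjects generated with `make_subject` the
vertices are recovered to about one voxel RMS.

A thin command-line interface wraps the same functions:

```sh
exec/foliakit synth --seed 7 --out phantom_dir
exec/foliakit voxelize --surface S.surf.gii --labels S.annot \
    --voxel-size 1.0 --out vol.nii.gz
exec/foliakit parcellate --surface S.surf.gii --labels S.annot \
    --n 800 --seed 7 --out parc.csv
exec/foliakit evaluate --pred P.nii.gz --truth T.nii.gz \
    --hierarchy inst/extdata/hierarchy_lobule.json --out report.csv
```

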