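# fsubr

Functional sub-bundle (FSuB) extraction from diffusion MRI tractograms.

## The problem

White-matter bundles reconstructed from diffusion MRI connect stretches of
cortex that are usually much larger than the functionally specialised regions
studied with task fMRI. To relate a bundle to a specific function — say, the
streamlines of the arcuate fasciculus that actually reach a word-selective
region — one wants the *functional sub-bundle*: the subset of streamlines
whose endpoints terminate at a functional ROI (fROI), evaluated where
streamlines should end, at the gray-matter/white-matter interface (GMWMI).

fsubr implements that extraction natively in R, for researchers combining
tractography (MRtrix/TrackVis-style tractograms), FreeSurfer surface
reconstructions, and task-fMRI-derived fROIs:

1. **GMWMI creation** — from a five-tissue-type (5tt) partial-volume
   segmentation, each voxel is scored `min(1, 4·g·w)` where `g` and `w` are
   the (cortical) gray- and white-matter fractions. The score is 1 at a
   50/50 mix and 0 in pure tissue; it is binarized at an adjustable
   threshold (default 0.25).
2. **fROI projection** — a surface label is swept inward along per-vertex
   normals (depth 2 mm, step 0.25 mm by default) and voxelized; no radial
   dilation, so the fROI footprint is not inflated.
3. **Intersection** — the streamline search space is the voxelwise product
   of the projected fROI and the binarized GMWMI, with no silent resampling.
4. **Endpoint matching** — each streamline endpoint is assigned to the
   nearest target voxel centre within a radius *r* (radial search, default
   r = 2 mm), by marching along the terminal tangent (forward search), or by
   exact containment (endpoint search). With one fROI, a streamline is kept
   if either endpoint matches; with two fROIs, it must connect them — one
   endpoint on each.
5. **Summaries** — per-endpoint assignment tables, fROI-volume-normalised
   counts, summed streamline weights (SIFT2-style), and *connectivity
   profiles*: for a fixed set of named bundles, the percentage of matched
   streamlines per bundle, comparable across methods via Pearson
   correlation.

I/O is bit-faithful and native: TCK (MRtrix) and TRK (TrackVis v2)
tractograms, NIfTI-1 volumes (via RNifti), FreeSurfer binary triangle
surfaces and ASCII `.label` files, plain-text 4×4 affines (plain and
ITK dialects), and one-float-per-line weight files. Everything is converted
to world RAS millimetres on ingest (TRK's corner-origin voxel-mm convention
included), so matching happens in a single metric space.

A deterministic slab-phantom generator (`make_slab_phantom()`) builds
meshes, 5tt segmentations, statistical maps, labels, and tractograms with
per-streamline ground truth, so the whole pipeline is testable without any
imaging data.

## Worked example

```r
library(fsubr)

ph     <- make_slab_phantom()                     # 100 target + 400 decoy streamlines
gmwmi  <- binarize(compute_gmwmi(ph$seg), 0.25)   # interface sheet
froi   <- project_label_to_volume(ph$mesh, ph$labels$A, ph$grid)
target <- intersect_masks(froi, gmwmi)            # fROI x GMWMI search space

res <- extract_fsub(ph$tractogram, target)        # radial search, 2 mm
res
#> <fsub_result> 100 / 500 streamlines matched (roi1, radial search, 2 mm)

fsub <- subset_tractogram(ph$tractogram, res$selected)
fsub_summary(res, fsub, target)
#> # A tibble: 1 x 7
#>   n_streamlines total_weight froi_volume_mm3 streamlines_per_mm3 mean_length_mm ...
#> 1           100          100              49                2.04           22.4
```

100 of 500 streamlines match the fROI: exactly the 100 planted into patch A
(the 400 decoys terminate on the interface but at least 5 mm away). The
target mask covers 49 voxels of 1 mm³, giving 2.04 matched streamlines per
mm³ of fROI, and the matched arcs average 22.4 mm in length. Ground truth
confirms the selection:

```r
evaluate_recovery(ph$truth, res)
#> # A tibble: 1 x 5
#>   precision recall n_selected n_true undefined_precision
#> 1         1      1        100    100 FALSE
```

`tidy(res)` returns the per-endpoint assignment table,
`glance(res)` a one-row run summary, and
`autoplot(connectivity_profile(...))` a grouped-bar profile figure.

A command-line front end mirroring the same workflow is installed at
`exec/extractor`:

```sh
extractor --subject sub-01 --tract bundle.tck --tract-name LeftArcuate \
  --roi1 lh.mOTS.label --roi1-name mOTS-words --hemi lh \
  --fs-dir lh.white --fivett 5tt.nii --fs2dwi fs2dwi.txt --out-dir out/
```

Outputs (FSuB tractogram, assignments TSV, JSON summary, three-panel
snapshot PNG, intermediates, log, manifest) use parseable BIDS-like names
such as `sub-01_desc-LeftArcuate_roi-mOTS-words_fsub.tck`.

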