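# vasquant

Quantitative 3D analysis of the embryonic zebrafish cerebral vasculature
from light sheet fluorescence microscopy (LSFM) volumes.

Characterising cerebrovascular development — which vessels form, where,
how reproducibly between individuals, and how experimental perturbations
change vascular topology — requires going beyond visual inspection of
maximum intensity projections. `vasquant` implements an automated
workflow for researchers working with transgenic vascular reporter lines:
it segments the vasculature, co-registers individuals into a common
coordinate system, builds population average maps that expose conserved
and variable vessels, and extracts an eight-parameter quantitative
description of the vascular network, including its left-right symmetry.

## The workflow

For each sample `n` with motion-corrected volume `O_n`:

1. **Enhancement and segmentation.** Slice drift is corrected by
   per-slice phase correlation; vessels are enhanced with the multi-scale
   Sato tubeness filter (response `sqrt(λ2·λ3)` of the σ²-normalised
   Hessian eigenvalues `λ1 ≥ λ2 ≥ λ3`, for `λ2, λ3 < 0`); the enhanced
   volume `E_n` is thresholded by Otsu's method, giving the binary
   segmentation `Se_n`.
2. **Registration.** Samples are brought into the template's coordinate
   system either by least-squares rigid fitting of 11 anatomical
   landmarks (Kabsch/Procrustes, no scaling) or automatically: an
   exhaustive coarse Euler-angle search with FFT translation matching on
   a downsampling pyramid, keeping the five best orientations for
   Nelder–Mead refinement of a squared-difference objective. Voxel-wise
   averaging of registered masks `Re_n` yields the population average
   map (PAM).
3. **Similarity.** Dice `DC = 2|M∩T|/(|M|+|T|)`, Jaccard, total overlap,
   mutual information (bits), SSD, MSE and SSIM quantify inter-sample or
   left-right agreement.
4. **Quantification** within a cranial ROI: vascular volume
   `V_n = N_vessel · v_xyz`, exposed-face surface voxels `A_n`, density
   `ρ_n = V_n/V_total`, then (after 1920→512 bilinear lateral
   downsampling) the Euclidean distance map `EDM_n`, a 3D-thinning
   skeleton `Sk_n`, network length `L_n`, branch points `BP_n`, mean
   vessel radius `R_n` from the skeletonised distance map
   `SDM_n = EDM_n × Sk_n`, and a Sholl intersection profile `C_n`
   (700-voxel radius, 5-voxel shells).
5. **Symmetry.** After aligning the anterior-posterior axis with the
   image y-axis, the right vasculature is mirrored across the midline
   and compared to the left by voxel overlap and per-hemisphere volume
   and network length.
6. **Reporting.** Per-group means, standard deviations and coefficients
   of variation (CoV), percent-difference tables between conditions, and
   agglomerative clustering of condition profiles (correlation distance,
   average linkage).

Because validation against real acquisitions requires the original
multi-gigabyte LSFM datasets, the package ships a synthetic phantom
generator (`generate_tube_phantom`, `generate_tree_phantom`,
`generate_symmetric_phantom`, `render_noisy`) producing vascular
geometries with exactly known volume, centerline length, branch points,
radii and symmetry, plus an LSFM-style noisy renderer (lumenised
double-peak or solid single-peak cross-sections, PSF blur,
Poisson–Gaussian noise). The whole pipeline is validated end-to-end
against these ground truths.

## A worked example

```r
library(vasquant)

# a vascular tree phantom with 5 bifurcations and exact ground truth
spec  <- phantom_spec(n_bifurcations = 5, seed = 7, spacing = c(1, 1, 1))
tree  <- generate_tree_phantom(spec)
image <- render_noisy(tree$mask, spec)        # noisy LSFM-style render

seg <- segment_vasculature(image, segmentation_params(scales_um = c(2, 3.5, 5)),
                           drift_correction = FALSE)
binary_overlap_metrics(seg, tree$mask)$dice
#> [1] 0.9185272

rec <- quantify_region(binary_mask(seg$data, seg$spacing),
                       downsample_to = NULL, sample_id = "phantom07")
rec[, c("sample_id", "volume_um3", "density", "branch_points",
        "length_voxels", "mean_radius_voxels")]
#>   sample_id volume_um3     density branch_points length_voxels mean_radius_voxels
#> 1 phantom07      47491 0.005661368             5           431           4.789794
tree$truth$branch_count
#> [1] 5
```

The segmentation recovers the phantom with a Dice coefficient of 0.92,
and the skeleton analysis recovers the constructed number of
bifurcations exactly; `volume_um3` is the foreground voxel count times
the voxel volume, `mean_radius_voxels` is the mean of the distance map
sampled along the skeleton (the phantom's tube radii range from 3 to 7
voxels, so a mean near 5 over a radius-tapered tree is expected).

A command-line interface wrapping the same functions (subcommands
`segment`, `register`, `pam`, `similarity`, `quantify`, `symmetry`,
`phantom`, `report`, `run-all`) is installed under
`system.file("cli/vasquant.R", package = "vasquant")`.

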