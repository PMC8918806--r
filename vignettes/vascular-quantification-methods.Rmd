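---
title: "Methods: quantifying 3D cerebral vasculature with vasquant"
author: "vasquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying 3D cerebral vasculature with vasquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, algorithms and design choices behind
`vasquant`, in the spirit of a methods section: what each stage assumes,
which parameters matter, how the synthetic validation substrate relates
to real light-sheet data, and where the known limitations are.

## Data model

Volumes are dense 3D arrays indexed `(z, y, x)` with an explicit
physical voxel size in micrometres (`(x, y, z)` order, e.g.
`0.33 × 0.33 × 0.5` µm for a typical light-sheet acquisition of a
zebrafish embryo head at 1920×1920 lateral pixels). Spacing is never
inferred from files — TIFF metadata in this domain is too unreliable —
so every reader requires it explicitly. Binary masks use foreground = 1
for vessel; an `inverted` I/O flag serves tools that count vessels as
zero-valued ("black") voxels. Physical coordinates put the centre of
voxel `(iz, iy, ix)` (0-based) at `(ix·sx, iy·sy, iz·sz)` µm; rigid
transforms act on these physical coordinates as
`p ↦ R (p − c) + c + t`.

## Segmentation

**Drift correction.** Between-plane acquisition jitter is translational,
so each z-slice is aligned to its predecessor by the 2D translation
maximising phase correlation, with a parabolic sub-pixel peak fit;
cumulative integer shifts are applied. A feature-based aligner could be
substituted, but for axial jitter the translation model is the correct
one and is testable by shift injection. Constant (structure-free)
stacks are detected and left untouched with a warning.

**Vessel enhancement.** The Sato line filter: at Gaussian scale σ the
image Hessian is computed by separable Gaussian-derivative convolution
(per-axis σ in voxels = σ_µm / spacing_axis, so anisotropic grids are
handled correctly), eigenvalues `λ1 ≥ λ2 ≥ λ3` are obtained in closed
form, and the tubeness response is `σ² · sqrt(λ2·λ3)` where both are
negative, else 0 (γ = 1 scale normalisation; the same response as the
popular "Tubeness" plugin). Multi-scale analysis takes the voxel-wise
maximum across scales. The discrete second-derivative kernels are
forced to zero DC response, which makes the filter exactly invariant to
additive intensity offsets; it scales linearly with multiplicative gain.

Default scales are `{1, 2, 4}` µm, covering vessel radii of roughly
1.5–6 µm (the response of a solid tube of radius r peaks near
σ ≈ 0.7 r); for targets outside this range the scale set should follow
the same matching rule. Our phantom validation, with tube radii of 3–7
voxel-µm, accordingly uses `{2, 3.5, 5}`.

**Thresholding.** Otsu's method on a 256-bin histogram: the threshold
maximises the between-class variance `ω0·ω1·(µ0−µ1)²`, ties broken
towards the lowest bin; the mask is `value > threshold` (strict).
Integer images whose levels fit in the bin budget are histogrammed at
native levels, making the result exactly equal to exhaustive search on
8-bit data; wider ranges are rebinned to 256 equal-width bins, matching
common histogramming practice for 16-bit data. A constant image raises
a degenerate-histogram error.

*Limitation.* Otsu assumes a two-class histogram. On a volume
containing no vascular signal at all it will happily split the noise
distribution and return substantial speckle foreground; such input is
detectable by the irreproducibility of that speckle across repeat
noise realisations, not by the foreground fraction. Downstream flags
(e.g. registration confidence) are the practical guard.

## Registration

**Landmark mode.** Given the same ≥3 non-collinear named points in both
samples (the protocol uses 11 anatomical landmarks), the least-squares
rigid transform (rotation + translation, no scaling) is the
Kabsch/Procrustes solution via SVD of the centred cross-covariance,
with a reflection guard. Collinear configurations are rejected. For
isotropic landmark noise of sd σ on N points the expected RMS residual
is `σ·sqrt((3N−6)/N)` (six degrees of freedom absorbed), which the test
suite verifies by Monte-Carlo.

**Automatic mode.** Operates on segmented masks by default (intensity
volumes work identically): a 3-level isotropic downsampling pyramid
(factors 6, 4, 2 — box smoothing plus stride subsampling); at the
coarsest level an exhaustive Euler-angle grid (30° steps over the full
orientation space) where each orientation's optimal translation comes
from FFT cross-correlation; the five best orientations by
squared-difference are refined with Nelder–Mead over all six rigid
parameters through the finer pyramid levels; the rotation centre is the
target volume's geometric centre. The final transform is re-scored at
full resolution, where the normalised objective for masks equals
`1 − Dice`; results above a confidence threshold (default 0.8,
i.e. Dice < 0.2) are flagged rather than silently returned. The grid
step, pyramid factors, candidate count and maximum shift are all
parameters of `auto_reg_params()`.

On displaced phantoms (10° + 15 voxels, the synthetic analogue of
re-imaging a sample after manual displacement) the search recovers the
displacement to well under 1° and 1 voxel; the validation suite holds
it to those bounds with post-registration Dice ≥ 0.95.

**Population average maps** are plain voxel-wise means of co-registered
binary masks; `mean · n` is an integer overlap count per voxel, high
values marking vessels conserved across the group.

## Similarity metrics

Dice, Jaccard and total overlap come from exact voxel counts (total
overlap is normalised by the *target* mask and is deliberately
asymmetric). Mutual information uses a 64-bin joint histogram on
min-max-normalised intensities (exact 2×2 table for binary input),
base-2 logs, so MI of an image with itself equals its histogram
entropy. SSD and MSE are the plain sums; SSIM follows the standard
formulation (K1 = 0.01, K2 = 0.03, Gaussian window σ = 1.5) computed
slice-wise on z-slices and averaged, with the dynamic range taken from
the image dtype unless overridden. Dice is the headline metric in
practice; the others are reported alongside.

## The eight-parameter quantification stack

Volume, surface and density are computed at full resolution inside the
ROI: `V = N_fg · sx·sy·sz`; surface voxels are foreground voxels with a
6-connected background neighbour (a deterministic, parameter-free
replacement for slice-wise edge detection — exactly testable on cubes);
density is the foreground fraction of the ROI. The mask is then
downsampled laterally to 512 pixels (bilinear, masks re-thresholded at
0.5) before the geometry stages, mirroring the workflow's cost-saving
step; `downsample_to = NULL` disables this.

**Distance map.** An exact Euclidean distance transform
(Felzenszwalb–Huttenlocher lower-envelope algorithm, implemented in
C++) gives each vessel voxel its distance to the nearest background
voxel, in voxel units by default (matching pixel-based distance-map
plugins) or spacing-weighted micrometres by flag.

**Skeleton.** Layer-by-layer homotopic thinning: each iteration peels,
for the six face directions in turn, border voxels that are *simple
points* (removal preserves foreground 26-connectivity and background
6-connectivity, Malandain–Bertrand characterisation) and not curve
endpoints; candidates are collected per direction and deleted
sequentially with re-checking. Connectivity is therefore exactly
preserved. Blunt tube ends leave short terminal spurs; these are pruned
below a length threshold and the result re-thinned to a fixpoint.

*Limitation.* Exactly even-width, axis-aligned digital tubes (axes on
half-integer lattice positions) can collapse under this class of
thinning algorithm — the reference layer-by-layer implementation erases
such inputs entirely — so the tube phantoms place their axes on the
voxel lattice. Segmentation masks of real, curved, noisy vessels do not
present this degenerate geometry at whole-vessel scale.

**Length.** The primary network length is the skeleton voxel count (the
histogram-based centreline count used in the original workflow). The
calibrated variant reduces the skeleton's 26-adjacency graph to its
minimum spanning forest, decomposes it into junction-to-junction
chains, and measures each chain as a polyline subsampled every third
voxel: raw step sums overestimate oblique digital curves by ~8–13%
(staircase bias), while the chord-subsampled measure recovers phantom
centerline lengths to within a few percent. Anastomotic loops lose one
edge per cycle in the spanning forest and are slightly underestimated.

**Branch points.** Skeleton voxels with ≥3 skeleton neighbours are
junction voxels; touching junction voxels merge into one cluster
(naive counting inflates thick junctions). A thick bifurcation can
additionally split into nearby non-touching clusters, so when the mask's
distance map is available, clusters closer than the local vessel
diameter are merged too. Raw junction-voxel counts are reported
alongside. On clean tree phantoms with 1–8 constructed bifurcations the
clustered count is exact.

**Radius.** The skeletonised distance map (EDM × skeleton) reads the
local vessel radius along the centreline; its mean is the mean vessel
radius. On digital tubes of radius 2–6 voxels the recovery error stays
within the ±0.5 voxel discretisation bound.

**Sholl complexity.** Computed on the 2D maximum-intensity projection
of the skeleton with circles (the source protocol applies the analysis
to 2D skeleton MIPs even though it speaks of spheres; we implement the
2D reading): each circle is sampled densely in angle and the
intersection count is the number of connected angular runs of
foreground. Defaults: 700-voxel maximum radius, 5-voxel shell step; the
centre is user-supplied (anatomically, the basilar-artery /
posterior-communicating-segment junction; it cannot be auto-detected),
falling back to the skeleton centroid.

## Left-right symmetry

The anterior-posterior midline is a straight line fitted (first
principal direction) through user-supplied anchor points along the
midline vessels; the volume is rotated in-plane so this axis runs along
image y, split at the midline voxel column (mean x of the aligned
anchors, rounded half-up), and the right hemisphere is reflected across
the midline plane (`x ↦ 2·mid − x`, a lattice bijection, so voxel
counts are conserved exactly). Reported: per-hemisphere volume and
skeleton length (computed with the same quantification operators, so
left/right numbers are comparable by construction), Dice between left
and mirrored right, and the overlap mask — voxels vascular on both
sides, our reading of "voxel majority decisions", recorded as an
interpretation since no formal rule is published. Mirror-symmetric
phantoms give Dice exactly 1 and exactly equal volumes; hemisphere
skeleton lengths can differ by a voxel or two because sequential
thinning is order-dependent.

## Synthetic phantoms

The generator is the package's validation substrate, standing in for
multi-gigabyte light-sheet acquisitions.

* **Geometry** lives in voxel-index space: tubes are rasterised by
  voxel-centre-in-cylinder inclusion (unambiguous and oracle-checkable;
  anti-aliasing only ever happens in the intensity render, never the
  truth mask). Trees grow by splitting a random active tip:
  two daughters diverge in a common random bifurcation plane at 20–40°
  each, with tapered radii, and candidates colliding with existing
  segments (surface clearance below 3 voxels) or leaving the volume are
  resampled; the whole tree restarts with a derived sub-seed if
  placement fails, and errors after a bound. Branch count, per-segment
  radii, centerline length and voxel volume are exact by construction.
  Symmetric phantoms grow one hemisphere and reflect it; injected
  right-only segments record their exact voxel count.
* **Default regime.** 128×256×256 voxels; tree radii 3–7 on an
  isotropic 1 µm grid give vessel diameters of 6–14 µm — inside the
  5–20 µm range typical of embryonic zebrafish cerebral vessels — and
  roughly the lateral resolution real data has after the workflow's own
  1920→512 downsampling. The anisotropic acquisition spacing
  (0.33, 0.33, 0.5 µm) can be requested, but since phantom tubes are
  circular in index space they are then elliptical in physical space,
  which degrades Hessian enhancement; end-to-end segmentation
  validation therefore runs on the isotropic grid.
* **Rendering.** Unlumenised vessels paint solid tubes at the vessel
  peak over a constant background; lumenised vessels paint a bright
  ~1 µm wall around a dimmer lumen, reproducing the double-peak
  cross-section of membrane-labelled lumenised vessels. The field is
  blurred with a Gaussian PSF (σ 0.4 µm), then degraded by Poisson shot
  noise (0.5 photons per intensity unit, i.e. ~10% shot noise at the
  default peak of 200 over background 20) and additive Gaussian read
  noise (sd 4). All randomness flows through one seed with the caller's
  RNG state restored.
* **What the phantoms do not emulate:** anatomy (no named vessels, no
  brain-shaped autofluorescence), pigment artefacts, depth-dependent
  attenuation and scattering, multi-view fusion seams, and vessel wall
  texture. Passing the phantom suite demonstrates the operators are
  correct and the pipeline is self-consistent at realistic SNR; it does
  not certify segmentation accuracy on any particular real acquisition.

At the default noise level the full render → segment → quantify chain
recovers the truth mask with Dice ≈ 0.91 and the bifurcation count
within ±1; segmentation quality degrades monotonically as noise grows.

## Group reporting

CoV uses the sample (n−1) standard deviation — the convention is
unstated in the source protocol, so it is fixed here and documented.
Percent differences are `100·(mean_treated − mean_control)/mean_control`
per parameter, with zero-control-mean entries flagged. Condition
clustering uses average linkage on `1 − Pearson correlation` between
condition profiles; per-parameter standardisation (the default of
common web clustering tools, and the setting that makes the tree
invariant to per-parameter affine rescaling) is available via
`scale_parameters = TRUE` but defaults off, because the raw correlation
distance is the stated definition and standardisation degenerates on
small sign-symmetric matrices. Statistical hypothesis testing is out of
scope by design: the CSV outputs are built for direct import into
dedicated statistics software.

## Numerical and testing notes

* Problem sizes: the validation suite runs phantoms at 128×256×256
  (registration, end-to-end, symmetry) and smaller grids for unit
  checks; brute-force oracles (exhaustive Otsu search, O(N·M) distance
  maps, voxel-count overlaps, naive agglomeration) back every core
  operator at sizes where enumeration is exact and fast.
* Sequential thinning is deterministic but order-dependent: exact mask
  symmetries (mirrors, 90° rotations) reproduce branch counts exactly
  while skeleton voxel counts may differ by a few voxels.
* Even-width axis-aligned tubes are the documented degenerate input of
  the thinning stage (see above).
* The coarse registration search assumes the displacement lies within
  the angular search range and `max_shift`; outside it, the flagged
  low-confidence path is the defined behaviour, not silent failure.
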