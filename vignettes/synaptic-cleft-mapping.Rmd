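---
title: "Mapping synaptic clefts in extracellularly labeled 3D volumes"
author: "SynaptoSeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping synaptic clefts in extracellularly labeled 3D volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Extracellular labeling inverts the usual fluorescence contrast: the dye fills
the space *between* cells, so membranes read out as shells of signal and the
protein-dense extracellular matrix of a synaptic cleft reads out as a compact
high-intensity feature. High intensity alone is not diagnostic — dense tissue
is full of bright non-synaptic features — so a cleft is only called when the
bright feature sits in the sandwich arrangement between a pre-synaptic
active-zone marker punctum and a post-synaptic scaffold punctum. SynaptoSeg
turns that criterion into a reproducible pipeline: segment bright candidates
from the structural channel under marker guidance, classify them by marker
co-localization, assign them to boutons, and quantify single-bouton
morphology and bouton–spine connectivity.

## The segmentation model

Two variants are implemented, differing in how the global intensity
distribution enters.

**Marker-guided global threshold.** The structural channel is linearly
rescaled so that its 1st and 99th intensity percentiles map to 0 and 1
(`contrastStretch`); values outside the window clip. The guide mask — the
post-synaptic marker channel after difference-of-Gaussians background
subtraction (σ~bg~ = 15, σ~sig~ = 1 voxels) and global Otsu binarisation
(`markerMask`) — is dilated with a 2-voxel Euclidean ball and multiplied
into the stretched volume. The binarisation threshold is the percentile
formula

$$\mathrm{thr} = p_{95} + s\,(p_{100} - p_{95}), \qquad s = 0.65,$$

with both percentiles taken, by default, over the full stretched volume
(`thresholdDomain = "full"`; the alternative "masked" restricts the domain
to the gated nonzero voxels — the source recipes are ambiguous on this
point, and both are exposed). Connected components (26-neighbourhood by
default) smaller than 8 voxels are discarded; "smaller than" is strict, so
an 8-voxel object survives.

**Refined local threshold.** Contrast stretch, then
difference-of-Gaussians with σ = 7 / 0.3 voxels, grayscale erosion with a
1-voxel ball (compensating the blur of upstream denoising and background
subtraction), binarisation at the *upper* threshold of a three-class Otsu
decomposition, gating by the 1-voxel-dilated guide mask, and a 6-voxel
minimum size. Both the background-subtraction and erosion stages can be
toggled off, as one published application of the procedure omits them.

**Classification and association.** A candidate is retained as a putative
synaptic cleft region iff its raw voxels overlap, by at least one voxel, the
intersection of the pre-synaptic mask with the *non-dilated* post-synaptic
mask — even when segmentation used a dilated guide, classification reverts
to the raw mask. Each retained cleft is assigned to the bouton with the
largest voxel overlap after dilating bouton masks with a 2-voxel ball (ties
break toward the lowest bouton label). Interactive proofreading is
represented as a JSON edit list (`applyProofreading`) rather than a GUI.

## Morphometry

Bouton volume and surface area come from a triangle mesh of the binary
bouton mask. Marching cubes is implemented from first principles: on every
cube face a marching-squares pass produces iso-segments (vertices at edge
midpoints, since the field is binary and the iso-level 0.5); the ambiguous
two-diagonal face configuration is always resolved by separating the inside
corners, a rule both adjacent cubes apply identically, which makes the
surface watertight by construction. Segments chain into closed loops that
are fan-triangulated; masks are padded by one voxel so border-touching
objects still close. Plain marching cubes on binary data overestimates
curved areas by roughly 9% (the staircase effect), so meshes are relaxed
with volume-preserving Taubin smoothing (λ = 0.5, μ = −0.53, 10 iterations)
before measurement; with it, a digital ball of radius 10 voxels reproduces
the analytic sphere volume to −0.6% and area to +0.7%, and a 10³ solid box
keeps its volume to −0.5%. Mesh volume uses the divergence theorem; an
even number of faces per edge counts as closed (count 4 marks a pinch where
the surface touches itself, which is still watertight).

Cleft–bouton contact areas use the cleft voxels adjacent to the bouton
(26-neighbourhood by default, 6 available) as a point cloud, reconstructed
by ball pivoting with radii 1 and 1.5 voxels (smaller first; boundary edges
left by the small ball are revisited by the large one). Two numerical
choices matter and are deliberate:

* the pivot never rolls past the plane of its edge (rotation capped at π),
  which keeps single-layer point sheets single-sided — a 10 × 10 unit grid
  triangulates to exactly 81 area units;
* at the larger radii, points exactly at ball distance count as blocking,
  so cocircular lattice configurations in already-triangulated regions are
  not re-covered.

Triangle circumradii never exceed the pivoting radius. Note a sampling bias
inherent to the procedure: triangulating voxel-*centre* samples of a disk of
radius $r$ spans only the centre hull, clipping about half a cell at the
rim — a factor $(r-\tfrac12)^2/r^2$, i.e. −30% at $r = 3$ voxels but within
10% at $r = 10$. Desk-scale contact patches therefore measure slightly
below the nominal disk area; the analytic oracle is validated at radius 10.

Spines are split from the dendrite by morphological opening with a 3-voxel
ball; the largest connected fragment is the main branch, its 1-voxel
dilation is subtracted from the original segment, and the remainder is
instance-labelled as spines (fragments under 27 voxels are dropped as
sub-resolution residue; filopodia are out of scope). The returned main
branch reclaims its own staircase rim — the voxels of the original segment
inside the 1-voxel dilation — so main branch and spines partition the
segment up to the dropped fragments. At desk scale the rim would otherwise
be ~3% of a thin dendrite's volume; on the data the procedure was designed
for it is negligible.

## Connectivity and validation

For every cleft, a 1-voxel dilation is intersected with the bouton and
spine label maps; all overlapping spines are kept, while only the
largest-overlap bouton is retained, making bouton assignment a function.
Degree summaries count *distinct* partners (multiple clefts between the
same pair count once).

Object-level validation matches segments of two label maps by spatial
overlap (≥ 1 voxel), scores each pair with IOU and Dice
($\mathrm{Dice} = 2\,\mathrm{IOU}/(1+\mathrm{IOU})$, exactly, on integer
voxel counts), and keeps per reference segment only the best-scoring pair.
At threshold $t$: $N_{TP}$ = retained pairs with score ≥ $t$ (the
comparison is inclusive; a strict option exists),
$N_{FP} = n_{test} - N_{TP}$, $N_{FN} = n_{ref} - N_{TP}$, and precision,
recall, F1 follow. Confidence intervals for Pearson correlations use the
Fisher z-transform with normal quantiles — the method reproduces the
published worked examples (r = 0.844, n = 30 → upper bound 0.923;
r = 0.841, n = 30 → 0.922) although the original analysis software did not
state its method. F1 comparisons require commensurate support: cleft
interfaces are thin, so blob-like segments are matched against the
reference dilated by one voxel, while the local variant's eroded cores —
thinner than the reference — are themselves dilated by one voxel before
scoring. A 6-voxel core inside a 33-voxel interface caps IOU at 0.18
regardless of detection quality; thickness matching is what makes the IOU
threshold measure localization rather than thickness.

## The phantom: what it emulates, and what it does not

The generator states one synthetic world and keeps it fixed:

* 50 nm isotropic voxels (the native acquisition grid) on a default
  112 × 96 × 144 grid (5.6 × 4.8 × 7.2 µm);
* a 0.35-µm-radius dendrite with five complex spines (2-voxel necks,
  heads of at least 0.3 µm radius);
* three boutons, ellipsoids with 0.6 ± 0.05 µm semi-axes, each engulfing
  one spine head across a 1.5-voxel extracellular gap (within the
  1–2-voxel range the geometry states; at exactly 2 voxels no voxel layer
  is 26-adjacent to both sides at every lattice phase, which would break
  the interface invariant);
* per-bouton cleft counts drawn from 3–8. The biologically observed range
  is 3–28 with mean ≈ 13, but those counts live on ~13.6 µm³ boutons with
  ~2 µm between clefts; on a desk-scale 1 µm³ bouton, heads adapt their
  radius so the drawn count stays resolvable at the stated PSF (patch
  centres ≥ 11 voxels = 550 nm apart), and beyond ~8 patches the required
  heads no longer fit the default grid. The full range works with a
  proportionally larger `gridShape`;
* cleft patches of 3-voxel (150 nm) in-plane radius — active-zone scale —
  rendered at 3× the membrane base amplitude. No measured contrast ratio
  exists; ≥ 2× is assumed and the value is a config knob;
* marker puncta (Gaussian blobs, σ = 1.5 voxels = 75 nm) displaced 100 nm
  from each cleft centroid along the interface normal, into the bouton
  (pre) and into the spine (post) — the sandwich ordering is asserted by a
  line-profile test along stored normals;
* 60 bright extracellular distractor hotspots (radius 4–6 voxels,
  amplitude 1.2–2.5× base). These are essential, not decorative: without
  them the 1–99% contrast stretch clips membranes and clefts into the same
  top intensity bin and the percentile-formula threshold cannot separate
  them. Real tissue fills its top percentile with dense non-synaptic
  protein features — which is precisely why the published pipeline needs a
  marker guide — and the hotspots reproduce that histogram structure.
  They are placed away from cleft neighbourhoods so that marker guidance,
  not placement, excludes them;
* a ~55 nm-σ Gaussian PSF per channel, and photon-counting noise:
  Poisson(50 × (intensity + 0.05)) plus Gaussian read noise (σ = 1),
  clipped at zero.

Everything is deterministic given the config seed; placement uses rejection
sampling capped at 1000 attempts per object and fails loudly naming the
object. What the phantom does *not* emulate: realistic optical transfer
(vectorial PSFs, depth aberration), labeling heterogeneity along membranes,
vesicle-scale texture inside boutons, expansion distortions, or the
spatially correlated residuals of learned denoising. A green phantom test
therefore establishes that the *computational* chain — thresholds,
morphology, matching, bookkeeping — does what it claims on data with the
assumed statistical structure; it cannot certify biological detection
performance on real volumes.

## Numerical choices and degenerate inputs

* Percentiles interpolate linearly between order statistics throughout.
* Gaussian filtering uses reflect boundaries with kernels truncated at 4σ;
  with σ = 15 on small fixtures the outer two σ retain a gradient residue,
  so oracle comparisons crop the boundary.
* Otsu histograms use 256 bins over [min, max]; between-class-variance ties
  break toward the lower threshold. Constant (or insufficiently diverse)
  inputs raise degenerate-input errors rather than returning a value.
* Foreground tests after thresholding are strict (`> thr`).
* A degenerate contrast-stretch window returns an all-zero volume with a
  warning; an empty guide mask yields an empty candidate set with a
  warning; empty meshes refuse to be written.
* CLAHE uses a tile grid (tile = 1/5 of each dimension), 256-bin clipped
  histograms with uniform redistribution of the excess, and trilinear
  interpolation between tile mappings; as the clip limit tends to zero the
  transform approaches the identity up to the 1/256 quantisation floor.
* Voxel indices are 0-based on disk interfaces and 1-based in R; axes are
  (z, y, x) everywhere; physical spacing rides along as nm per axis and all
  reported geometry is µm / µm² / µm³. TIFF stores float data at 32 bits,
  HDF5 at full precision.

## Known limitations

* The local variant's grayscale erosion can shrink a weak cleft below its
  6-voxel minimum under noise (observed: 11/12 recovered on noisy phantoms
  versus 12/12 for the global variant) — faithful to the procedure, which
  was designed for denoised input.
* Segment counts are not monotone in the threshold fraction `s`: lowering
  the threshold can merge neighbouring clefts into one component. The
  monotone property is the shrinkage of the foreground voxel set.
* Ball pivoting assumes locally sheet-like point clouds (contact patches);
  it is not a general surface reconstructor for volumetric point sets.
* The phantom's hotspots and membrane amplitudes are a stand-in histogram
  model, not a calibrated forward model of any particular microscope.
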