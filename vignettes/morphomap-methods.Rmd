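---
title: "Quantifying tissue motion and deformation from fragmented 3D+t imaging"
author: "morphomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue motion and deformation from fragmented 3D+t imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(morphomap)
```

## The problem

Live imaging of mammalian organogenesis — early heart-tube formation in
the mouse is the motivating system — produces 3D time-lapse volumes that
are individually too short, too incomplete, and too variable to describe
the full morphogenetic process. A single two-photon acquisition covers a
few hours of a roughly twelve-hour transformation, often misses
peripheral structures such as the inflow and outflow tracts, and every
embryo differs in size, orientation and developmental pace. morphomap
implements a framework that first extracts continuous tissue motion from
each acquisition and then fuses the fragments into a single consensus
description on a staged reference atlas: per-region growth rates,
deformation anisotropy, cumulative deformation across the full window,
and an in-silico fate map for pseudo-cell tracking.

## Per-specimen motion: B-spline free-form registration

Motion is estimated directly from image intensity, not from tracked
cells. Consecutive frames are aligned by minimising

$$E(u) = \frac{1}{|\Omega|}\sum_{x \in \Omega}
  \bigl(I_t(x) - I_{t+1}(x + u(x))\bigr)^2
  \;+\; \lambda\, E_{\mathrm{reg}}(u),$$

where the displacement field $u$ is a cubic B-spline interpolation of a
regular lattice of control displacements. Sum-of-squared differences is
an adequate similarity because consecutive frames are highly similar at
the frame intervals in scope (minutes). The recovered field maps
earlier-frame coordinates to later-frame coordinates, which is exactly
the direction needed to propagate points forward.

Choices the tier of the algorithm leaves open, and what this package
does:

* **Regulariser.** $E_{\mathrm{reg}}$ is the mean squared lattice
  Laplacian of the control displacements divided by the squared knot
  spacing — a discrete bending energy that is invariant under lattice
  refinement. With this normalisation the published weight
  $\lambda = 0.01$ balances the two terms across resolutions and
  image-content densities; without it, the balance would silently depend
  on the control-grid resolution.
* **Optimiser.** Each resolution level is minimised by L-BFGS-B with the
  analytic gradient of the exact trilinear interpolant, so the objective
  and its gradient are mutually consistent. Four levels, coarsest first,
  with the physical control spacing held at 10 µm (half a cardiomyocyte
  diameter); the coarser solution warms up the next level by sampling
  its displacement field at the finer control positions.
* **Anchoring.** A sequence of $N$ frames is registered outward from the
  midpoint anchor $\lfloor N/2 \rfloor$, giving independent forward and
  backward chains. Propagation error accumulates with chain length, so
  midpoint anchoring roughly halves the worst-case accumulated error
  relative to anchoring at the first frame; the acceptance suite asserts
  this ordering on rendered synthetic scenes.
* **Tolerance and iterations.** Relative target change $10^{-8}$, at
  most 100 iterations per level.
* **Out-of-domain points** are clamped to the volume boundary and
  flagged rather than dropped — meshes legitimately graze the volume
  edge.

Masks are warped through a field by pushforward: the inverse of the
smooth displacement is found by fixed-point iteration and the 0/1 field
interpolated and thresholded at 0.5, so a translation field translates
the mask and a dilation field dilates it.

## Continuous tissue description

The segmentation of the anchor frame is converted to a triangular
surface (marching tetrahedra on the lightly smoothed binary field,
Laplacian smoothing 0.9 × 5 iterations) and each node is propagated
through the field chains. Topology never changes — nodes cannot
exchange positions — so the sequence (the Live-Shape) is a Lagrangian
sampling of the tissue surface. This assumes locally coherent tissue
motion; on tissues with strong cell mixing the assumption fails, and the
mixing-control harness demonstrates the failure mode (accumulated error
grows several-fold faster on random tangential walks than on coherent
flow).

## Staging against the atlas

Specimens are synchronised on the atlas timeline by a morphometric
feature: the ratio h/w of two landmark distances, measurable on
incomplete shapes (the atlas's own staging parameter requires the full
3D shape). Seven landmarks are placed (three replicates, coordinatewise
median) on the anchor frame only and carried to every other frame by the
motion profile. Each atlas group contributes one normal component over
h/w — sample mean and standard deviation per group, equal priors since
group sizes are small — and frames are assigned by maximum posterior.
The maximal leading and trailing runs that share the first (or last)
assigned group are treated as uncertain and must exceed a 0.75 posterior
to stay assigned; per group, the single highest-posterior frame becomes
the representative (ties break to the earlier frame).

## Projection into atlas space

Each staged frame is projected onto the matching atlas shape in three
steps: (1) robust rigid alignment of the atlas onto the live mesh by
expectation–maximisation over a Student's-t mixture (degrees of freedom
3; components at half the live node count; at most 150 iterations;
clouds centred first). Principal-axis candidate initialisations — all 24
proper alignments of the principal frames — make large pose differences
recoverable, and the winning candidate is chosen by a saturating
(Geman–McClure) one-way distance from the target cloud to the aligned
source, which resolves near-symmetric poses that a trimmed or
mutual-pair score misses. (2) Atlas nodes without live support are cut;
the default support radius is 1.5 × the live mesh's median inter-node
spacing. A looser cut retains a margin of atlas surface beyond the
live boundary, and the following morph then stretches the live nodes
tangentially to cover it — on stage-matched synthetic pairs this
roughly doubles the node error relative to the tighter default, which
is why the tighter cut was chosen. (3) Both surfaces are rasterised as thin membrane-shell masks on
a common grid (about 56 voxels across), lightly blurred, and the live
mask is non-rigidly registered onto the cut-atlas mask; the recovered
field moves the live nodes, and the inverse rigid transform carries them
into canonical atlas coordinates. Finally every atlas face is matched to
its nearest morphed face centroid, resolving node-density differences.

The projection standardises geometry but preserves each specimen's own
dynamics: deformation is always computed on the native Live-Shape before
projection, never after, because the morph itself would register as
spurious deformation.

## Finite-deformation mechanics

For each triangle, rest and deformed edge vectors are expressed in local
orthonormal 2D bases (Gram–Schmidt on the two edges); the deformation
gradient is $F = T R^{-1}$. The growth rate $J = \det F$ is the local
area ratio; the strain tensor $\tfrac12(F^\top F - I)$ is available for
completeness. Anisotropy is reported as the ratio of the two principal
stretches — the singular values of $F$ — rather than the ratio of
strain-tensor eigenvalues, which is ill-posed when an eigenvalue crosses
zero; under both readings uniform scaling gives exactly 1 and rigid
motion leaves every quantity unchanged. The principal direction is the
leading right-singular vector lifted through the rest basis. Per-face
values are smoothed by an unweighted mean over a geodesic neighbourhood
(shortest paths on the face-adjacency graph, centroid-distance weights);
the 20-unit default radius matches the scale used to suppress isolated
events such as uncoordinated beating in live data.

## Integration across specimens

Cross-stage anatomical correspondence uses a chain: a reference point
cloud (the eye) is snapped by nearest neighbour to a hook specimen's
SurfaceMap at one stage and carried by that specimen's own morph to the
next stage. For cumulative deformation the carried positions are
averaged over all hooks covering a transition; per reference point the
mean stepwise growth $\bar J_{gr}$ and anisotropy $\bar\theta_{gr}$ are
arithmetic means over contributing embryos (a geometric mean is
available behind a flag, with a message when the two differ by more than
1%), and the cumulative values are the products
$\bar J = \prod_{gr} \bar J_{gr}$, $\bar\theta = \prod_{gr}
\bar\theta_{gr}$. Points without coverage at any step are excluded, not
imputed. For the fate map, averaging across embryos with inconsistent
missing parts would produce physically impossible jumps, so exactly one
hook — the most complete motion profile — links each transition, and a
continuity guard (no jump above ten times the transition's median
displacement) fails the build loudly rather than smoothing over a bad
link.

## The synthetic ground-truth scene

Because no benchmark dataset with analytic truth exists for this
pipeline, the package ships a generator whose truth is closed-form: a
tapered crescent sheet

$$S(u, v, t) = c + \bigl(r_u \cos\alpha,\; r_u \sin\alpha,\; z(u, t)\bigr),
\qquad \alpha = \psi(t)\,(v - \tfrac12),$$

whose arc $\psi$ closes from $\pi$ to $1.85\pi$, radius grows 12 to
14 µm, axial length 36 to 50 µm with a u-dependent stretch modulation,
over a 64³ volume at 1 µm voxels and 8 frames at 10-minute spacing —
matching the field sizes, frame intervals and spans of the live
acquisitions in scope. The taper (±12.5% radius along the axis) breaks
the crescent's two-fold symmetry so pose recovery is well defined. The
surface metric is orthogonal, so the axial and circumferential stretch
ratios, and hence per-face area ratio J and anisotropy, are exact
closed forms. Rendering splats a Gaussian membrane shell (σ 1.2 µm)
plus brighter blobs at 80 labelled cells (σ 1.5 µm, nominal cell radius
3 µm), with additive noise (σ 0.02) and exponential bleaching (2% per
frame). A mixing mode replaces coherent advection with random
tangential walks to reproduce the gastrulation negative control as a
property.

Cohorts fragment the timeline into overlapping windows of 4 of 8 atlas
stages across 6 specimens, each with a random rigid pose, a global size
factor (±7%), its own mesh density (18–26 grid cells), and about 10% of
each tube end removed (the missing inflow/outflow tracts). Size, pose,
density and coverage are the modelled sources of variability; the
underlying shape family is shared, so the analytic deformation remains
the exact reference. What passing tests therefore demonstrate is the
correctness of the integration machinery — staging, projection,
chaining, averaging, multiplication — not robustness to biological
shape variation, which has no ground truth and is assessed in live data
only by the area-pattern transfer check (quantified here as a Spearman
rank correlation, with 0.8 as the acceptance bar where the original
analysis relied on visual consistency).

The synthetic atlas calibration draws 6 specimens per group with a
noise level of a quarter of the smallest adjacent-group gap in h/w
(groups separated by about 4σ), the regime of a well-resolved staging
system.

## Numerical choices and degenerate inputs

* Constant frames rescale to all zeros (documented convention).
* Degenerate triangles (area below $10^{-9}$ µm²) are flagged and
  excluded from deformation maps, never silently filled.
* A singular deformation gradient reports infinite anisotropy with a
  flag.
* Channel merging offers voxelwise sum-clip (default) and maximum; the
  originating workflow does not state the operation.
* The drift corrector uses translational cross-correlation only;
  rotational drift correction is off by default so the stage stays
  deterministic.
* Mask warping thresholds the interpolated 0/1 field at 0.5.
* The integration harness smooths deformation over a 5 µm geodesic
  radius — about two face diameters of the synthetic meshes — enough to
  suppress discretisation noise without erasing the genuine axial
  gradient of the analytic flow; the 20-unit default remains the
  recommendation for live data, where isolated-event noise dominates.
* Problem sizes used by the validation suite: 64³ volumes with 8
  frames for motion estimation; 6-specimen cohorts at mesh densities of
  roughly 500–1300 faces; these sizes keep every check reproducible on
  a laptop in minutes.

## Known limitations

* No diffeomorphic guarantee: the FFD optimum may fold under extreme
  motion; the regulariser discourages but does not forbid it.
* SSD assumes stable intensity statistics between consecutive frames;
  per-frame rescaling mitigates bleaching but not channel crosstalk.
* The chain snaps to mesh nodes, so its spatial resolution is the hook
  mesh's node spacing.
* Tangential correspondence within the projection is constrained only
  by the rigid stage and field smoothness — membrane masks carry no
  tangential texture. The synthetic checks bound this error at about
  one rasterisation voxel for stage-matched shapes.
* Statistical inference across cohorts (testing differences between
  genotypes, say) is out of scope; the framework is descriptive.
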