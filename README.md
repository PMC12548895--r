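# morphomap

Tissue motion and deformation mapping for fragmented 3D+t live imaging
of organogenesis.

## The problem

Live imaging of mammalian organ formation — early mouse heart-tube
morphogenesis is the motivating system — never captures the whole
process in one acquisition: each time-lapse covers a few hours of a
~12-hour transformation, peripheral structures (the inflow and outflow
tracts) drop out of the field, and embryos differ in size, pose and
developmental pace. `morphomap` turns a collection of such fragments
into one quantitative description of the morphogenesis: per-region
tissue growth and anisotropy, cumulative deformation across the full
developmental window, and an in-silico fate map on which pseudo-cells
can be tracked from the cardiac-crescent stage to the heart tube.

## The method in brief

1. **Motion estimation.** Consecutive frames of each specimen are
   aligned with a free-form deformation: a cubic B-spline displacement
   field $u$ minimising
   $\frac{1}{|\Omega|}\sum_x (I_t(x) - I_{t+1}(x+u(x)))^2 + \lambda\,E_{\mathrm{reg}}(u)$
   over a 10 µm control lattice ($\lambda = 0.01$, four resolution
   levels, anchored at the sequence midpoint so propagation error stays
   below a cell diameter in both directions).
2. **Continuous description.** The segmented tissue at the anchor frame
   becomes a triangular mesh whose nodes ride the displacement fields —
   a Lagrangian "Live-Shape" with fixed topology.
3. **Staging.** A landmark ratio h/w, computable on incomplete shapes,
   is modelled per atlas group as a Gaussian mixture; frames are
   assigned by posterior probability (boundary frames need > 0.75).
4. **Spatial mapping.** Each staged frame is projected onto the staged
   reference atlas: robust Student's-t mixture rigid alignment, removal
   of unsupported atlas regions, then non-rigid morphing of membrane
   masks; face-to-face matching gives anatomical correspondences.
5. **Mechanics.** Per triangle, the deformation gradient $F = TR^{-1}$
   yields the growth rate $J = \det F$ (area ratio) and the anisotropy
   ratio of principal stretches, geodesically smoothed.
6. **Integration.** A chain of correspondences carries reference points
   across stages through hook specimens; cumulative growth and
   anisotropy are products of mean stepwise values,
   $\bar J = \prod_{gr}\bar J_{gr}$, and a single-path chain builds the
   Dynamic Atlas fate map.

Everything is validated against a synthetic scene generator
(`makeScene`, `makeSyntheticAtlas`, `makeCohort`) whose deformation has
a closed form, so per-face growth, anisotropy and trajectories have
exact ground truth.

## Worked example

Deformation of a growing, closing sheet between two times, against the
analytic truth:

```r
library(morphomap)

p    <- sceneParams()                  # crescent -> tube family
rest <- sceneMesh(p, t = 0.2)          # early shape
late <- sceneMesh(p, t = 0.7)          # later shape, same topology
dm   <- deformationMap(rest, late, smoothingRadius = 5)
dm
#> DeformationMap on 1152 faces (0 degenerate): median J = 1.736, median theta = 1.248

truth <- analyticDeformation(p, rest@provenance$faceUV[, 1], 0.2, 0.7)
median(abs(growthRates(dm) / truth$J - 1))
#> [1] 0.003746843
```

The map reports, per triangle, a growth rate J (the local area ratio:
the median 1.74 says the sheet grew ~74% in area between the two
times) and an anisotropy ratio (1.25: moderately directional stretch).
The discrete estimates agree with the closed-form flow to about 0.4%.

Registering a rendered scene and checking motion recovery against the
labelled-cell ground truth:

```r
scene <- makeScene(sceneParams(noiseSigma = 0.01), seed = 3)
r     <- renderStack(scene)
stack <- preprocessHyperstack(r$stack, sigma = 0.5)
tset  <- registerSequence(stack, regParams())   # ~2 min, 64^3 x 8 frames
stepwiseError(r$tracks, tset)$overall$mean
#> [1] 0.1454539     # micrometres, versus a 3 um cell radius
```

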