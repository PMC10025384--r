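---
title: "Shape morphometry of the ascending aorta: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape morphometry of the ascending aorta: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortamorph)
```

## The problem

Elective surgery for ascending aortic aneurysm (AsAA) is still indicated
mainly by the maximum diameter, yet aortas below the 55 mm threshold
rupture and large ones sometimes remain stable. Growth rate between two
exams is therefore increasingly used for risk assessment, and the question
this package addresses is whether *local shape* measured at the first exam
predicts which aneurysms will grow fast.

`aortamorph` computes four dimensioned/dimensionless shape features from a
segmented luminal surface mesh of the ascending aorta (annulus to
brachiocephalic-trunk ostium, Valsalva sinuses included):

* **D** — maximum cross-sectional diameter (mm), the clinical reference
  measurement;
* **DCR** — D normalized by the centerline length `L(C)` of the segment,
  separating tall/robust from slender anatomies;
* **EILR** — ratio of the external to the internal curvature-line length,
  sensitive to outward wall expansion (saccular and root aneurysms);
* **T** — tortuosity `L(C)/L(C0)`, with `C0` the endpoint-to-endpoint
  chord.

Downstream, the package computes the growth rate
`GR = (D'' − D') / Δt` (mm/month) between two exams, splits patients at
`GR ≤ 0.25` mm/month (the 3 mm/year guideline rate; boundary inclusive on
the low-risk side), and benchmarks six classifiers — decision tree, linear
discriminant, logistic regression, naive Bayes, SVM, k-nearest neighbours
— under leave-one-out cross-validation (LOOCV), reporting confusion-matrix
metrics, diagnostic likelihood ratios and AUROC.

## Geometric pipeline

### Centerline

The lumen centerline is the medial path between the inlet and outlet.
Interior medial points are obtained with the *shrinking-ball* algorithm:
for each sampled surface point with inward normal, the maximal tangent
sphere empty of other surface samples is found by iterative radius
reduction; its center is a medial point and its radius the local inscribed
radius. Points with radius under 10% of the maximum are discarded,
coincident centers are merged on a voxel grid (0.1 × the maximal radius),
and the survivors form a k-nearest-neighbour graph (k = 10). The
centerline is the shortest path from inlet to outlet with edge weight
`length / r^2`, where the radius term is the smaller of the mean endpoint
radius and the clearance at the edge midpoint — the midpoint term makes
chords that cut across the lumen expensive, so the path hugs
maximal-inscribed-sphere centers. The path is smoothed (centered moving
average, window 5, endpoints fixed, 2 iterations) and resampled uniformly
in arc length (default 100 points, matching the section count).

This construction replaces the Voronoi-diagram medial extraction used by
vascular toolkits such as VMTK: the shrinking-ball field is the same
maximal-inscribed-sphere field that Voronoi vertices of a dense surface
sampling approximate, and on synthetic tubes the two ideas coincide to
well under a percent. The extraction is deterministic — subsampling uses
regular strides and no random numbers are drawn. Seeds default to the
centroids of the two largest boundary loops; a user-supplied centerline
(e.g. from VMTK) can be imported verbatim with `importCenterline()`.

### Domain isolation

`isolateAscending()` cuts the surface with two planes perpendicular to the
centerline: at the annulus (default arc 0, i.e. the proximal end — whether
the upstream tool's centerline starts exactly at the annulus is exposed as
the `annulusArc` parameter) and at the ostium, a required user landmark,
mirroring clinical practice where the brachiocephalic ostium is the one
manually identified point. Cut-plane normals are centerline tangents by
central differences; if a cut disconnects the mesh the component containing
the mid-segment is kept. The result must have exactly two boundary loops.

### Sections and diameter

`extractSections()` places `n = 100` planes at equal arc-length stations.
Each plane/mesh intersection may have several components near curved
regions; the closed component nearest the centerline point is kept, which
discards grazing intersections with other lumen portions. Because the
discrete tangent estimate wiggles near the cut ends, tangents within ~8%
of the arc of either end are blended into the end-ring plane normal, and
terminal stations retry slightly deeper if their contour is still open —
without this, end planes occasionally tilt out through the open boundary.

On each section the maximum diameter is found by a rotating sweep: planes
perpendicular to the section through its center at angular steps of
`α = 10°` (180/α directions). Per direction, the chord through the center
is the segment between the farthest contour intersections on either side;
the maximum over directions is `D_max^k`, and `D = max_k D_max^k`. On
non-convex contours the through-center chord is the stated definition; a
rotating-calipers "any chord" alternative is available via
`chordType = "any"` in `maxDiameterSection()`, since published
descriptions of the sweep are ambiguous on this point. Refining α can
only increase the result (max over a superset); at α = 10° the worst-case
underestimate for an ellipse of major axis 50 mm is
`50·(1 − cos 5°) ≈ 0.19` mm.

### Curvature lines

The internal curvature line (ICL) starts from the shortest *discrete
geodesic*: Dijkstra on the mesh edge graph with Euclidean edge lengths,
over **all** pairs of annulus/ostium boundary vertices. Seeding every
annulus vertex at distance zero (multi-source Dijkstra) gives the same
minimum as enumerating all pairs — asserted against an exhaustive
brute-force oracle in the tests — at a fraction of the cost. Exact
polyhedral geodesics (MMP, heat method) are deliberately out of scope: the
edge-restricted path overestimates slightly, and the subsequent smoothing
(same moving-average scheme, points re-projected onto the surface,
shortening capped at 10%) compensates, as the smoothing step does in the
original imaging pipeline.

For the external curvature line (ECL), each section contributes an anchor:
the ICL is intersected with the section plane, the unit versor from that
point through the section center is cast against the surface, and the
first intersection *strictly beyond* the center is taken — the
strictly-beyond rule resolves what "the intersection with S" means when
the ray re-enters folds. Sections whose ray misses (open ends) are
skipped, with a 20% cap. A natural cubic spline interpolates the ordered
anchors; its length is measured on a 10× oversampled polyline. Because the
first and last sections sit slightly inside the cut planes, the anchor
polyline is linearly extended to the annulus and ostium planes (capped at
5 anchor spacings) so the ECL spans the same extent as the ICL.

On a half-torus tube (centerline radius `R = 40` mm, tube radius
`r = 15` mm) the pipeline recovers the closed forms
`L(C) = πR = 125.66` mm, `ICL = (R−r)π = 78.54` mm,
`ECL = (R+r)π = 172.79` mm, `EILR = (R+r)/(R−r) = 2.2` and `T = π/2` to
well within the test tolerances (2–5%).

## Growth and classification

Growth rate uses the two exams' maximum diameters wherever they occur
along the centerline (they need not be at the same station); negative
rates from measurement noise are kept. Spearman correlations relate each
first-exam feature to GR; the Mann-Whitney test compares GR between
patients with double ECG-gated acquisitions and the rest (gating changes
which cardiac phase the diameter samples). Both tests are delegated to
`stats::cor.test`/`stats::wilcox.test`, which provide exact small-sample
null distributions and tie-corrected approximations.

`loocvClassify()` holds out one patient at a time. Features are
standardized with training-fold statistics (LD/LR/SVM/KNN; trees and naive
Bayes are scale-free). Hyperparameters — tree complexity via `rpart`'s
internal cross-validated pruning, SVM cost over {0.1, 1, 10, 100} by
10-fold inner CV, k over {1,3,5,7,9} by inner LOOCV — are tuned **inside
each training fold** (nested), so model selection never sees the held-out
patient; logistic regression has nothing to tune. A `paperMode` flag
reproduces the laxer protocol of tuning once on the full data set, which
some studies use. Held-out scores are pooled across folds into a single
ROC; AUROC is the Mann-Whitney pair statistic (ties half). Likelihood
ratios handle the degenerate cells explicitly: perfect specificity with
non-zero sensitivity gives `LHR+ = +Inf`; zero sensitivity with perfect
specificity is undefined and returned as `NA`.

Two statistical caveats are worth knowing. First, pooled-LOOCV scores are
*pessimistically biased under the null*: leaving a patient out shifts the
training-fold class statistics away from that patient's class, so
label-permuted cohorts give mean AUROC slightly below 0.5 (about 0.45
with four noise features at n = 50, with a wide spread). The acceptance
checks therefore average several permutation replicates rather than
asserting a single draw. Second, with 9 positives in 50 patients, one
reclassified patient moves sensitivity by 11 percentage points — small
metric differences between models are not meaningful at this cohort size.

## Synthetic data

`makeTube()` builds structured quad-grid tubes split into triangles
(default 200 × 64, giving meshes with vertex positions exact to the
parametric surface): straight cylinders, torus segments, helices
(non-planar tortuosity, ground truth by quadrature), optionally with a
Gaussian radius bulge `r(s) = r + A·exp(−(s−s0)²/2σ²)` emulating a
fusiform aneurysm. Ground-truth features come from closed forms where they
exist and from a 10⁴-point quadrature of the inner/outer profile curves
otherwise.

`simulateCohort()` draws feature vectors from class-conditional
multivariate Gaussians and constructs `D''` from the drawn growth rate and
interval, so `GR = (D''−D')/Δt` holds exactly. Defaults emulate the
reported cohort scale: 50 patients, 9 fast growers (18% prevalence),
feature centers near D = 48.6 mm, DCR = 0.50, EILR = 2.32, T = 1.21 with
SDs from the published interquartile ranges (IQR/1.349), the fast class
shifted mainly in DCR and EILR (about +1.2 SD) and only mildly in D and T
(+0.3–0.5 SD) — consistent with the reported pattern of moderate rank
correlations for DCR/EILR and weak ones for D/T. Low-risk growth rates
center on 0.09 mm/month (IQR ≈ 0.17), fast rates are uniform up to the
0.56 mm/month maximum; intervals are uniform on 6–90 months. What the
generator does **not** emulate: sinus lobes and arch branches, segmentation
and motion artefacts, correlated measurement error between the two exams,
and any real covariance between shape and growth beyond the linear/class
structure imposed — passing tests demonstrate algorithmic correctness on
idealized tubes and statistical machinery, not clinical validity.

## Numerical choices

* Vertex merge tolerance 1e-6 mm (STL repeats facet corners; merging is a
  precondition for all graph algorithms). Zero-area faces dropped.
* Plane cuts snap vertices within 1e-7 mm of the plane onto it; contour
  extraction nudges exactly-on-plane vertices by an infinitesimal instead,
  so every crossing is a clean edge crossing.
* Boundary loops are oriented counter-clockwise about the outward
  best-fit-plane normal and sorted by descending perimeter.
* Diameter-sweep ties break to the smallest angle; the global maximum ties
  to the smallest section index.
* The tortuosity of an extracted centerline is rotation-equivariant only
  up to the medial sampling grid (about 0.5% in practice); the geodesic
  ICL, living on the coordinate-free edge graph, is invariant to numerical
  precision.
* Problem sizes in the tests (meshes of roughly 2–10 k faces, cohorts of
  30–50, Gaussian recovery at n = 200) were chosen as the smallest sizes
  at which the asymptotic statements above are comfortably observable.

## Known limitations

* Single inlet→outlet tubes only: no branch handling, so supra-aortic
  vessels must be removed by the segmentation step.
* The mesh is used as given (duplicate/degenerate cleanup only). Input
  meshes from differently smoothed segmentations will shift features —
  EILR and T are the most sensitive — and the pipeline deliberately does
  not re-smooth.
* Discrete geodesics overestimate true surface geodesics on coarse
  meshes; below ~1 k faces the ICL error can exceed the 3% envelope seen
  at the default resolutions.
* Growth is modeled linearly between two exams; exponential growth laws
  need at least three time points and are out of scope.
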