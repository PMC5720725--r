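---
title: "Methods: statistical shape modelling of labelled tooth surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical shape modelling of labelled tooth surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model and its assumptions

A point-distribution shape model treats every vertex of a corresponded
mesh as a semilandmark. After registration, specimen $i$ is the vector
$x_i = [x_1, y_1, z_1, I_1, \dots, x_M, y_M, z_M, I_M]^\top$ on the
baseline's $M$ nodes, where $I \in \{0, 1\}$ flags enamel. The mean is
$\bar{x} = \frac{1}{N}\sum_i x_i$. Because millimetre coordinates and
unitless labels share one vector, the PCA is run on standardised
variables (the *correlation method*): with per-variable standard
deviation $s$ (computed with the $1/(N-1)$ convention throughout),
eigenvectors $\phi_j$ and weighting coefficients $d_j$,

$$x = \bar{x} + s \odot \sum_{j=1}^{c} \phi_j d_j .$$

The back-scaling by $s$ is the correlation-method reading of the usual
mean-plus-modes instance equation, which as printed (without $s$) is
only dimensionally consistent for covariance PCA. Setting all
$d_j = 0$ returns the mean tooth; $c$ is the smallest number of PCs
reaching a requested cumulative variance. Variance fractions are
reported from the standardised decomposition, matching the basis in
which the PCs are computed (a covariance-matrix variance report over
mixed units would not be interpretable).

Assumptions worth stating: size is *not* removed (no Procrustes
scaling), so the leading PC of any realistic cohort is overall size;
correspondence is as good as the elastic registration; the material
variable is meaningful only on the surface (no volumetric intensity is
modelled).

## Numerical choices in the PCA

* PCs come from the thin SVD of the standardised $N \times V$ matrix;
  the $V \times V$ correlation matrix is never formed ($V$ is ~12k at
  the default mesh resolution).
* Variables with $s < \varepsilon$ ($\varepsilon = 10^{-8}$ native
  units) are marked constant and excluded: most material components
  are identical across specimens deep in the root or crown interior,
  and dividing by a near-zero $s$ would amplify noise unboundedly.
  Constant variables re-enter generated instances at their constant
  values.
* Eigenvector signs are fixed by making each PC's largest-magnitude
  loading positive, so sigma sweeps are reproducible across BLAS
  implementations. The sign itself is arbitrary; monotone trends along
  a sweep may therefore run in either direction.
* Generated material components are clamped to $[0, 1]$; downstream
  they are binarised at the mid-range ($I \ge 0.5 \to I_h = 1$).
* User-facing weights are in per-PC standard deviations
  ($d_j = w_j \sqrt{\lambda_j}$), matching the $-3\sigma..+3\sigma$
  sweep convention.

# Rigid pre-alignment

The chain is: optional programmatic coarse transform (Z-Y-X intrinsic
Euler angles, standing in for interactive manual alignment), per-axis
bounding-box scaling of the baseline to the target, centroid
alignment, and point-to-vertex ICP with a closed-form
(reflection-corrected SVD) update. Two facts, both measured on
generated teeth, forced refinements beyond that textbook recipe:

1. **Bounding-box extents lie.** Extents measured across a residual
   rotation bias the per-axis scale factors by several percent at
   20-30 degrees. `align_chain()` therefore treats the bbox factors
   only as an initial estimate and re-estimates the per-axis scale
   (applied in the baseline's own frame, about its centroid) from the
   current ICP correspondences; at the fixed point both the scale and
   the rigid fit are exact.
2. **Teeth are nearly rotationally symmetric.** The exact-recovery
   basin of plain point-to-point ICP about the tooth's long axis is
   only a few degrees: an azimuthal offset slides vertices *along* the
   surface, which nearest-neighbour distances barely see. Recovery of
   azimuthal rotations therefore needs global initialisation:
   `align_chain()` aligns the principal frames of baseline and target
   (all proper sign combinations, plus both pairings of the two
   nearly degenerate cross-sectional axes, plus small azimuthal
   jitter) and keeps the candidate with the lowest final RMS.
   `icp()` itself stays a plain single-start method with an optional
   `z_starts` multistart argument.

Defaults: ICP capped at 60 iterations per start, improvement tolerance
$10^{-12}$ mm, jitter $\pm 3, \pm 6$ degrees.

# Elastic registration

Each iteration pulls every baseline vertex a fraction $\alpha$
(default 0.5) toward its exact nearest target vertex, then smooths the
**displacement field** with one synchronous Laplacian pass of weight
$\lambda_t = \lambda_0 \rho^{t-1}$ (defaults $\lambda_0 = 0.5$,
$\rho = 0.9$), so early iterations deform coherently and late ones fit
detail. Iteration stops when the mean vertex displacement drops below
`tol` (default $10^{-4}$ mm) or at `max_iter` (200). Connectivity is
never modified; face inversions are warned about with face ids, and a
mean distance that rises for ten consecutive iterations aborts with a
trace.

Smoothing the displacement field rather than the positions is a
deliberate choice: position smoothing moves a *perfectly fitted*
curved mesh (Laplacian shrinkage), so a converged registration would
never be a fixed point and an identical baseline/target pair would not
terminate after one iteration. Field smoothing makes a perfect fit
exactly stationary, which also gives the idempotence property
(re-registering a converged result moves vertices less than `tol`).

Registration runs twice: pass 1 from a user-supplied baseline, pass 2
from the pass-1 mean shape, which is closer to every specimen and
therefore converges at least as well under a matched iteration budget.
Note the displacement-based stopping rule clamps the final
distance-to-target of *both* passes near `tol`; comparisons between
passes are meaningful at a fixed iteration budget (`tol = 0`), which
is how the acceptance suite runs them.

Enamel labels transfer after pass 2: a registered node is enamel iff
its distance to the nearest enamel-mesh vertex is at most `delta`. The
default `delta` is one median target edge length: registered nodes lie
essentially on the target surface, so true enamel nodes sit within a
fraction of an edge of an enamel vertex while dentin nodes are at
least about one edge away; a larger cutoff (e.g. two edges) visibly
dilates the enamel band by one to two vertex rings.

# CEJ identification

Probabilistic material values on synthetic instances are binarised at
0.5, voted onto elements (2-of-3 majority; ties impossible), and the
element partition is smoothed by the rule *flip any element with two
or more opposite-material edge-neighbours*. The sweep is sequential in
element-index order, repeated until no element flips. A synchronous
schedule looks more elegant but is wrong here: along a straight
staircase boundary on a structured triangulation, the entire boundary
band satisfies the flip condition on both sides simultaneously and
enters a two-cycle that never terminates (observed on the default
tooth). The sequential sweep is deterministic (fixed order) and can
only stop in a state with zero rule violations, which is the property
the pipeline needs. Node labels are recovered by majority over
incident elements, ties resolving to enamel so the crown cap stays
closed.

Boundary edges (one enamel, one dentin element) are chained into
closed loops by walking edge adjacency; branch points abort the
affected loop with a warning. An anatomically plausible CEJ is exactly
one loop; the count is the pipeline's continuity check.

# Landmarks and measurements

All criteria operate in the model frame (+x mesial, +y labial,
+z incisal; units mm) with partition planes through the whole-mesh
centroid: the root apex is the global minimum-z node; the five crown
landmarks are extrema over *enamel-labelled* nodes (so a flared root
can never capture them); the four CEJ landmarks are extrema over nodes
of the extracted CEJ curve (min z per labial/lingual half, max z per
mesial/distal half). Ties break to the lowest vertex index. The eight
measurements are Euclidean inter-landmark distances plus enclosed
volume (signed tetrahedron sum; requires a closed mesh) and total
triangle area. Landmarks are deliberately frame-dependent — the
upstream alignment guarantees a common frame, and the test suite
documents that rotating a mesh without re-alignment moves them.

One notation wrinkle: the mesiodistal cervix diameter is defined in
the source notation via CEJ-peak symbols that its own landmark table
does not contain; it is read here as the distance between the mesial
and distal CEJ peaks.

# The synthetic-tooth generator

No micro-CT data accompany the study this package operationalises, so
a parametric generator stands in for it. A canine-like tooth is built
as a surface of revolution with azimuth-dependent elliptical radius:
a convex elliptical crown cap with its bulge at a fixed 35% of crown
height, a root tapering as $(1-s)^{\text{taper}}$ to a single apex
displaced mesially by the curvature parameter, and a CEJ whose height
varies as $\frac{A}{2}\cos 2\theta$ — peaks mesial/distal, troughs
labial/lingual, peak-to-trough $A$. Default dimensions approximate a
permanent mandibular canine (crown 11 mm, root 16 mm, crown diameters
7 / 7.5 mm, cervix 5.5 / 7 mm, $A = 1.5$ mm, ~3k vertices). Every
gross measurement then has a closed form
(`tooth_true_landmarks()` / `tooth_true_measurements()`), which is
what the recovery tests compare against.

Populations draw each mm-valued parameter log-normally (unit mean,
stated CV), optionally through two latent modes: an overall-scale
factor applied to all mm parameters and a crown:root factor applied to
the crown length and inversely to the root length. Surface noise is
independent Gaussian displacement along vertex normals, preserving
closedness. Defaults for study-like cohorts: per-parameter CV 0.05,
noise 0.02-0.05 mm (roughly the micro-CT voxel size of the source
study), group sizes 9/13/5 mirroring its three samples.

Two generator subtleties matter for validity:

* **Correspondence by construction.** At a fixed `mesh_resolution`
  the ring-to-parameter map is identical across specimens, so shape
  vectors can be stacked without elastic registration. This requires
  the crown/root split of the axial ring budget to be a *constant*
  fraction (40%), not proportional to the specimen's lengths — a
  length-dependent split silently re-labels rings between crown and
  root across specimens and corrupts the correspondence.
* **Designed factors.** With two iid latent modes at $n = 30$, the
  sample correlation of the draws is $\pm 0.18$ typically, which
  rotates nearly degenerate principal axes; roughly one seed in ten
  then drops the best mode-PC correlation below 0.9 with no defect in
  the method. `population_spec(orthogonalize_modes = TRUE)` whitens
  the realised log-factors in-sample (exact sd, zero sample
  correlation) — the shape-model validation uses these designed
  factors, exactly as a designed experiment would use an orthogonal
  design matrix.

What the generator does **not** emulate: wear facets, pulp chambers,
cementum as a third material, multi-rooted teeth, segmentation
artefacts, or spatially correlated scan noise. A green test therefore
establishes that the pipeline recovers what it claims on smooth,
single-rooted, cleanly labelled geometry — not that it is robust to
real scan pathology.

# Statistics

* Bland-Altman: differences $a - b$; limits of agreement
  $\text{bias} \pm 1.96\,\text{sd}$ with the $n-1$ standard deviation
  (variants with 2.0 or the $n$ denominator exist; the choice is
  pinned here).
* Regression of each measurement on the sigma level of each PC:
  ordinary least squares, $R^2$, two-sided slope t-test with
  $\alpha = 0.01$.
* Group comparison of PC scores: one-way fixed-effects ANOVA at
  $\alpha = 0.05$, followed when significant by Tukey HSD
  (Tukey-Kramer for unequal $n$) at the same level. Tukey is a
  documented choice — the source text names only "a post-hoc multiple
  comparison test". F statistics, studentised-range p-values and the
  boxplot summaries (quartiles, 1.5 IQR outliers, whiskers at inlier
  extremes, notches $\pm 1.57\,\text{IQR}/\sqrt{n}$) are computed from
  first principles and cross-checked against `aov`/`TukeyHSD` in the
  test suite, so the reported numbers are never a black box.

# Known limitations

* Point-to-vertex registration bounds accuracy by the target's vertex
  density; there is no point-to-plane or sub-triangle matching.
* The elastic scheme can invert slivers near high-curvature regions
  (warned, not repaired); quality is reported, not enforced.
* PCA axes are only as interpretable as the population's eigenvalue
  gaps — two modes of similar variance mix under sampling noise, a
  property of PCA rather than of this implementation.
* The CLI config is JSON (no YAML parser is assumed available).
* Landmark criteria assume a single-cusped, canine-like topology; a
  molar's multiple cusps would defeat the max-z incisal criterion.
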