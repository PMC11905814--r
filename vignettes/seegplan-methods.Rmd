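---
title: "Vessel-risk scoring and prior-constrained SEEG planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel-risk scoring and prior-constrained SEEG planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seegplan)
```

This vignette explains the models implemented by **seegplan**, the
conventions and numerical choices behind them, and what the synthetic
phantoms can and cannot tell you about behaviour on real patient data.

## The planning problem

Stereoelectroencephalography (SEEG) localises the epileptogenic zone by
implanting on the order of ten depth electrodes, each along a straight
stereotactic trajectory from a scalp/skull entry point $E$ to an
intracerebral target $T$. The dominant safety concern is haemorrhage from
vessel transgression, so planning revolves around keeping every part of
every shaft as far from vasculature as the anatomy allows, while keeping
trajectories short, drilling close to orthogonal to the skull, sampling
relevant gray matter, and keeping shafts apart from each other.

`seegplan` operates downstream of image processing: it consumes a tissue
parcellation (NIfTI label volume with a `{id, name, class}` sidecar), a
vessel model (polylines with per-vertex radii in world mm, or a binary
vessel mask), and trajectory tables in world mm (RAS). Registration,
parcellation, and vessel segmentation are explicit non-goals.

## The vessel-proximity risk score

For a trajectory $\overline{ET}$, $N$ evenly spaced nodes $x_1,\dots,x_N$
are placed from $E$ to $T$ inclusive ($N = 128$ by default, spacing
$\lVert T-E\rVert/(N-1)$), and $f(x_i)$ is the shortest distance from node
$i$ to the vessel model. With a safety margin $d_{\min}$ (3 mm default)
and a risk margin $d_{\max}$ (10 mm default):

$$
R_{\overline{ET}} \;=\;
\begin{cases}
\displaystyle\sum_{i=1}^{N} \frac{d_{\max} - f(x_i)}{N\,(d_{\max}-d_{\min})}
  & \text{if } f(x_i) \ge d_{\min} \;\forall i,\\[2ex]
1 + \displaystyle\sum_{i=1}^{N} \frac{d_{\min} - f'(x_i)}{N\,d_{\min}}
  & \text{otherwise, with } f'(x_i) = \min(f(x_i),\, d_{\min}).
\end{cases}
$$

The score lives in $[0,2]$: $0$ when every node clears $d_{\max}$, exactly
$1$ when every node sits on the safety margin, $2$ when the shaft touches
vessels along its whole length. It is continuous across the branch
boundary, monotone (moving any node closer to a vessel can only raise it),
and permutation-invariant in the nodes.

Two conventions needed fixing where the operating definition leaves room:

* **Distances above $d_{\max}$ are clamped** to $d_{\max}$ before the
  first-branch sum, so the score cannot go negative. Clinical vasculature
  is dense enough that node distances near 10 mm are rare, which is why
  the unclamped form was never stressed; clamping preserves the $[0,1]$
  range claim for the first branch.
* **Distances are measured to the vessel surface**, i.e. centerline
  distance minus the linearly interpolated local radius, floored at 0. The
  surface is the physically relevant obstacle; radius-0 models recover
  centerline distance, so either convention is available through the data.

When a parcellation is supplied, **only intracranial nodes participate**
(classes CSF/gray/white/deep-structure) and $N$ becomes the participating
count: the vessel model is intracranial, so extracranial nodes carry no
information and would only dilute the mean. Scoring without a parcellation
uses all 128 nodes; both behaviours are exercised in the tests.

## The other safety metrics

* **Intracranial length (mm):** distance from the first intersection of
  the $E\!\to\!T$ ray with the intracranial space to the target. The
  crossing is located by vectorised bisection between the last
  extracranial and first intracranial node (40 iterations, i.e. well below
  voxel resolution); node spacing (< 1 mm for clinical lengths) makes
  shell-tunnelling between nodes a non-issue at 2 mm voxels.
* **Drilling angle (degrees):** the angle between the trajectory direction
  and the outward skull-surface normal at the skull-entry point; 0° means
  orthogonal drilling. The normal is the (negated, normalised) gradient of
  a Gaussian-smoothed indicator of "at or inside the outer skull table"
  ($\sigma$ = 2.5 voxels, central differences at half-voxel offsets).
  Smoothing over ~2.5 voxels averages the voxelised surface over a patch
  comparable to a drill contact area; on spherical phantoms the radial
  error stays below 2°. The published phrasing ("angle to the outer
  table") is ambiguous between deviation-from-normal and from the tangent
  plane; deviation-from-normal is implemented, consistent with clinical
  means near 19–20°.
* **Gray:white matter sampling ratio:** gray-class node count divided by
  white-class node count over the intracranial risk nodes; undefined
  (`NA`) when no node lies in white matter. Nodes, not modelled electrode
  contacts, are the sampling unit: contact geometry is hardware-specific
  and out of scope.
* **Minimum vessel distance (mm):** minimum of the un-clamped
  participating node distances.

`metrics_table()` computes all five per electrode; per-electrode problems
(degenerate trajectory, no intracranial nodes, no skull crossing,
undefined ratio) become `flags` entries, never aborts.

## Distance backends

Two interchangeable backends evaluate $f(x)$:

* **Exact polyline** (`vessel_distance_polyline()`): the true minimum over
  segments of $\lVert p - x(t)\rVert - r(t)$, $t \in [0,1]$. With a
  linearly varying radius the minimiser is not the orthogonal projection;
  the function is convex in $t$, so the interior critical point is solved
  in closed form (a quadratic) and compared against the endpoints.
* **Grid-sampled field** (`vessel_distance_field()`): the exact surface
  distance evaluated at every voxel center, queried by trilinear
  interpolation. The contract, verified on seeded phantoms, is agreement
  with the exact backend within half a voxel diagonal (1.73 mm at 2 mm
  isotropic). This is the planner's default backend — one field build
  amortises over thousands of candidate evaluations.

`build_distance_field()` (an exact anisotropic Euclidean distance
transform of a binary mask, Felzenszwalb–Huttenlocher in compiled code)
covers the third input modality, a vessel *mask* NIfTI with no polylines;
it is exact to the voxelised vessel, which adds the voxelisation error a
mask inherently carries.

## Spatial priors

A prior is an ellipsoidal summary of where previous electrodes of one
clinical class entered or targeted, in MNI-152 (ICBM 2009a nonlinear
asymmetric) template space. Construction (`build_library()`):

1. **Lesional exclusion.** Electrodes placed for a patient-specific lesion
   are removed; they carry no transferable information.
2. **Grouping** by the clinical `(target zone, approach)` labels into an
   entry point set and a target point set per group. Grouping is driven by
   labels, never inferred by clustering: the groups encode clinical
   judgment, and silent re-clustering would destroy reproducibility.
3. **Outlier exclusion** (`exclude_outliers()`): iteratively remove the
   point with the largest leave-one-out Mahalanobis distance — its
   distance, in SD units, from the ellipsoid of the *remaining* points —
   while that distance exceeds a threshold, with a floor of 5 points and
   deterministic ordering (largest first, ties by lowest id).
4. **Ellipsoid fit** (`fit_ellipsoid()`): center = mean; axes =
   eigenvectors of the sample covariance ($n-1$ denominator) sorted by
   descending eigenvalue, signs fixed (largest-magnitude component
   positive); semi-axes = $k\sqrt{\lambda_j}$.
5. **QC report** instead of manual review: per-group counts, exclusions,
   and covariance condition numbers.

**Why the outlier threshold defaults to 4 SD.** A literal reading of
"outside 1 standard deviation of the remaining electrodes" cannot be the
operating rule: for any $m$ points in 3-D the (non-leave-one-out)
Mahalanobis distances satisfy $\sum_i d_i^2 = 3(m-1)$, so the largest is
at least $\approx\sqrt{3} > 1$ — iterating at threshold 1 removes *every*
group down to the floor regardless of the data. The intent is plainly
"clear outliers". The expected extreme leave-one-out distance of a clean
trivariate Gaussian sample of a few hundred points is about 3.9 SD, so a
threshold of 4 SD leaves clean clusters intact while removing grossly
displaced electrodes; it separates perfectly in the synthetic recovery
conditions (outliers planted at 10 SD), and it is exposed as a parameter
for centers that want a different operating point.

**Semi-axis scale $k$.** "1 SD capturing 95% of variance" is internally
inconsistent in 3-D (1 SD covers ~20% of trivariate mass; $k \approx 2.8$
would cover 95%). The package stores 1-SD semi-axes with a configurable
`k_sd` and records $k$ in the library JSON, rather than resolving the
inconsistency silently.

Transport to patient space (`to_patient_space()`) maps the center
affinely and transports the quadratic form ($\Sigma \mapsto A\Sigma A^\top$,
then re-eigendecomposition), so axes stay orthonormal under anisotropic
affines. Nonlinear (deformation-field) transport is a non-goal.

## The planner

The published contribution is the *constraint set* (paired entry/target
ellipsoids, the safety margin) and the *primary metric* (the risk score);
the search strategy of the clinical software lives in prior publications.
The planner here is deliberately simple and fully deterministic:

1. **Candidates:** a `resolution`³ lattice in each ellipsoid's
   principal-axis frame, keeping points with Mahalanobis membership ≤ k;
   Cartesian product of entry × target points (entry-major order).
   Shrinking an ellipsoid can only shrink its lattice, so candidate sets
   are monotone in $k$.
2. **Hard feasibility:** minimum vessel distance ≥ `safety_margin`
   (default = $d_{\min}$ = 3 mm), drilling angle ≤ 30°, intracranial
   length ≤ 90 mm. The angle/length defaults are package choices bracketing
   clinical means (≈ 19–20° and ≈ 54–56 mm); every threshold is exposed in
   `plan_constraints()`.
3. **Ranking:** lexicographic — risk ascending, length ascending, angle
   ascending, GM:WM ratio descending (undefined last), candidate index as
   a stable tie-break. A strict sort key makes the ranking a total order.
4. **Greedy placement in priority order** with a spacing guarantee: a
   candidate is accepted only if the minimum distance between its
   *intracranial segment* and those of all previously placed electrodes is
   ≥ 5 mm ("crossing or contact" concerns the shafts inside the head, not
   the scalp entries). If no candidate survives, the electrode is marked
   `infeasible->manual` and planning continues — mirroring clinical
   practice, where such electrodes are planned by hand.
   `manual_planning_rate()` summarises that proportion overall and per
   target zone. Greedy sequential placement (no joint optimisation) keeps
   the plan deterministic and desk-scale; the binary auto/manual status is
   a simplification of the clinical spectrum from "tip extension" to full
   replanning.

## Synthetic phantoms

Everything is testable without patient data through two seeded
generators. One global seed feeds named substreams (head, vessels,
history), so changing one component's draw count does not perturb the
others.

* **Head phantom** (`make_head_phantom()`): concentric ellipsoidal shells
  (scalp/skull/CSF/gray/white; default outer radii 88/80/74/70/60 mm,
  axis scales 0.9/1.0/0.85) on a 96³ grid at 2 mm — small enough that the
  full build-priors → plan → score chain runs in seconds, while leaving
  ≥ 10 voxels across the white core. The CSF/gray and gray/white
  boundaries share a smooth angular perturbation (amplitude 3 mm,
  frequency 8) emulating gyral folding; two deep ellipsoidal structures
  stand in for mesial temporal targets.
* **Vessel tree** (`make_vessel_tree()`): branching polylines seeded just
  inside the cortical surface, growing inward with bounded jitter and
  per-level radius decay (root radius 1.5 mm, decay 0.7, depth 3); every
  vertex is intracranial by construction.
* **Implantation history** (`make_history()`): per zone, entry and target
  points drawn from known Gaussians, with a stated fraction displaced by a
  stated Mahalanobis distance (defaults: 5 zones, 200 electrodes/zone, 10%
  outliers at 10 SD, 5% lesional) and a ground-truth record for recovery
  tests. Zone SDs of 1–3 mm reflect the few-mm spread of clinical prior
  ellipsoids.

What passing on phantoms does **not** show: real parcellations have
topologically complex cortex, real vessel trees are far denser
(clinically, trajectories ≈ 10 mm from all vessels were never observed),
real priors have heterogeneous group sizes, and registration error is
absent here by construction. The phantoms validate the *computational*
contracts — geometry, scores, recovery, constraint enforcement — not
clinical performance.

## Evaluation statistics

These primitives are part of the validated method and are implemented
from first principles; base-R equivalents act as independent cross-checks
in the test suite only.

* **Fisher exact 2×2** (`fisher_exact_2x2()`): two-sided $p$ = sum of
  hypergeometric point probabilities ≤ the observed table's (the most
  common convention; conventions differ, so it is stated). Computed in
  log space with a $10^{-12}$ relative tie guard; empty margins give
  $p = 1$.
* **Bonferroni** (`bonferroni_adjust()`): $\min(1, m\,p)$.
* **Krippendorff's alpha** (`krippendorff_alpha()`): nominal metric,
  coincidence-matrix formulation with missing-data support (items need
  ≥ 2 ratings to contribute; within an item rated $m$ times, ordered
  pairs weigh $1/(m-1)$). The optional CI is an item-level bootstrap
  (default 1000 resamples) with a required seed, since no CI method is
  canonical for alpha.
* **Paired t-test** (`paired_t_test()`): classical two-tailed test on
  per-pair differences with a $t_{n-1}$ CI; zero-variance differences are
  flagged degenerate ($p = 1$ if the mean is 0, else $p \to 0$).
* **Random-intercept difference model** (`random_intercept_fit()`): for
  per-electrode differences $y_{ij} = \beta_0 + U_i + \varepsilon_{ij}$
  with patient random effect $U_i \sim N(0, \tau^2)$ and residual
  $\varepsilon_{ij} \sim N(0, \sigma^2)$, the package uses the one-way
  ANOVA method-of-moments estimator: $\hat\sigma^2 = \mathrm{MSW}$,
  $\hat\tau^2 = (\mathrm{MSB}-\mathrm{MSW})/n_0$ truncated at zero, with
  $n_0 = (N - \sum n_i^2/N)/(a-1)$; $\hat\beta_0$ is the grand mean, its
  CI built from the between-patient variance of patient means
  ($t_{a-1}$), which respects within-patient clustering. This closed-form
  moment estimator deliberately replaces REML fitting: same estimand,
  no iterative machinery, exactly reproducible. In balanced designs
  $\hat\beta_0$ equals the paired-t mean difference.

## Numerical choices and degenerate inputs

* Coordinates: world mm, RAS; voxel indices 0-based; NIfTI affine
  convention. Voxel coordinates never cross a file boundary.
* Eigenvector signs fixed by largest-magnitude component positive (ties
  by component order) for byte-stable serialisation; library JSON writes
  full precision and round-trips to ~1 ulp.
* Degenerate trajectories (entry = target) error in scalar APIs and flag
  in table APIs; all-equal point sets are rejected as rank-deficient
  covariance with the deficient direction reported; empty vessel trees
  error in the distance op but `vessels = NULL` is an explicit avascular
  mode (distances $+\infty$, risk 0) used for "vessels removed" analyses.
* The outlier loop's 5-point floor matches the minimum fit size; ties in
  the removal step resolve by lowest electrode id.
* Test problem sizes: 96³ phantom, ~60–70 vessel polylines, 5 zones ×
  200 electrodes, 1000-replicate null simulations — chosen so the full
  suite completes in well under a minute while keeping Monte-Carlo
  standard errors far inside the asserted tolerances.

## Known limitations

* Straight rigid trajectories only; no bolt/drill hardware geometry, no
  electrode contact modelling, no sulcal-crossing penalties.
* Affine template transport only; nonlinear warps are out of scope.
* The greedy planner does not trade one electrode's placement against
  another's; a globally better joint plan can exist.
* The auto/manual dichotomy compresses the clinical spectrum of manual
  adjustment.
* Patient-level published summaries (mean metric tables, planning times,
  inter-rater alpha on clinical ratings) depend on unreleased imaging and
  rater data; the package validates the machinery by property and
  recovery tests instead of reproducing those numbers.
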