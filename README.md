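# seegplan

Computer-assisted planning support for stereoelectroencephalography
(SEEG) depth-electrode implantation. SEEG localises the epileptogenic
zone by implanting about a dozen electrodes along straight stereotactic
trajectories; the dominant safety concern is haemorrhage from vessel
transgression. `seegplan` is aimed at researchers and planning-software
developers who need a reproducible, scriptable implementation of:

* the **vessel-proximity risk score** and the other per-electrode safety
  metrics (intracranial length, drilling angle to the outer skull table,
  gray:white matter sampling ratio, minimum vessel distance);
* **spatial-prior ellipsoids** — template-space summaries of where
  previous electrodes of a clinical class entered and targeted — built
  from an implantation history by lesional exclusion, Mahalanobis outlier
  exclusion, and PCA ellipsoid fitting;
* a **prior-constrained planner** that searches candidate trajectories
  inside paired entry/target ellipsoids under hard feasibility
  constraints and an inter-electrode spacing guarantee;
* the **evaluation statistics** used to validate such planners (Fisher
  exact 2×2, Bonferroni, Krippendorff's alpha, paired t-test,
  random-intercept moment estimator);
* seeded **synthetic head phantoms** (tissue shells, branching vessel
  trees, implantation histories with known ground truth) so the entire
  pipeline runs and is testable without patient data.

## The risk score

For a trajectory $\overline{ET}$, $N = 128$ evenly spaced nodes $x_i$ are
sampled from entry to target and $f(x_i)$ is the shortest distance from
each node to the vessel model. With safety margin $d_{\min} = 3$ mm and
risk margin $d_{\max} = 10$ mm:

$$
R_{\overline{ET}} =
\begin{cases}
\sum_i \dfrac{d_{\max}-f(x_i)}{N(d_{\max}-d_{\min})} & \text{if } f(x_i)\ge d_{\min}\ \forall i\\[1.5ex]
1+\sum_i \dfrac{d_{\min}-f'(x_i)}{N\,d_{\min}} & \text{otherwise},\quad f'(x_i)=\min(f(x_i), d_{\min})
\end{cases}
$$

$R \in [0,1]$ while every node keeps the safety margin, $(1,2]$ once any
node breaches it; 0 = fully clear at 10 mm, 1 = everywhere exactly at the
margin, 2 = touching vessels along the whole shaft. Lower is safer.

## Worked example

Everything below is synthetic and seeded; it runs in a few seconds.

```r
library(seegplan)

# risk-score anchors
risk_score(rep(10, 128))              # 0      (fully clear)
risk_score(rep(3, 128))               # 1      (everywhere at the margin)
risk_score(c(rep(5, 64), rep(2, 64))) # 1.166667  = 1 + 64*(3-2)/(128*3)

# a head phantom, its vessel tree, and a synthetic implantation history
spec    <- phantom_spec(seed = 17)
head    <- make_head_phantom(spec)
vessels <- make_vessel_tree(spec, head)
hist    <- make_history(history_spec(seed = 202))

# build the spatial-priors library from the history
lib <- build_library(hist$history)
lib
#> prior_library (MNI152-ICBM2009a-nlin-asym): 10 ellipsoid(s) (5 target, 5 entry), 5 pairing(s)

# plan two electrodes inside their prior ellipsoids
req <- data.frame(
  id     = c("A", "B"),
  target = c("amygdala/target/lateral", "posterior_hippocampus/target/lateral"),
  entry  = c("amygdala/entry/lateral",  "posterior_hippocampus/entry/lateral"))
plan <- plan_implantation(req, lib, diag(4), head, vessels)
plan$placements[, c("electrode_id", "status", "length_mm", "angle_deg",
                    "risk_score", "gm_wm_ratio", "min_dist_mm")]
#>   electrode_id status length_mm angle_deg risk_score gm_wm_ratio min_dist_mm
#> 1            A   auto  39.84603  19.24986 0.05941994   0.3157895    7.921173
#> 2            B   auto  28.57525  21.41702 0.00000000   0.6097561   25.451947
manual_planning_rate(plan)$overall
#> [1] 0
```

Both electrodes planned automatically: shafts 40 mm and 29 mm long,
drilled about 20° from the skull normal, never closer than 7.9 mm to a
vessel, with first-branch risk scores of 0.059 and 0 (the second corridor
is entirely beyond the 10 mm risk margin). An electrode for which no
candidate satisfies every hard constraint (and the 5 mm spacing to
already-placed shafts) would instead be reported `infeasible->manual`.

The evaluation statistics are available directly, e.g. the implantability
contingency of two planning methods (246/280 vs 246/277 rated
implantable):

```r
fisher_exact_2x2(matrix(c(246, 34, 246, 31), 2, byrow = TRUE))
#> [1] 0.7922322
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/seegplan` with subcommands `phantom`, `build-priors`, `plan`,
`score`, and `stats`.

## Documentation

The methods vignette (`vignettes/seegplan-methods.Rmd`) documents the
models, conventions (surface vs centerline distance, intracranial node
masking, deviation-from-normal drilling angle, outlier-threshold
calibration), numerical choices, what the phantoms do and do not emulate,
and known limitations.
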