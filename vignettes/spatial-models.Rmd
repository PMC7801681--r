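---
title: "Spatial models and the SDI test for confined 3D object patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial models and the SDI test for confined 3D object patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Many biological image-analysis questions reduce to the same abstract one:
given repeated 3D observations of finite-sized objects inside a bounded,
irregular domain — heterochromatin chromocenters inside a cell nucleus is
the motivating case — do the objects follow some spatial organization rule
(attraction to the boundary, mutual repulsion, radial layering), or is the
observed arrangement explained by chance once the domain shape, the number
of objects and their sizes are accounted for?

Classical spatial statistics (single 2D patterns of dimensionless points in
arbitrary windows, edge-corrected summary functions, comparison against
complete spatial randomness only) fits this setting poorly. `sdi3d`
implements the alternative this package is built around:

* objects are **hard spheres** (centroid $p_i$, equivalent radius $r_i$)
  confined to a domain $D$, with non-overlap
  ($\lVert p_i - p_j \rVert \ge r_i + r_j$) and containment
  ($\lVert p_i - p_i' \rVert \ge r_i$, with $p_i'$ the closest boundary
  point) both allowing exact contact;
* edge effects are handled by **conditional simulation** — every model is
  simulated in the observed domain with the observed object count and radii
  — rather than by analytic edge corrections;
* goodness-of-fit is assessed per pattern with a Monte-Carlo index (the
  **SDI**) whose population distribution is uniform exactly when the model
  fits, so collections of heterogeneous patterns can be tested together.

# Descriptors

Six cumulative distance distribution functions summarize a pattern
$\mathcal{P} = \{p_1, \dots, p_N\}$ in domain $D$. All are estimated with
strict indicator sums, e.g.
$\hat F(x) = \frac1L \sum_k \mathbb{1}\{\lVert q_k - \eta(q_k)\rVert < x\}$:

| id | distance | sensitive to |
|----|----------|--------------|
| F | evaluation position to nearest object centroid | void spaces (aggregation vs. regularity) |
| G | object to nearest neighbour | short-range interactions |
| H | every unordered object pair | all scales |
| B | object to nearest boundary point | peripheral positioning |
| C | object to domain centroid | radial positioning (robust in flat domains where B saturates) |
| Z | object to farthest neighbour | long-range structure |

Descriptors use centroid-to-centroid (and centroid-to-boundary) distances;
object size enters through the hard-core constraint of the models, not
through surface distances. A `dist_cdf` is a step function equal to the
total weight of jumps *strictly below* the argument, so `eval_cdf(f, a)`
is 0 at the smallest jump `a` — the convention the indicator-sum estimators
imply. The sandwich inequality $\hat Z \le \hat H \le \hat G$ holds
pointwise for every pattern.

For F, the evaluation positions are the foreground voxel centres when the
domain is image-backed; for analytic or mesh domains, `eval_positions()`
draws `L` uniform points (default `L = 10000`, about the voxel count of a
small nucleus). The same position set is shared between an observed pattern
and all of its model simulations, which removes one Monte-Carlo variance
source from the comparison.

# Spatial models

All models are conditioned on domain, $N$ and radii
(`condition_spec()`):

* **csr** — sequential random addition: candidates uniform over the
  domain, rejected on overlap or boundary crossing. When an object
  accumulates `restart_threshold` (default 1000) failed candidates the
  pattern is cleared and the insertion order re-randomized; after
  `max_restarts` (default 100) cycles the packing is declared infeasible.
  The per-placement distribution is uniform conditional on validity.
* **border_attraction / border_repulsion** — as csr, but a *valid*
  candidate at boundary distance $d$ is kept with probability 1 on the
  favoured side of $\mu$ and $\exp(-\frac12((d-\mu)/\sigma)^2)$ otherwise.
  Only validity failures count toward the restart threshold: bias
  rejections indicate no packing difficulty. With $\mu \ge$ the domain
  inradius, attraction reduces exactly to csr.
* **orbital** — each object is uniform on its *orbit*, the iso-surface of
  a fixed boundary distance (measured on the conditioning pattern). Sphere
  domains sample the concentric shell analytically (the orbit is then
  honoured to machine precision); other domains use rejection sampling
  within `orbit_tol` (default 1% of the mean radius).
* **max_repulsion / orbital_max_repulsion** — the configuration minimizing
  the energy $E = -\frac1N \sum_i \min_{j \ne i} \lVert p_i - p_j \rVert$
  (negative mean nearest-neighbour distance), found by Metropolis
  annealing started from a csr (resp. orbital) draw; the orbital variant
  projects every move back onto the object's orbit.

## Annealing details

The energy landscape is non-convex, so `maximize_repulsion()` uses
simulated annealing with the *best-visited* configuration as the contract:
whatever the schedule does, the returned pattern is the lowest-energy valid
configuration encountered, and the reported best-so-far trace is
nonincreasing by construction. Choices, all overridable via `control`:

* proposals are uniform in a ball of radius $\delta$ around the current
  centroid; $\delta$ starts at the mean radius and adapts by a factor 0.9
  toward 30% acceptance per window; invalid proposals count as rejections;
* $\beta_0$ is calibrated from 100 probe moves so that initial uphill
  acceptance is about 0.5 ($\beta_0 = \ln 2 / \mathrm{median}\,\Delta E^+$),
  then grows geometrically by 1.05 per sweep of $N$ moves;
* "stabilization of energy" is operationalized as a relative mean-energy
  change below $10^{-4}$ between consecutive windows of $50N$ proposed
  moves, with a hard cap of $2000N$ moves; hitting the cap is reported in
  the fit object, not raised;
* sphere domains run in compiled code; other domains use an R path whose
  orbit projection walks along the boundary-distance gradient (projection
  failure counts as rejection).

With two objects in a sphere the optimum is known (antipodal placement,
nearest-neighbour distance $2(R-r)$) and the annealer reaches it within 2%,
which is the regression test the schedule must keep passing.

# The SDI test

For one pattern and one descriptor, `sdi_test()`:

1. simulates `n_sim1` (default 99) conditioned patterns and averages their
   descriptor estimates into the model mean $\bar f$ (a weighted step
   function — the pooled jump distribution);
2. finds $x^\* = \arg\max_x |f_{\mathrm{obs}}(x) - \bar f(x)|$ and the
   signed deviation $S = f_{\mathrm{obs}}(x^\*) - \bar f(x^\*)$. Both
   functions are piecewise constant, so the supremum is attained among the
   right-limits at the union of jump abscissae; ties are broken toward the
   smallest abscissa;
3. simulates `n_sim2` (default 99) further patterns, scores each *exactly
   like an observation* (its own $x^\*$ against the same first-set mean),
   and reports $\mathrm{SDI} = \#\{S_{\mathrm{sim}} > S_{\mathrm{obs}}\}/n_{\mathrm{sim2}}$.

The SDI is a Monte-Carlo p-value against the "observed function above the
model mean" alternative: SDI near 0 means the descriptor runs above the
model expectation at the maximizing abscissa (for B, objects closer to the
boundary than the model predicts; for F, smaller void spaces), SDI near 1
the opposite. This orientation is what makes the index readable in the
descriptor tables: low B-SDI = peripheral attraction, high G-SDI = larger
nearest-neighbour spacings than the model. Under the generating model the
observed pattern and second-set simulations are exchangeable, so the SDI is
uniform on the lattice $\{0, 1/n_2, \dots, 1\}$; the lattice discreteness
(multiples of 1/99 by default) is accepted rather than smoothed, and ties
($S_{\mathrm{sim}} = S_{\mathrm{obs}}$, which happens with step functions)
are not counted.

Two decision-sensitive points, resolved as follows:

* each second-set simulation recomputes its own maximizing abscissa rather
  than reusing the observed $x^\*$ — this is what keeps observation and
  simulations exchangeable, hence the SDI exactly calibrated;
* the first-set mean is kept fixed for all scorings, so the statistic is
  conditionally i.i.d. given the first set.

`test_uniformity()` applies the asymptotic two-sided Kolmogorov–Smirnov
test to the SDI values exactly as observed (no continuity correction), and
`compare_mean_distances()` pairs each pattern's mean
nearest/pairwise/farthest distance with its conditioned model prediction in
a two-sided Wilcoxon signed-rank test. No multiple-testing correction is
applied across descriptors; reports print all descriptor p-values side by
side and leave the correction to the analyst.

## A structural degeneracy worth knowing about

Orbital conditioning fixes every object's boundary distance, so the
simulated B̂ jump multiset *equals* the observed one by construction, and in
a spherical domain the same holds for Ĉ. All deviations are then exactly
zero, every SDI is 0, and uniformity is unattainable: **B (and C in
spheres) carries no information against orbital-family models**. Use F, G,
H and Z there — that is precisely their role. The envelope bands
(`estimate_model_function()`) have a related small-sample quirk: with very
few jumps the discrete order statistics can sit on one side of the mean, so
the band is clipped to contain the mean; envelopes are diagnostic only and
never enter the inference.

# The synthetic benchmark generator

`generate_fixtures()` writes the package's reference conditions: patterns
of 10 spheres of radius 5 in a spherical domain of radius 30 (voxel units)
under csr, border attraction ($\mu = 5$, $\sigma = 5$) and border repulsion
($\mu = 15$, $\sigma = 5$), 100 patterns per model by default. These
parameters are the study conditions of the acceptance suite, chosen so that
roughly a tenth of the domain volume is occupied and the border biases act
on a length scale (one object diameter) where both B and G respond.

What the generator emulates: hard-core packing in a confined domain, and
radial biases of realistic strength. What it deliberately does not emulate:
non-spherical and flattened domains, heterogeneous radii, segmentation
noise, anisotropic voxel artifacts, or object-count variability — so a
green test suite demonstrates the statistical machinery is calibrated and
directionally correct, not that any particular biological dataset follows
these models. Mesh- and mask-backed domains are exercised separately in the
geometry tests.

# Numerical choices

* **Voxel convention**: voxel $(i,j,k)$ (0-based) has its centre at
  $((i{+}0.5)s_x, (j{+}0.5)s_y, (k{+}0.5)s_z)$; all computation is in
  physical units, anisotropic spacing allowed and never read from TIFF
  tags.
* **Iso-surface extraction** (`mask_to_mesh()`): marching tetrahedra on
  the Kuhn 6-tetrahedron decomposition at iso-level 0.5. Unlike
  table-based cube marching it has no ambiguous configurations, so the
  mesh is watertight and consistently oriented for any binary mask —
  a property the rest of the package (ray-parity containment, signed-tet
  volume and centroid) relies on. No mesh smoothing is applied by default;
  volume converges to the voxel-count volume (within 5% for blobs ≥ 15
  voxels across), but the *area* of a staircase surface is inflated by
  ~25–30%, so sphericity ($\psi = \pi^{1/3}(6V)^{2/3}/A$, 1 for a perfect
  ball) is computed from a mesh extracted off a 3×3×3 box-smoothed
  indicator with linear vertex interpolation, recovering $\psi \approx
  0.99$ for rasterized balls; objects too small to survive smoothing fall
  back to the raw indicator.
* **Mesh queries**: point-in-mesh by ray parity with a fixed direction and
  random re-draws on grazing hits; closest boundary point by exhaustive
  point-to-triangle distance (first-index tie-break, so results are
  deterministic); interior-point distance for axis-aligned ellipsoids by
  root-finding on the standard one-parameter closest-point equation.
* **Degenerate inputs**: the domain centre of a sphere has every boundary
  point closest — the +x pole is returned deterministically. Empty
  patterns are representable and round-trip through the file format;
  descriptor estimation refuses them explicitly. Patterns extracted from
  real masks that violate the equivalent-sphere constraints (touching,
  elongated objects) are returned with a violation report
  (`validate_pattern()`), while simulators always enforce the constraints
  exactly.
* **Reproducibility**: every stochastic entry point takes a seed; a single
  seed drives pattern simulation, position sampling and annealing through
  one sequential RNG stream, so identical configurations reproduce
  identical files byte for byte.

# Problem sizes used by the test and acceptance suites

Population-level checks run at a reduced tier chosen as a sensible
statistical size for routine verification: 40–50 patterns per model with
49 + 49 simulations and 1000–2000 F-positions (the full-size protocol, 100+
patterns with 99 + 99 simulations, is used where the border-bias directions
are asserted). The KS uniformity checks at $\alpha = 0.01$ are stochastic
by nature and are run under fixed seeds.

# Limitations

* The SDI captures only the largest deviation per descriptor; antagonistic
  effects at different scales need multiple descriptors (that is why six
  are provided).
* Only equivalent-sphere geometry is modelled; strongly non-convex objects
  are summarized by centroid and radius.
* The orbital-family degeneracy of B/C described above.
* Mesh/mask domain queries are exhaustive per face; they are comfortable at
  segmentation-mesh sizes (thousands of faces) but not tuned for very
  large meshes.
* `simulate_csr` is random *sequential* addition conditioned to validity —
  for the sparse packings used here it is indistinguishable from the
  uniform hard-core distribution, and it is exactly the construction the
  conditional test machinery assumes.
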