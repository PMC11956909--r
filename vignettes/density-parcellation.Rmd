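---
title: "Density-based parcellation of whole-brain cell-type point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based parcellation of whole-brain cell-type point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densityatlas)
```

## The problem

Whole-brain imaging of nuclear reporter lines yields, per animal and per
cell type, a cloud of millions of 3D nucleus coordinates registered to a
common reference space. Two complementary questions follow. First, the
*compositional* one: how do atlas regions differ in their cell-type make-up,
and which regions resemble each other? Second, the *spatial* one: can
anatomical territories be delineated directly from local cell density,
without drawing on expert-annotated boundaries at all? `densityatlas`
implements a pipeline for both, together with a synthetic-brain generator
that makes every stage testable at desk scale, and an unsupervised nuclei
detector for the image stacks such point clouds come from.

## Regional quantification and composition clustering

Points are assigned to regions by voxel lookup in an integer label volume.
The convention is fixed and documented: world coordinates in micrometres are
corner-anchored, voxel `(i, j, k)` covers the half-open box
`[i*s_x, (i+1)*s_x) x ...`, and a point maps to `floor(coord / spacing)`. A
point exactly on a shared face therefore belongs to the higher-index voxel;
tests pin this down. Region volumes are voxel counts times the voxel
volume, so a density is exactly `count / volume` with no geometric
approximation that a voxel-counting oracle could disagree with.

Per cell type, regional densities (cells/mm^3) are *max-normalised*: each
type's column is divided by its maximum over regions, mapping every profile
into [0, 1] with the peak region at exactly 1. This removes the huge
between-type abundance differences (a pan-neuronal marker would otherwise
swamp a sparse interneuron type) while preserving each type's regional
pattern. All-zero columns are left at zero with a warning rather than
producing NaN.

Regions are then clustered on the correlation distance between their
normalised composition profiles (`d = 1 - Pearson r`, range [0, 2]) with
Ward's update rule applied directly to those dissimilarities. Two caveats
are deliberate and documented rather than hidden:

* Ward's method is derived for squared Euclidean distances; applying its
  Lance-Williams update to correlation dissimilarities is formally improper
  but is the method of record for this analysis style. We implement the
  update rule verbatim and verify it against `stats::hclust(method =
  "ward.D")` on tie-free inputs.
* Exact ties are broken by the lexicographically smallest (min index, max
  index) pair of cluster ids, so trees are reproducible across platforms.
  Heights are merge dissimilarities and are non-decreasing under this
  update; flat cuts at `k` are nested refinements of cuts at `k - 1`.

The number of clusters `k` is an analyst's choice (the motivating analyses
cut at four major groups); nothing in the package selects it automatically.

## The percentile-DBSCAN parcellation

The core procedure works on one cell type at a time:

1. **Neighbour counts.** For every cell, count the other cells within
   `epsilon = 150` um (Euclidean, boundary inclusive, self excluded). The
   count is computed with a uniform-grid spatial index but is contractually
   identical to the all-pairs definition, and unit tests enforce exact
   agreement with an O(n^2) oracle.
2. **Percentile thresholds.** Per subject, reduce the counts to the 10th,
   20th, ..., 90th percentiles (linear interpolation between order
   statistics — `quantile` type 7). Average each percentile over subjects,
   multiply by the number of subjects, and round (half up) to get the
   pooled *MinPoints* for that level. The multiplication matches the pooled
   clustering below: stacking `n` statistically identical brains multiplies
   local counts by `n`.
3. **DBSCAN sweep.** Run DBSCAN once per level on the pooled cloud at the
   fixed `epsilon`: a point is *core* if its neighbour count is at least
   MinPoints; clusters are the epsilon-connected components of core points;
   non-core points within epsilon of a core point attach to the cluster of
   their lowest-index core neighbour; the rest is noise. Because MinPoints
   is non-decreasing in the level, core sets are nested across the sweep —
   high percentiles carve out only the densest foci inside the territories
   the low percentiles delineate. This nestedness is asserted exactly in
   the tests.
4. **Density units.** A neighbour count `k` converts to a per-brain density
   `(k / n_subjects) / V_eps` with `V_eps = (4/3) pi (0.15 mm)^3 ~ 0.01414
   mm^3`, so thresholds are reportable in cells/mm^3. One count is worth
   `1 / V_eps ~ 70.7` cells/mm^3, which bounds every rounding error in the
   round trip between counts and densities.

Conventions worth restating because reference implementations differ: the
neighbour count *excludes* the point itself (classical DBSCAN includes it);
the boundary is *inclusive* (distance exactly epsilon is a neighbour); both
the implementation and the brute-force reference used in tests share these
conventions, and the shift they induce relative to the self-inclusive
convention is a single count (~71 cells/mm^3), negligible at the densities
involved. Border-point ties go to the lowest-index core neighbour and
cluster ids are ordered by lowest member index, making results a pure
function of the input row order.

Cluster quality against an atlas is scored by Dice and Jaccard overlap of
point sets (cluster members vs region members), which quantifies statements
like "the top-percentile cluster coincides with region X" without any
anatomical naming.

## The synthetic brain

The generator defines the conditions every test runs under:

* **Toy atlas.** A 4 x 4 x 2.4 mm volume at 50 um isotropic voxels with
  eight disjoint regions (six boxes, two spheres, 0.06-1.5 mm^3). It makes
  no attempt to mimic cortical layering or realistic region shapes; it
  exists so that assignment, quantification and overlap scoring have exact
  ground truth.
* **Point clouds.** Within each region each cell type is a homogeneous
  Poisson process: per labelled voxel, a Poisson count at `lambda x voxel
  volume`, placed uniformly inside the voxel — an exact draw, not an
  approximation. The default intensity table spans, at full scale, the
  regional density range such data exhibit (~2e4 to 5e5 cells/mm^3) in four
  two-region blocks, so composition clustering has a planted partition.
  Demonstration cohorts use a scaled-down table (`scale = 0.005`, ~1e5
  points across six subjects); the clustering and parcellation behaviour
  probed by the tests is invariant to this scale, and the published density
  values themselves are used unscaled in the parameter-recovery checks.
  Group effects are multiplicative per (cell type, group). Reproducibility
  is exact: subject `i` under root seed `s` draws from seed `(s * 48271 +
  i * 391) mod (2^31 - 1)`.
* **Image stacks.** Nuclei render as anisotropic Gaussian blobs (sigma =
  nuclear radius, converted to voxels per axis) on a constant background
  with additive Gaussian noise, at micrometre in-plane sampling and 50 um
  section spacing. The generator returns the true centroids so detection
  can be scored exactly. What it does *not* emulate: autofluorescence
  gradients, optical blur anisotropy beyond the voxel grid, cell clumping,
  or intensity variation between nuclei — so a high F1 here bounds
  detector correctness on clean data, not its performance on real tissue.

## The nuclei detector

The unsupervised stage mirrors a standard bright-blob pipeline: Gaussian
regularisation at a nuclear scale (sigma in um, converted per axis to
voxels; the z sigma at 50 um spacing is below one voxel, so no z smoothing
occurs and anisotropy is handled by per-axis derivatives in physical
units), the second-derivative (curvature) tensor per voxel, and the score
`prod(max(0, -lambda_i))` over its eigenvalues — positive only where
intensity curves downward along all three principal directions. The
threshold is a percentile of the score distribution (robust to amplitude
units; the response is also invariant to affine intensity rescaling), then
26-connected components, a size filter, and score-weighted centroids.

Numerical choices: the size floor defaults to 8 voxels because the
regularised score field has a correlation length of roughly sigma, so pure
noise produces spurious components of up to ~7 voxels at realistic noise
levels, while in-focus nuclei span tens of voxels at micrometre sampling.
Two nuclei closer than about one diameter in the same section merge into
one component — a documented merge, not a defect; the matcher then scores
it as one hit and one miss. Detection counts are monotone non-increasing
in both the percentile and the size floor.

Scoring uses maximum-cardinality one-to-one matching between detections
and ground truth within a radius (augmenting-path search). TP/FP/FN depend
only on the maximum cardinality, which is unique; the mean centroid error
is averaged over the matched pairs and can vary slightly between
equal-cardinality matchings.

The gamma-compression + Sobel operator used to enhance anatomical features
before registration is included as a self-contained image transform;
registration itself (an external-toolbox affair) is out of scope.

## Group comparison

Per (region, cell type), per-subject densities are compared between two
groups with Welch's t test (Mann-Whitney behind `test = "wilcoxon"`), and
Benjamini-Hochberg correction is applied across all region x type tests
jointly; effects are reported as ratios of group means. Rows where a group
has fewer than two subjects are flagged untested rather than dropped
silently. Calibration fixtures use Gaussian between-subject noise (sd =
CV x mean), the large-count Poisson limit of regional densities and the
assumption Welch's test is built on; under that fixture the measured
per-test size at n = 8 is ~0.0485. A known limitation: on skewed
(lognormal) noise at small n the Welch test is mildly conservative
(measured size ~0.047 at CV 10%, n = 8), so discovery counts on strongly
skewed data will be slightly pessimistic, not inflated.

## Problem sizes and numerical tolerances

The test and acceptance fixtures use these sizes, chosen so the full suite
exercises every claim on one CPU in minutes while keeping Monte-Carlo error
well below the asserted tolerances:

* Density recovery: one draw per published density value in boxes sized for
  ~3e4 points (0.42-1.05 mm side); the estimator uses interior points only
  (at least epsilon from the box boundary) because a boundary cell's
  epsilon-ball leaves the sampled domain and would bias the estimate
  downward. Expected relative error is ~0.6%, asserted at 2%.
* Planted insert: a 350 um-radius sphere at the published top-to-bottom
  percentile density contrast (~10.6x), with both intensities divided by 16
  so the fixture stays at ~2e4 points; the Dice target of 0.9 is asserted
  per seed over five seeds. The contrast ratio, not the absolute scale,
  drives recovery; the border shell a cluster gains around a dense insert
  scales like `(lambda_bg / lambda_in) * 3 epsilon / R`, which caps
  attainable Dice at ~0.95 for this geometry.
* Oracle equivalence: exact partition identity on 20 mixed blob/noise
  fixtures (n <= 500) and exact count identity at n = 2000 over 10 seeds.
* Comparison calibration: 200 replicates of a 50 x 5 null grid (50,000
  tests) for the size check; 20 replicates for the 20%-effect power check.
* Detection: five 400 x 400 x 8 stacks with 200 nuclei each at peak/noise
  = 10, minimum same-slice separation 14 um (under 2% of truth pairs
  within one matching radius).

## Known limitations

* The toy atlas is geometrically trivial; overlap scores against it say
  nothing about performance on convoluted real anatomy.
* Homogeneous within-region intensity is an idealisation; the generator has
  no gradients, so the parcellation's behaviour on smoothly varying density
  fields is untested here.
* Ward-on-correlation inherits the impropriety discussed above; trees are
  reproducible and cross-checked, but heights have no variance
  interpretation.
* The detector is tuned for the rendered-blob regime; real stacks with
  autofluorescence or touching nuclei will need parameter changes and
  would historically motivate a learned detector bootstrapped from this
  one.
* Whether percentile thresholds should be computed on single brains or the
  pooled cloud is exposed as a choice (`percentile_thresholds` on any
  subset); the pooled construction is the default throughout.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "demo_run", seed = 1)
manifest <- run_pipeline(cfg)
```

This generates a six-subject cohort (~1e5 points), writes the atlas
(NIfTI + region CSV), the tidy and normalised density matrices, the Ward
linkage and 4-cut labels, the nine-level threshold table and parcellation,
cluster-region overlaps, and the male/female-style comparison table, plus
`manifest.json` with an md5 hash per artefact; rerunning the identical
config reproduces identical hashes.
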