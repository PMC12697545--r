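---
title: "Axis-aware analysis of chromatin tracing data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axis-aware analysis of chromatin tracing data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axistrace)
```

This vignette is the package's own account of its statistical machinery:
the trace model and its assumptions, every tunable parameter with its
default and rationale, what the synthetic generator does and does not
emulate, the numerical choices, and the known limitations. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The trace model

A chromatin trace is the ordered set of 3D positions (nm) of `p`
consecutive genomic bins in one chromosome copy of one cell. After
centering each trace (subtracting its per-axis mean over observed spots),
the observed coordinates on one axis are modelled as

$$x = \tilde{x} + \varepsilon_x, \qquad
  \tilde{x} \sim N_p(0, K), \qquad
  \varepsilon_x \sim N_p(0, \sigma_x^2 I),$$

and likewise for y and z with the *same* signal covariance $K$ (the three
axes are exchangeable views of the same polymer) but *axis-specific* noise
variances $\sigma_x^2, \sigma_y^2, \sigma_z^2$. The asymmetry is physical:
spots are localized in x–y imaging planes acquired along a z stack, so the
axial precision generally differs from the lateral one.

Squared 3D distance decomposes as the sum over axes of squared coordinate
differences, so every distance-based 3D-genome feature (loops, domains,
compartments) leaves the same signature in each axis's pairwise-difference
variances — just diluted by that axis's noise. The package therefore
processes axes separately and re-combines them with noise-adaptive weights,
instead of collapsing to Euclidean distances where the noisiest axis
contaminates all of them.

### Noise estimation and weights

With $K$ of low rank, most per-bin variances $\mathrm{Var}(x_j)$ equal
$\sigma_x^2$ plus a small signal contribution confined to a minority of
bins, so the **median of the per-bin sample variances** (pairwise-complete
across traces, denominator $m-1$) is a robust noise estimate. Weights are
normalized inverse variances, $w_a \propto 1/\hat\sigma_a^2$, as in
inverse-variance meta-analysis. The rank condition is an identifiability
assumption, not checked at run time; a diagnostic warning is emitted below
10 bins.

A deliberately documented limitation: on data whose backbone covariance is
*not* low-rank (e.g. an unconfined random walk), the median picks up a
common signal term, so $\hat\sigma_a^2$ is biased upward **equally on all
axes**. The weights are then attenuated toward 1/3 but keep the correct
ordering; everything downstream uses only the weights, never the absolute
variances. `summary()` of the worked example in the README shows exactly
this behaviour.

## The variance field

All tests consume three per-axis objects — a normalized variance matrix
$V_a$, a count matrix $C_a$ and an expected-variance curve $E_a$ — built in
six steps per axis:

1. **Robust raw variance.** Entry $(j,k)$ is
   $c \cdot \mathrm{median}_i\,[(d_i - \mathrm{median}_i\, d_i)^2]$ over
   traces observing both spots, $d_i = x_{ij} - x_{ik}$, with the Gaussian
   consistency constant $c = 1/\Phi^{-1}(0.75)^2 \approx 2.1981$ so the
   result is on the ordinary variance scale. Fewer than 3 complete pairs
   gives `NaN`. The robust form keeps step 2's trend estimate insensitive
   to gross mislocalizations.
2. **First lowess fit** of the finite entries against 1D genomic distance
   $s = |j-k| \cdot \text{resolution}$ (span 0.3, 3 robustifying
   iterations, every entry one point), linearly extrapolated at the range
   ends and floored at 1 nm². These parameters are fixed, not exposed:
   they are part of the method's definition so results are reproducible.
3. **4-SD filter.** A difference is kept iff $|d| \le 4\sqrt{E(s)}$. The
   Z-score is taken about 0, not the stratum median: pairwise differences
   are symmetric about zero under random chromosome orientation, and a
   zero center makes the rule a function of $|d|$ alone.
4. **Filtered variance**: the ordinary mean-based sample variance of the
   surviving differences (denominator $C-1$); the robust form is only
   needed before outliers are removed.
5. **Second lowess fit** of the filtered variances against distance,
   per axis.
6. **Normalization**: filtered variance divided by the second fit's
   prediction. Variances are divided (not SDs), so a variance *ratio*
   against any background built from the same field is trend-free.

The diagonal is excluded throughout. Computation streams one distance
stratum at a time ($O(np)$ working memory), so the $n \times p \times p$
difference tensor never exists in memory; `pooled_variance()` exposes the
count-weighted pooling rule ($s^2 = \sum (C-1)V / \sum(C-1)$,
$df = \sum(C-1)$) that makes $(V_a, C_a)$ sufficient for every downstream
test, a contract the test suite verifies against brute-force recomputation
from raw differences.

## Feature callers

### Loops

For pair $(j,k)$ the local background is the Chebyshev ring of pairs whose
anchors are displaced by 25–50 kb (radii converted to bins by the
resolution; ring entries must themselves be off-diagonal by at least
25 kb). Chebyshev (not Manhattan) distance is used so "25–50 kb from the
tested pair" constrains both anchors simultaneously. Per axis, a
lower-tail F test compares the entry's variance ($df = C-1$) with the
pooled ring ($df = \sum(C-1)$): loops are *closer* than their
neighbourhood, i.e. have smaller difference variance. Pairs with fewer
than 3 valid ring entries, or $C < 3$, are untestable on that axis.

Per-axis p-values are combined with the weighted aggregated Cauchy rule

$$T = \sum_a w_a \tan\{(0.5 - p_a)\pi\}, \qquad
  p = 0.5 - \arctan(T)/\pi,$$

which is exact for a single axis, robust to dependence between axes, and
lets untestable axes drop out with weight renormalization. P-values are
clipped to $[10^{-15}, 1 - 10^{-15}]$ before the tangent to avoid
overflow; the clip bound is a package constant.

Candidates are pairs with BH FDR below `fdr_threshold` (default 0.1)
among tested pairs. Candidates within 50 kb (Chebyshev, transitive
closure) form clusters; each cluster's minimum-p member is its summit
(ties broken lexicographically). Final loops are summits with
$p < 10^{-5}$; an optional contact-frequency filter (off by default, as
its use is dataset-specific) additionally requires cluster summits to
have population contact frequency ≥ 1/3 and singleton summits ≥ 1/2 at a
configurable 500 nm contact cutoff. The minimum tested separation
defaults to 100 kb so the ring cannot straddle the diagonal.

### TAD boundaries

Each bin $i$ is scored with a window of `window_kb` (default 200 kb —
read as *per side*, 8 bins at 25 kb; the alternative total-window reading
is available by halving the parameter) on each side: upstream set $U$,
downstream set $D$, the tested bin in neither. Intra-domain pairs are the
pairs within $U$ plus those within $D$; inter-domain pairs are
$U \times D$. An upper-tail F test on pooled inter vs intra variance
(same count-weighted pooling) flags insulation: at a boundary,
cross-window differences are inflated. Bins with less than half a window
available per side are excluded.

Exact p-values saturate at 0/1 once thousands of traces are available, so
peak *location* uses p-values recomputed from the same variance ratios
under an F(1,1) reference — far heavier-tailed, hence graded at any
sample size. One numerical point discovered in implementation: F(1,1)
p-values are compressed into roughly [0.1, 0.6], so a BH step-up over
them collapses to a single constant; the package therefore scans the
combined approximated *p-value* profile for local minima (BH is monotone
in it, so the scan is equivalent whenever the adjusted profile is
non-degenerate) while the BH-adjusted version is still reported. A
plateau counts once, at its leftmost bin; profile ends are not minima.
Final boundaries are minima whose *exact* FDR is below 0.1.

Hierarchical TADs: level-0 intervals tile the region between consecutive
boundaries; boundaries are then removed one at a time, least significant
first (smallest combined Cauchy statistic), each removal adding the
interval between the surviving neighbours with the level incremented per
removal. A region without boundaries reports one level-0 interval so the
tiling invariant holds downstream.

### A/B compartments

Compartmentalization is treated as a two-block stochastic block model on
bins. Per axis, the normalized variance matrix (missing entries imputed
with their distance-stratum mean, diagonal set to 1 — the normalization's
expected value; any constant gives the same eigenvectors) is
eigendecomposed; eigenpairs are ordered by |eigenvalue| because the
normalized matrix is not positive semidefinite, and the **second**
eigenvector is kept — the first tracks residual distance decay. The three
eigenvectors, scaled by the axis weights, are 2-means clustered (25
restarts, fixed seed, best inertia). With a TSS table the denser group is
labelled A; otherwise — or on ties — the group with lower within-group
weighted variance is B (condensed heterochromatin). The matrix choice
(normalized variance rather than a correlation transform) is isolated in
`axis_embedding()` so it can be swapped.

## The synthetic generator

`simulate_planted()` draws each axis independently from $N_p(0, K)$ with

* backbone $K_0(j,k) = \text{scale}^2 \min(j,k)$ — a cumulative random
  walk, so pairwise-difference variance grows linearly with separation,
  emulating polymer distance decay;
* **boundaries**: covariances of pairs straddling a boundary divided by
  the insulation factor (eigenvalue-clipped at 0 with a warning if an
  extreme factor breaks positive semidefiniteness);
* **compartments**: an additive rank-1 block term $c^2 uu^\top$
  ($u = \pm 1$ by label), i.e. a spatial separation of the two
  compartment clusters: cross-label pairs gain $4c^2$ nm² of difference
  variance, same-label pairs none. An additive term is used because
  multiplicative within-label scaling violates positive semidefiniteness
  at useful strengths and distorts the per-bin variances the weight
  estimator sees;
* **loops**: an anchor contraction $K \leftarrow AKA^\top$ that blends the
  two anchor coordinates toward their midpoint, shrinking the pair's
  difference variance to *exactly* the proximity factor while keeping
  $K$ positive semidefinite. Contractions also pull the anchors toward
  intermediate loci — visible as stripes along the anchors, as around
  real loop anchors;
* per-axis Gaussian noise, an optional per-trace random rigid offset of
  all bins past a split point (an "arm shift", the whole-chromosome
  confounder for compartment calling), and spot-level missingness.

`simulate_spiked()` generates the sparse low-rank regime in which the
median-diagonal noise estimator is consistent; its loadings are centered
within their support because the analysis model lives on per-trace
centered coordinates, where a center-of-mass signal component does not
exist. `resample_uniform_noise()` implements the real-data benchmark
design: three x-axis profiles from three distinct traces become the x, y
and z of a new trace, so all axes share one noise level by construction,
and `add_axis_noise()` injects controlled axis-specific noise on top.

**What the generator does not emulate.** Gaussian traces have no
excluded-volume effects, no locus-specific detection efficiency, no
mislocalization outliers beyond what the noise SD encodes, and the
random-walk backbone is not low-rank — which is why weight estimates on
planted datasets are attenuated (see above). Passing tests therefore
demonstrate calibration and recovery under the stated covariance-level
conditions, not performance on any particular experimental dataset.

## Reference study conditions

The acceptance checks (test suite and `scripts/acceptance.R`) fix these
conditions, chosen once as realistic for the data class:

* **Noise recovery**: spiked rank-3 signal on 10 of 60 bins, loading SD
  300 nm, noise 100/100/200 nm, n = 800, 20 replicates.
* **Null calibration**: structureless traces (backbone scale 0, noise
  100 nm on all axes), n = 500, p = 60, 20 replicates. Structureless,
  because the F-test's independence approximations hold there exactly:
  with a polymer backbone the tested entry and its ring share trace
  realizations, positively correlating numerator and denominator, which
  makes the test *conservative* (p-values pile toward 0.5) — a
  documented property, not a calibration target. KS uniformity is
  evaluated on 10⁴ pooled per-axis p-values.
* **Loops**: three planted loops at bin pairs (10,25), (20,50), (35,55)
  with proximities 0.6/0.7/0.75 (distinct strengths, so that rank
  stability across noise levels is a meaningful quantity), n = 800 at
  25 kb, scale 85 nm, base noise 100 nm, z-noise injections of 0/100/200
  nm; recall is measured at the FDR-0.1 candidate screen, 10 replicates.
* **TADs**: boundaries after bins 12/24/36/48 with insulation 2, n = 400;
  stability compared between 0 and 150 nm added z noise, ±1-bin matching,
  10 replicates.
* **Compartments**: 60 bins at 250 kb, scale 40 nm (a weakly drifting,
  territory-like backbone), alternating 15-bin blocks separated by
  100 nm, noise 150/150/50 nm, an x/y arm shift of SD 300 nm at the
  midpoint as confounder, n = 30, 10 replicates — the regime where
  adaptive weighting must rescue the z-axis signal from the x/y
  confounder while equal weights degrade.

Problem sizes are the package's reference choices: large enough for the
asymptotic F/BH machinery to apply, small enough that the full evaluation
re-runs in minutes on one CPU.

## Numerical choices and degenerate inputs

* Variance pooling weights are $C-1$ (per-entry degrees of freedom);
  entries with $C < 2$ are never used; guard `pmax(v, 0)` absorbs
  floating-point round-off in streamed variance accumulation.
* Lowess evaluators collapse tied abscissae by averaging, interpolate
  linearly, extrapolate with the end-segment slopes and floor at 1 nm².
  Fewer than 5 finite points (or fewer than 3 distinct distances) falls
  back to interpolated stratum means.
* `cauchy_combine` clips p-values at $10^{-15}$; combined p-values below
  that are reported at the clip and are ties by construction.
* K-means uses a fixed seed (default 0, a CLI/function parameter) and
  ≥ 10 restarts; the caller's RNG state is saved and restored around all
  seeded operations, including the simulators.
* Summit and minimum ties break lexicographically; plateau minima report
  their leftmost bin.
* Traces with zero observed spots are dropped with a warning; datasets
  are not filtered by missingness by default (`max_missing_frac = 1`).

## Known limitations

* The weight estimator's absolute noise variances are meaningful only
  under (approximately) low-rank signal; otherwise trust the ordering,
  not the magnitudes.
* The loop F-test is conservative on strongly structured backbones (see
  the calibration note); its nominal FDR is then an upper bound.
* Strong planted loops induce anchor stripes whose candidates can chain
  clusters together; summit counts are then not a loop count. The
  candidate table, not the summit list, is the statistically calibrated
  object.
* Each chromosome is analysed independently; there is no multi-chromosome
  joint model, no spot-localization step, and no single-cell (per-trace)
  domain detection.
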