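# axistrace

Axis-aware discovery of 3D-genome features — chromatin loops, TAD
boundaries and A/B compartments — from multiplexed DNA FISH chromatin
tracing data.

## The problem

Chromatin tracing experiments (DNA seqFISH+, DNA-MERFISH, ORCA, …) report
the 3D coordinates, in nm, of consecutive genomic segments in thousands of
single cells. Because images are acquired in x–y planes while stepping
along the optical axis, the z coordinate usually carries a different — often
larger — measurement error than x and y. Pipelines that first collapse the
data into pairwise *Euclidean distance* matrices mix the axes with equal
weight, so one noisy axis can mask the accurate signal in the other two.

axistrace instead analyses each axis separately and combines the evidence
with adaptive weights:

1. **Axis weights.** Each centered trace is modelled as
   `x = x̃ + ε_x`, `x̃ ~ N_p(0, K)`, `ε_x ~ N_p(0, σ_x² I)` (and likewise
   for y, z) with a low-rank signal covariance `K`. Under this spiked-
   covariance model the median of the per-bin sample variances estimates
   σ_a², and the weights are `w_a = σ_a⁻² / Σ_b σ_b⁻²` — the
   inverse-variance rule familiar from meta-analysis.
2. **Variance field.** For every axis the p×p matrix of pairwise-difference
   variances `Var(x_ij − x_ik)` is computed robustly (median-based, with
   the Gaussian consistency constant 1/Φ⁻¹(0.75)² ≈ 2.198), outliers beyond
   4 expected SDs of a lowess distance trend are removed, and the filtered
   variances are divided by a second lowess fit so the genomic-distance
   decay is flattened to 1. Squared 3D distance is the *sum* of the three
   per-axis difference variances, so each normalized matrix carries the
   same loop/TAD/compartment geometry as a distance matrix — one axis at a
   time.
3. **Feature tests, combined across axes.**
   - *Loops*: each bin pair is tested (one-sided F) for a smaller variance
     than its pooled 25–50 kb local background ring; per-axis p-values
     `p_x, p_y, p_z` are combined with the weighted aggregated Cauchy
     statistic `T = Σ_a w_a tan((0.5 − p_a)π)`, `p = 0.5 − arctan(T)/π`;
     BH FDR < 0.1 defines candidates, which are clustered (50 kb) into
     summits and filtered at p < 1e−5 (optionally by contact frequency).
   - *TAD boundaries*: inter- vs intra-domain pooled variance F-test in a
     200 kb window per side, Cauchy-combined, FDR-screened, with peak
     finding on an F(1,1)-approximated profile and a removal algorithm
     that assembles hierarchical TAD levels.
   - *A/B compartments*: the second eigenvector of each axis's normalized
     matrix forms a 3D embedding, scaled by the weights and 2-means
     clustered; the cluster with higher TSS density is A (with a
     within-group-variance fallback).

The package also ships the evaluation machinery: a FOF-CT reader/writer, a
real-data resampling simulator with axis-noise injection, a fully synthetic
generator with planted loops/domains/compartments, and interval utilities
(TSS counting, log2 enrichment, reference-loop consensus).

## Worked example

```r
library(axistrace)

# 600 synthetic traces, 60 bins at 25 kb; z noisier than x/y (200 vs 100 nm);
# two planted loops
sim <- simulate_planted(simulation_spec(
  n = 600, p = 60, seed = 7, noise_sd = c(100, 100, 200),
  loops = data.frame(j = c(10, 35), k = c(25, 55), proximity = c(0.55, 0.65))))

fit <- axistrace(sim$data)    # center, estimate weights, build the field
summary(fit)
#> Axis-aware trace model: 600 traces x 60 bins on chrS (25000 bp/bin)
#>
#> Estimated noise SD (nm) and weights:
#>   axis noise_sd weight
#> 1    x    272.9 0.3680
#> 2    y    272.7 0.3687
#> 3    z    322.6 0.2633
#>
#> Normalized variance field (upper triangle):
#>   axis frac_testable mean_V
#> 1    x             1  0.994
#> 2    y             1  0.990
#> 3    z             1  0.995
```

The noisier z axis is automatically down-weighted (0.26 vs 0.37); the
estimated noise SDs exceed the injected values because the polymer backbone
contributes to every per-bin variance — the *ordering*, which drives the
weights, is what matters. The normalized field is flat at 1, confirming the
distance trend was removed.

```r
call_loops(fit)
#> Loop calls: 1596 tested pairs, 12 candidates, 7 summits, 2 final
#>   j  k            p          fdr contact_freq
#>  10 25 1.735612e-12 2.770036e-09    0.5533333
#>  35 55 1.282071e-06 1.023093e-03    0.4150000
```

Exactly the two planted pairs survive the full pipeline, with the stronger
loop (proximity 0.55) at the smaller p-value.

```r
sim2 <- simulate_planted(simulation_spec(
  n = 400, p = 60, seed = 8,
  boundaries = data.frame(pos = c(20, 40), insulation = 2)))
call_tads(axistrace(sim2$data))
#> TAD calls: 2 boundaries over 60 bins
#>   boundary bins: 21, 41
#>   5 hierarchical intervals (levels 0-2)
```

Both planted boundaries (after bins 20 and 40) are located at the first bin
of the downstream block.

A thin command-line wrapper is available after installation:
`exec/axistrace <weights|loops|tads|compartments|simulate> --input traces.csv …`.

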