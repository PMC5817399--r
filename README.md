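# morphodisp

Disparity-through-time analysis for paleobiological samples, built around
the two morphometric data types common in studies of fossil fishes:
2-D landmark configurations of whole-body outlines (geometric
morphometrics) and functional character ratios measured on lower jaws.
The package takes digitized specimens from TPS files and CSV tables to
per-time-bin disparity series, permutation tests across extinction
boundaries, and subgroup decompositions, in one reproducible pipeline.

## What it computes

**Superimposition.** Generalized Procrustes analysis removes position,
scale and orientation: every configuration is centred, scaled to unit
centroid size and rotated (proper rotations only) to an iteratively updated
consensus. Semilandmarks — points that capture curve geometry but have no
exact anatomical identity — are slid along their tangent directions to
minimize the thin-plate-spline bending energy

E(X) = x'Mx + y'My,

where `M` is the bending energy matrix of the consensus (kernel
U(r) = r² log r²). The tangent offsets solve the generalized least-squares
system restricted to the sliders; cycles that fail to lower total energy
are rejected, so the energy trajectory is monotone.

**Morphospace.** PCA (covariance by default) of the aligned coordinates or
of the five jaw characters: anterior and posterior mechanical advantage
(in-lever / out-lever), maximum and average relative jaw depth, and
relative tooth-row length. Shapes can be reconstructed anywhere along an
axis as `consensus + score · loading`.

**Disparity per time bin**, with three complementary metrics:

- sum of variances across PC axes, SoV = Σⱼ s²ⱼ (denominator n − 1);
- mean pairwise Procrustes distance, MPD = mean over all C(n,2) pairs;
- convex-hull content over the first 2…5 axes, normalized by the series
  maximum.

Percentile bootstrap CIs (1000 replicates, 95%) accompany the variance and
MPD series.

**Inference.** Permutation tests across boundary bin pairs (by default the
Permo-Triassic boundary, late Permian vs Early Triassic, and the
Triassic-Jurassic boundary, Rhaetian vs Hettangian): a centroid-shift test
(Euclidean distance between bin means in full score space, 9999
permutations, NPMANOVA-style) and a disparity-difference test
(|D(A) − D(B)|, 1000 permutations). Small problems are enumerated
exhaustively for exact p-values; sampled p-values carry the +1 correction.

**Partial disparity** (Foote): with the bin centroid c,
PD(g) = Σᵢ∈g ‖xᵢ − c‖² / (N − 1), which sums exactly to the bin's sum of
variances over any partition — by infraclass (Chondrostei, Holostei,
Teleostei, Incertae sedis) or environment (marine, freshwater).

Specimens are grouped by stratigraphic stage into a 17-bin
Permian–Jurassic scheme (12 single stages plus five combined bins over 27
ICS stages, Asselian to Tithonian) that ships as an editable CSV.

## Worked example

The synthetic-data generator plants a known per-bin disparity ladder, so
the whole pipeline can be exercised and validated without any external
data:

```r
library(morphodisp)
design <- simulationDesign(n_per_bin = 20)
sim <- generateLandmarkDataset(design, seed = 42)
res <- runBodyShape(sim$configurations, design$scheme$slider_triples,
                    sim$records, seed = 1,
                    B_bootstrap = 500, B_npmanova = 999, B_disparity = 499)
#> stage gpa: 340 configurations, k = 28
#> stage sliding: 2 cycle(s), 0 fallback(s)
#> stage pca: 56 axes; PC1-2 = 27.8%
#> stage disparity: 9 series over 17 bins
#> stage tests: 10 boundary tests

head(res$series$variance[c("bin", "value", "ci_low", "ci_high", "n")], 5)
#>             bin     value    ci_low   ci_high  n
#>   early Permian 0.0004097 0.0003438 0.0004335 20
#>  middle Permian 0.0007203 0.0005739 0.0007948 20
#>    late Permian 0.0008824 0.0006502 0.0010253 20
#>  Early Triassic 0.0011893 0.0008897 0.0013874 20
#>         Anisian 0.0019346 0.0014186 0.0022852 20

subset(res$tests, metric %in% c("all_axes", "variance"),
       select = c(test, bin_A, bin_B, observed, p))
#>                   test        bin_A          bin_B    observed     p
#> 1       centroid_shift late Permian Early Triassic 0.013552145 0.029
#> 2 disparity_difference late Permian Early Triassic 0.000306913 0.084
#> 6       centroid_shift     Rhaetian     Hettangian 0.036122287 0.414
#> 7 disparity_difference     Rhaetian     Hettangian 0.007956062 0.002
```

The variance series climbs the planted ladder (disparity was generated to
increase toward the youngest bin); its bootstrap interval brackets each
value, and the boundary tests read off whether the planted increase across
each boundary is detectable at these sample sizes. The functional arm works
the same way from `generateTraitDataset()` /
`runFunctional()`, reporting the missingness fraction and complete-case
count before ordination.

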