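---
title: "Measuring morphological disparity through time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring morphological disparity through time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

morphodisp quantifies how the morphological variety (disparity) of a clade
changes across geologic time, from two data sources: 2-D landmark
configurations of body outlines, and functional character ratios of lower
jaws. This vignette explains the model behind each stage, the parameters
that matter, the numerical choices, and what the synthetic-data validation
does and does not demonstrate.

## Superimposition model

A landmark configuration is a $k \times 2$ matrix of coordinates in
arbitrary image units. Shape is what remains after position, scale and
orientation are removed, which `gpa()` does in the standard iterative way:
each configuration is centred, scaled to unit centroid size (the root
summed squared deviation from the centroid), and rotated by the proper
rotation minimizing its summed squared distance to the running consensus;
the consensus is the arithmetic mean of aligned configurations, rescaled to
unit centroid size each iteration. Iteration stops when the consensus moves
less than `tol = 1e-8` (RMS per coordinate), usually within a handful of
iterations.

Two assumptions are deliberate:

* **Reflections are excluded.** The optimal rotation is constrained to
  determinant $+1$. A mirrored specimen (a fossil photographed from the
  other side) would otherwise be silently flipped into apparent
  similarity; inputs are assumed to be pre-standardized to face the same
  way.
* **The output pose is canonical.** After convergence the whole sample is
  rotated so the consensus' major principal axis lies along $x$, with the
  sign fixed by its largest-$|x|$ landmark. Without this step the output
  orientation would follow the arbitrary pose of whichever specimen was
  listed first; with it, GPA is invariant (to numerical precision) under
  reordering and under similarity transforms of the inputs.

## Semilandmark sliding

Fixed landmarks mark discrete anatomical features; semilandmarks capture
curvature between them and have no exact positional identity along the
curve, so their tangential position is treated as a nuisance parameter.
`slideSemilandmarks()` optimizes it by bending-energy minimization: from
the consensus the thin-plate-spline bending energy matrix $M$ is built
(kernel $U(r) = r^2 \log r^2$, bordered by the affine block $[1\,|\,x\,|\,y]$;
$M$ is the upper-left $k \times k$ block of the inverse system). $M$ is
symmetric positive semi-definite and annihilates affine terms, so purely
affine deformations cost nothing. For each specimen, each semilandmark may
move only along its tangent — the unit chord between its `before` and
`after` neighbours in that specimen — and the vector of tangent offsets
solves the generalized least-squares system restricted to the sliders.
If that system is numerically singular the specimen falls back to a plain
tangent projection (counted and reported).

After all specimens slide, the sample is re-superimposed and the consensus
updated, and the cycle repeats (`max_cycles = 10`). Pure sliding against a
continually updated consensus admits a slow collective drift mode — all
semilandmarks migrating together along the outline — so the loop keeps the
best state: a cycle that fails to lower the summed bending energy is
rejected and iteration stops. The accepted energy trajectory is therefore
monotone non-increasing by construction, and within every cycle the exact
GLS solve guarantees the decrease. This was a genuinely open design point
(the alternative is sliding against a frozen initial reference); the
updated-consensus flavour was chosen because it treats all specimens
symmetrically at the fixed point, with the rejection rule supplying the
stability the frozen-reference variant gets for free.

## Ordination and shape reconstruction

`shapePCA()` is a column-centred PCA (`prcomp`), covariance-mode by
default, reporting $\min(n-1, p)$ axes with trailing numerically-zero
eigenvalues (below $10^{-12}$ of the largest) set to exact zeros, and a
deterministic sign convention (each loading column's largest-magnitude
entry is positive) so results are stable across platforms. Covariance mode
is the default for both arms: aligned coordinates share units by
construction, and the five jaw characters are dimensionless ratios of
comparable scale. Correlation mode is available (`mode = "correlation"`),
and for functional data both are worth running, since standardization can
redistribute variance among axes. `shapeAlongAxis()` reconstructs the
configuration at any score as consensus + score × loading, which is how
axis extremes are visualized.

## Disparity metrics and uncertainty

Three metrics cover the density and extent aspects of morphospace
occupation:

* **Sum of variances** (`sumOfVariances`): sample variance, denominator
  $n-1$, summed over PC axes. The denominator is a deliberate choice — it
  makes the Foote partial-disparity identity below exact.
* **Mean pairwise distance** (`meanPairwiseDistance`): mean of all
  $\binom{n}{2}$ Euclidean distances. Applied to aligned coordinates these
  are partial Procrustes distances *in the common frame* of the joint
  superimposition — the default flavour, because bin-wise distances are
  naturally read off one joint alignment. A per-pair re-rotation flavour
  (`pair_align = TRUE`) is offered; it can only shrink distances.
* **Convex hull content** (`hullMeasure`): area to 5-D hypervolume over
  the leading axes, computed by an incremental (beneath-beyond) hull
  construction written for the small, low-dimensional point sets of
  per-bin morphospaces. Degenerate bins (fewer than `n_axes + 1` points,
  or affinely dependent points) are reported *missing*, not zero — a zero
  would read as a real collapse of morphospace — and are excluded from the
  series maximum when hull series are normalized to their largest bin.

Variance and MPD series carry percentile bootstrap intervals
(`bootstrapCI`; 1000 replicates, 95%, resampling specimens with
replacement at the bin's own $n$). The percentile method was chosen over
BCa as the simplest interval consistent with bracketing the mean disparity
value; replicates on which a metric is undefined are skipped and counted,
and an interval with more than half its replicates skipped is reported
missing rather than fabricated. The bootstrap resamples specimens (not
pairwise distances) for MPD — the option that keeps the replicate a valid
sample of configurations.

**Foote partial disparity** decomposes a bin's total: with the centroid
$c$ of all bin members, $PD(g) = \sum_{i \in g} \lVert x_i - c \rVert^2 /
(N-1)$. Over any partition the $PD(g)$ sum *exactly* to the bin's sum of
variances — an algebraic identity the test suite asserts to $10^{-10}$ on
random partitions.

## Permutation tests

`centroidShiftTest()` tests for location shifts between two bins
(NPMANOVA-style): the statistic is the Euclidean distance between group
centroids in full score space; the null re-partitions the pooled specimens
into the original group sizes. `disparityDifferenceTest()` does the same
with $|D(A) - D(B)|$ for any of the three metrics — two-sided via the
absolute difference, since the question is "different", not "larger".
Defaults are 9999 permutations for the centroid test and 1000 for the
disparity tests, $\alpha = 0.05$. When $\binom{n_A+n_B}{n_A}$ does not
exceed the budget, all assignments are enumerated and the p-value is exact
(the observed assignment is part of the enumeration); otherwise the
sampled p-value carries the +1 correction $(\#\{null \ge obs\}+1)/(B+1)$,
which can never be zero — chosen for validity, since an uncorrected
sampled p of 0 overstates the evidence. The preset boundary pairs are
late Permian vs Early Triassic (Permo-Triassic boundary, ~252 Ma) and
Rhaetian vs Hettangian (Triassic-Jurassic boundary, ~201 Ma); any pair can
be passed explicitly.

## Time binning

The default scheme spans the Asselian (298.9 Ma) through the Tithonian
(145 Ma): 27 ICS stages grouped into 17 bins — 12 single stages plus five
combined bins (early, middle and late Permian, Early Triassic, Middle
Jurassic) that pool short or poorly sampled stages. Combined-bin
membership follows ICS series boundaries, the natural convention where the
exact grouping is not otherwise dictated; midpoint ages are series/stage
midpoints. The scheme ships as an editable CSV
(`inst/extdata/bins_permian_jurassic.csv`), so alternatives — e.g.
series-level bins across the Permo-Triassic boundary — are a config swap.
Bins below `min_bin_n = 3` specimens are reported missing in disparity
series: a variance over two specimens is not a disparity estimate, and the
smallest bins are exactly where a fossil record is least trustworthy.
(The functional arm of a real dataset may drop to $n = 2$ in its worst
bin; the policy reports such bins' sample sizes but withholds their
disparity values.)

## The synthetic-data generator

`generateLandmarkDataset()` emulates the statistical structure the
pipeline assumes, not fish anatomy: each specimen is a 28-landmark
fish-like template (14 fixed landmarks, 14 semilandmarks on six curves)
plus a random combination of orthonormal deformation modes plus isotropic
digitization noise, then hit with a random rotation, translation and scale
for GPA to undo. The deformation modes are sinusoidal displacement fields
over the outline, projected off the four similarity directions
(translations, rotation, scaling) at the template and orthonormalized, so
the planted variance survives the Procrustes projection to first order;
the residual leakage plus the noise's loss of four similarity directions
are the reasons the truth table's `planted_total`
($\sigma^2_{bin} + 2k\,\sigma^2_{noise}$) is an approximation rather than
an exact target.

Defaults are chosen once as the study conditions for validation: 30
specimens per bin across the 17 bins (the order of per-bin sampling in a
well-sampled fossil compilation), noise SD 0.0015 on the unit-size shape
(sub-percent digitization error), and a geometric ladder of planted
per-bin variances, $4 \times 10^{-4} \cdot 1.5^{i-1}$, increasing toward
the youngest bin. The 1.5 ratio deserves a note: for the *entire* 17-bin
ordering to be recoverable from sample variances in at least 95% of runs
at $n = 50$ per bin, adjacent bins must differ by several standard errors
of a variance estimate, which forces the ladder to span roughly three
orders of magnitude. That makes the top bins strongly deformed — this is a
statistically resolvable ladder, not a realistic fossil signal, and the
recovery test should be read as validating the pipeline's ordering
fidelity, not as a statement about real disparity magnitudes.

`generateTraitDataset()` draws jaw characters from three ecotype clusters
(a generalist, a deep-jawed high-mechanical-advantage durophage cluster,
an elongate piscivore cluster) with independent within-cluster spreads,
truncated below at 0.01 to respect positivity, and masks cells missing
completely at random at per-character rates `(0.06, 0.30, 0.05, 0.05,
0.40)` — 17.2% of cells overall, concentrated in the posterior
mechanical-advantage and tooth-row characters, the two that preservation
obscures most in real jaw material. Real missingness is preservational,
not MCAR; MCAR suffices here because the analysis path is complete-case,
so only the plumbing (rate accounting and filtering), not a
missingness-mechanism model, is being exercised. Imputation is
deliberately not offered: regularized-PCA imputation of such gaps
produces artefactual linear structure in morphospace, so the package
filters to complete cases instead.

What passing the synthetic suite shows: superimposition, sliding,
ordination, the metrics, the bootstrap and the tests are implemented
correctly and interact correctly at realistic sample sizes. What it does
not show: robustness to taphonomic distortion, preservational
(non-random) missingness, phylogenetic autocorrelation, or digitization
operator effects — none of which the generator emulates.

## Numerical choices

* Bending-energy system inverted directly ($k+3$ square; $k = 28$ is
  tiny); coincident landmarks are a hard error (singular kernel).
* The sliding GLS solve falls back to tangent projection when the
  restricted system's reciprocal condition number drops below $10^{-12}$.
* Hull construction uses a visibility tolerance of $10^{-9}$ times the
  point-cloud extent; points within tolerance of a facet plane count as
  interior, which perturbs volumes by at most that order.
* PCA eigenvalues below $10^{-12}$ of the largest are reported as exact
  zeros (they are Procrustes-constraint artefacts, not variance).
* Exhaustive permutation enumeration triggers whenever
  $\binom{n_A+n_B}{n_A} \le B$; the $\ge$ comparisons in p-values use a
  $10^{-12}$ slack so ties at the observed value count as extreme.
* All generators and pipeline stages draw per-stage sub-seeds from one
  master seed, so changing one stage's replication budget does not
  perturb any other stage's draws.

## Problem sizes used in validation

The shipped test-and-acceptance suite validates at sizes chosen to make
the statistical assertions sharp while keeping a full run comfortable on a
single CPU: 100 similarity copies for GPA exactness; 100 random point sets
against the shoelace oracle and Monte-Carlo hull checks at $10^6$ samples;
500 null pairs at $n = 20$ per group for test size and 100 repeats at
$n = 30$ for power; 50 pipeline runs at $n = 50$ per bin for
ordering recovery; 200 simulated bins at $n = 200$ for bootstrap
coverage.

## Known limitations

* 2-D landmarks only; no 3-D, no curve resampling (input semilandmarks are
  taken as digitized), no retrodeformation of distorted specimens.
* Common-frame MPD and covariance-mode PCA are defaults with documented
  alternatives, not the only defensible choices; both switches are
  exposed.
* The centroid-shift test is a location test against an exchangeable null;
  like all NPMANOVA-style tests it can respond to dispersion differences
  when group sizes are unequal.
* Hull volumes in more than ~5 dimensions need more points than fossil
  bins usually offer; the interface caps hull dimensionality at 5 axes.
* No multiple-testing correction is applied across boundary tests; the
  handful of preset comparisons are reported as-is.
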